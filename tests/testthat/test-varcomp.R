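test_that("GRM matches the brute-force double-loop oracle", {
  set.seed(2)
  dosage <- matrix(rbinom(10 * 20, 2, 0.35), 10, 20)
  dosage[sample(length(dosage), 6)] <- NA
  map <- data.frame(chrom = rep(c("chr1", "chr2"), each = 10),
                    pos = rep(1:10 * 1000L, 2), id = sprintf("s%02d", 1:20),
                    ref = "A", alt = "C")
  G <- genotype_matrix(dosage, map)
  grm <- compute_grm(G)
  oracle <- brute_force_grm(G$dosage)
  expect_lt(max(abs(grm$A - oracle)), 1e-12)
  # identical individuals: off-diagonal equals each diagonal
  d2 <- rbind(dosage[1, ], dosage[1, ], dosage[3:10, ])
  d2[is.na(d2)] <- 1
  G2 <- genotype_matrix(d2, map)
  g2 <- compute_grm(G2)
  expect_equal(g2$A[1, 2], g2$A[1, 1])
  expect_equal(g2$A[1, 2], g2$A[2, 2])
})

test_that("GRM sampling behavior on an unrelated cohort", {
  set.seed(77)
  m <- 5000; n <- 60
  p <- runif(m, 0.1, 0.5)
  dosage <- matrix(rbinom(n * m, 2, rep(p, each = n)), n, m)
  map <- data.frame(chrom = "chr1", pos = seq_len(m) * 100L,
                    id = sprintf("s%05d", seq_len(m)), ref = "A", alt = "C")
  grm <- compute_grm(genotype_matrix(dosage, map))
  off <- grm$A[upper.tri(grm$A)]
  # standardization with estimated frequencies centers every SNP exactly, so
  # the off-diagonal mean is -mean(diag)/(n-1) rather than 0
  expect_lt(abs(mean(off) + mean(diag(grm$A)) / (n - 1)), 0.002)
  expect_lt(abs(sd(off) * sqrt(grm$n_snps) - 1), 0.3)
  expect_lt(abs(mean(diag(grm$A)) - 1), 0.05)
})

test_that("LOCO GRMs exclude their chromosome and reconstruct the full GRM", {
  cc <- make_cohort(seed = 41, n = 120, n_chrom = 5, chrom_mb = 8)
  G <- cc$G
  grms <- compute_loco_grms(G)
  # weighted average (weights = SNP counts used) reconstructs the full GRM
  num <- Reduce(`+`, lapply(grms$loco, function(g) g$A * g$n_snps))
  den <- sum(vapply(grms$loco, function(g) g$n_snps, 0))
  expect_lt(max(abs(num / den - grms$full$A)), 1e-10)
  # zeroing test: perturbing chr1 dosages leaves chr1's LOCO GRM untouched
  G2 <- G
  j <- G$map$chrom == "chr1"
  set.seed(1)
  G2$dosage[, j] <- matrix(rbinom(sum(j) * n_individuals(G), 2, 0.5),
                           ncol = sum(j))
  grms2 <- compute_loco_grms(G2)
  expect_equal(grms$loco$chr1$A, grms2$loco$chr1$A, tolerance = 1e-12)
  expect_gt(max(abs(grms$loco$chr2$A - grms2$loco$chr2$A)), 1e-6)
  expect_error(compute_loco_grms(subset_genotypes(G, snps = which(j))),
               ">= 2 chromosomes")
})

test_that("REML matches a brute-force grid maximization at small n", {
  set.seed(5)
  n <- 12
  A <- tcrossprod(matrix(rnorm(n * 30), n)) / 30
  L <- chol(0.6 * A + 0.4 * diag(n))
  for (rep in 1:3) {
    y <- drop(t(L) %*% rnorm(n))
    grm <- structure(list(A = A, ids = as.character(1:n), n_snps = 30,
                          excluded_chrom = NULL), class = "grm")
    fit <- fit_greml(y, grm)
    h2_bf <- brute_force_reml_h2(y, A)
    expect_lt(abs(fit$h2 - h2_bf), 1e-4)
  }
})

test_that("GREML recovers a planted heritability and estimates are invariant
           to covariate reparameterization", {
  set.seed(99)
  n <- 400; m <- 800
  p <- runif(m, 0.1, 0.5)
  dosage <- matrix(rbinom(n * m, 2, rep(p, each = n)), n, m)
  map <- data.frame(chrom = "chr1", pos = seq_len(m) * 100L,
                    id = sprintf("s%04d", seq_len(m)), ref = "A", alt = "C")
  G <- genotype_matrix(dosage, map)
  grm <- compute_grm(G)
  h2_true <- 0.4
  L <- chol(h2_true * (grm$A + 1e-6 * diag(n)) + (1 - h2_true) * diag(n))
  x <- rnorm(n)
  y <- drop(t(L) %*% rnorm(n)) + 0.5 * x
  f1 <- fit_greml(y, grm, covariates = data.frame(x = x))
  expect_lt(abs(f1$h2 - h2_true), 0.15)
  expect_lt(f1$lrt_p, 0.05)
  # REML log-likelihoods shift by a constant under covariate
  # reparameterization; the estimates and the LRT are invariant
  f2 <- fit_greml(y, grm, covariates = data.frame(x = 3 * x - 7))
  expect_equal(f1$h2, f2$h2, tolerance = 1e-6)
  expect_equal(f1$sigma2_g, f2$sigma2_g, tolerance = 1e-6)
  expect_equal(f1$lrt, f2$lrt, tolerance = 1e-6)
})

test_that("identity relatedness is flagged as unidentifiable and null traits
           give small h2", {
  set.seed(13)
  n <- 150
  grm_i <- structure(list(A = diag(n), ids = as.character(1:n), n_snps = 100,
                          excluded_chrom = NULL), class = "grm")
  fit <- fit_greml(rnorm(n), grm_i)
  expect_match(paste(fit$note, collapse = " "), "identifiable")
  expect_equal(fit$sigma2_g + fit$sigma2_e, 1, tolerance = 0.3)
  # structured GRM, pure-noise trait: h2 near 0, LRT p not small
  n <- 250
  A <- tcrossprod(matrix(rnorm(n * 1500), n)) / 1500
  grm <- structure(list(A = A, ids = as.character(1:n), n_snps = 1500,
                        excluded_chrom = NULL), class = "grm")
  fits <- lapply(1:10, function(i) fit_greml(rnorm(n), grm))
  h2s <- vapply(fits, `[[`, 0, "h2")
  expect_lt(mean(h2s), 0.15)
  expect_true(all(vapply(fits, `[[`, 0, "lrt_p") > 0))
  expect_true(all(vapply(fits, `[[`, 0, "lrt_p") <= 1))
})

test_that("GRM TSV round-trips", {
  cc <- make_cohort(seed = 47, n = 30, n_chrom = 2, chrom_mb = 5)
  grm <- compute_grm(cc$G)
  prefix <- file.path(tempdir(), "grm_test")
  write_grm_tsv(grm, prefix)
  grm2 <- read_grm_tsv(prefix)
  expect_equal(grm2$A, grm$A, tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(grm2$ids, grm$ids)
  unlink(paste0(prefix, c(".grm.tsv", ".grm.id")))
})
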