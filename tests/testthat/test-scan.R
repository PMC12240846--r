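test_that("with sigma2_g pinned at 0 the scan reproduces OLS exactly", {
  cc <- make_cohort(seed = 51, n = 200, n_chrom = 2, chrom_mb = 5,
                    density = 5)
  G <- suppressMessages(filter_snps(cc$G, quiet = TRUE))
  grms <- compute_loco_grms(G)
  set.seed(1)
  y <- rnorm(200)
  x_cov <- rnorm(200)
  res <- assoc_scan(y, G, grms$loco, covariates = data.frame(x = x_cov),
                    var_components = list(sigma2_g = 0, sigma2_e = 1))
  for (j in seq_len(min(50, n_snps(G)))) {
    s <- G$dosage[, j]
    sm <- summary(lm(y ~ x_cov + s))$coefficients
    expect_equal(res$effect[j], sm["s", "Estimate"], tolerance = 1e-8)
    expect_equal(10^(-res$neglog10_p[j]), sm["s", "Pr(>|t|)"],
                 tolerance = 1e-8)
  }
})

test_that("null scans give uniform p-values", {
  cc <- make_cohort(seed = 53, n = 150, n_chrom = 4, chrom_mb = 25)
  G <- suppressMessages(filter_snps(cc$G, quiet = TRUE))
  expect_gt(n_snps(G), 1500)
  grms <- compute_loco_grms(G)
  # LD makes per-SNP tests strongly dependent, so the rejection fraction of a
  # single scan is noisy; average over independent null phenotypes instead
  prep <- hsqtl:::scan_prep(G, grms$loco)
  set.seed(2)
  fracs <- replicate(10, {
    res <- hsqtl:::scan_with_y(prep, rnorm(150))
    mean(10^(-res$neglog10_p) < 0.05, na.rm = TRUE)
  })
  expect_lt(abs(mean(fracs) - 0.05), 0.015)
})

test_that("conditioning SNPs become untestable covariates that absorb their
           signal", {
  cc <- make_cohort(seed = 55, n = 250, n_chrom = 2, chrom_mb = 10,
                    qtls = list(planted_qtl("chr1", 5e6, 0.15)))
  G <- suppressMessages(filter_snps(cc$G, quiet = TRUE))
  grms <- compute_loco_grms(G)
  y <- prepare_trait(cc$table, "trait", "sex")
  causal <- cc$truth$qtls$snp_id
  res0 <- assoc_scan(y, G, grms$loco)
  peak0 <- res0$neglog10_p[res0$id == causal]
  expect_gt(peak0, 4)
  res1 <- assoc_scan(y, G, grms$loco, conditioning_snps = causal)
  expect_true(is.na(res1$neglog10_p[res1$id == causal]))
  left <- res1[res1$chrom == "chr1" & res1$id != causal, ]
  expect_lt(max(left$neglog10_p, na.rm = TRUE), peak0)
})

test_that("permutation threshold quantiles behave and warn when unresolvable", {
  cc <- make_cohort(seed = 57, n = 100, n_chrom = 2, chrom_mb = 5)
  G <- suppressMessages(filter_snps(cc$G, quiet = TRUE))
  grms <- compute_loco_grms(G)
  set.seed(3)
  y <- rnorm(100)
  thr <- permutation_threshold(y, G, grms$loco, n_perm = 40, alpha = 0.05,
                               seed = 9)
  expect_equal(thr$value,
               unname(quantile(thr$maxima, 0.95, type = 7)))
  thr_all <- permutation_threshold(y, G, grms$loco, n_perm = 40, alpha = 1,
                                   seed = 9)
  expect_equal(thr_all$value, min(thr$maxima))
  expect_lte(thr_all$value, thr$value)
  expect_warning(
    permutation_threshold(y, G, grms$loco, n_perm = 30, alpha = 0.01,
                          seed = 9),
    "achievable")
  expect_error(permutation_threshold(y, G, grms$loco, n_perm = 10), ">= 20")
})

test_that("LD r2 matches hand values and handles degenerate input", {
  dosage <- cbind(a = c(0, 1, 2, 0), b = c(2, 1, 0, 2), c = c(1, 1, 1, 1),
                  d = c(0, 2, 1, 1))
  map <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L, 40L),
                    id = c("a", "b", "c", "d"), ref = "A", alt = "C")
  G <- genotype_matrix(dosage, map)
  expect_equal(ld_r2(G, "a", "a"), 1)
  expect_equal(ld_r2(G, "a", "b"), 1)            # perfect anti-correlation
  expect_true(is.na(ld_r2(G, "a", "c")))         # monomorphic
  set.seed(6)
  n <- 1000
  d2 <- cbind(x = rbinom(n, 2, 0.3), y = rbinom(n, 2, 0.4))
  G2 <- genotype_matrix(d2, data.frame(chrom = "chr1", pos = c(1L, 2L),
                                       id = c("x", "y"), ref = "A", alt = "C"))
  expect_lt(ld_r2(G2, "x", "y"), 0.01)
})

test_that("the support-SNP rule is applied with inclusive boundaries", {
  thr <- 5.58
  # supported peak: neighbor within 0.5 Mb and within 2 units
  sc <- fake_scan("chr1", c(35e6, 35.2e6, 36e6), c(7.0, 6.2, 3.0))
  q <- call_qtls(sc, thr)
  expect_equal(nrow(q), 1)
  expect_equal(q$pos, 35e6)
  expect_equal(q$n_support, 1)
  # nearest neighbor below peak - 2: rejected
  sc2 <- fake_scan("chr1", c(35e6, 35.2e6), c(7.0, 4.9))
  expect_equal(nrow(call_qtls(sc2, thr)), 0)
  # boundaries exactly at peak - 2 and exactly 0.5 Mb: accepted
  sc3 <- fake_scan("chr1", c(35e6, 35.5e6), c(7.0, 5.0))
  expect_equal(nrow(call_qtls(sc3, thr)), 1)
  # 1 bp beyond the window: rejected
  sc4 <- fake_scan("chr1", c(35e6, 35500001), c(7.0, 5.0))
  expect_equal(nrow(call_qtls(sc4, thr)), 0)
  # sub-threshold peaks are never candidates
  sc5 <- fake_scan("chr1", c(1e6, 1.1e6), c(5.5, 5.4))
  expect_equal(nrow(call_qtls(sc5, thr)), 0)
  # ties at the peak break to the lower bp
  sc6 <- fake_scan("chr1", c(2e6, 1e6, 1.2e6), c(7, 7, 6.5))
  expect_equal(call_qtls(sc6, thr)$pos, 1e6)
})

test_that("LD intervals contain the peak, shrink with r2_min, ignore
           contiguity", {
  set.seed(31)
  n <- 300
  peak <- rbinom(n, 2, 0.4)
  noisy <- function(x, flips) {
    y <- x
    i <- sample(n, flips)
    y[i] <- rbinom(flips, 2, 0.4)
    y
  }
  dosage <- cbind(s1 = rbinom(n, 2, 0.4),      # independent (low r2)
                  s2 = noisy(peak, 30),        # strong LD
                  s3 = peak,                   # the peak
                  s4 = noisy(peak, 40),        # strong LD
                  s5 = rbinom(n, 2, 0.4),      # independent gap
                  s6 = noisy(peak, 35))        # strong LD, distal
  map <- data.frame(chrom = "chr1", pos = c(1e6, 2e6, 3e6, 4e6, 5e6, 6e6),
                    id = paste0("s", 1:6), ref = "A", alt = "C")
  G <- genotype_matrix(dosage, map)
  r2 <- sapply(paste0("s", c(1, 2, 4, 5, 6)), function(s) ld_r2(G, "s3", s))
  expect_true(all(r2[c("s2", "s4", "s6")] >= 0.6))
  expect_true(all(r2[c("s1", "s5")] < 0.6))
  iv <- qtl_interval(G, "s3")
  expect_equal(unname(iv), c(2e6, 6e6))  # s6 qualifies despite the s5 gap
  # peak always inside; raising r2_min can only shrink
  iv_hi <- qtl_interval(G, "s3", r2_min = 0.99)
  expect_true(iv_hi[1] >= iv[1] && iv_hi[2] <= iv[2])
  expect_true(iv_hi[1] <= 3e6 && iv_hi[2] >= 3e6)
  # no qualifying neighbor: zero-width interval at the peak
  iv0 <- qtl_interval(G, "s1")
  expect_equal(unname(iv0), c(1e6, 1e6))
  # search window bounds the reach
  iv_w <- qtl_interval(G, "s3", search_window = 1.5e6)
  expect_equal(unname(iv_w), c(2e6, 4e6))
})

test_that("colocation respects the 3 Mb window and flags LD strength", {
  set.seed(33)
  n <- 200
  peak <- rbinom(n, 2, 0.4)
  tag <- peak; i <- sample(n, 10); tag[i] <- rbinom(10, 2, 0.4)
  weak <- peak; i <- sample(n, 120); weak[i] <- rbinom(120, 2, 0.4)
  dosage <- cbind(p = peak, t1 = tag, w1 = weak, far = rbinom(n, 2, 0.3))
  map <- data.frame(chrom = "chr1", pos = c(10e6, 11e6, 12e6, 14.5e6),
                    id = c("p", "t1", "w1", "far"), ref = "A", alt = "C")
  G <- genotype_matrix(dosage, map)
  ann <- data.frame(
    feature_id = c("GeneA", "GeneB", "GeneC", "GeneD"),
    tissue = c("NAcc", "PrL", "BLA", "OFC"),
    modality = c("eQTL", "coding", "sQTL", "eQTL"),
    snp_id = c("t1", "w1", "far", "absent"),
    chrom = "chr1", pos = c(11e6, 12e6, 14.5e6, 12.5e6),
    stringsAsFactors = FALSE)
  peak_row <- list(chrom = "chr1", id = "p", pos = 10e6)
  out <- colocate(peak_row, ann, G)
  expect_false("GeneC" %in% out$feature_id)    # 4.5 Mb away: excluded
  expect_true(out$strong_ld[out$feature_id == "GeneA"])
  expect_false(out$strong_ld[out$feature_id == "GeneB"])
  expect_true(is.na(out$r2[out$feature_id == "GeneD"]))   # absent from G
  expect_true(all(out$distance_bp <= 3e6))
})

test_that("PheWAS lookup extracts the exact SNP across trait scans", {
  s1 <- fake_scan("chr1", c(1e6, 2e6), c(6, 2)); attr(s1, "trait") <- "tr1"
  s2 <- fake_scan("chr1", c(1e6, 2e6), c(3, 1)); attr(s2, "trait") <- "tr2"
  s3 <- fake_scan("chr2", c(5e6), 4);            attr(s3, "trait") <- "tr3"
  out <- phewas_lookup("chr1:1000000", list(s1, s2, s3))
  expect_equal(out$trait, c("tr1", "tr2", "tr3"))
  expect_equal(out$neglog10_p, c(6, 3, NA))
  # identity: lookup against the same trait's scan returns its own record
  expect_equal(out$neglog10_p[out$trait == "tr1"],
               s1$neglog10_p[s1$id == "chr1:1000000"])
})
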