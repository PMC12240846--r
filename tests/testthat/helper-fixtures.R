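# Shared fixture builders and independent oracles. Oracles are deliberately
# brute-force / dense implementations that share no code path with the
# package internals they check.

# small mosaic cohort: genotypes (+ optional trait) at desk scale
make_cohort <- function(seed = 1, n = 200, n_chrom = 3, chrom_mb = 25,
                        density = 20, qtls = list(), h2_poly = 0,
                        recomb_rate = 0.5,
                        site_shift = c(site1 = 0, site2 = 0),
                        site_scale = c(site1 = 1, site2 = 1),
                        sex_effect = 0) {
  lens <- stats::setNames(rep(chrom_mb * 1e6, n_chrom),
                          paste0("chr", seq_len(n_chrom)))
  cfg <- sim_config(seed = seed, n_individuals = n, chrom_lengths = lens,
                    snp_density = density, recomb_rate = recomb_rate,
                    qtl_specs = qtls, h2_poly = h2_poly,
                    site_effect = list(shift = site_shift, scale = site_scale),
                    sex_effect = sex_effect)
  founders <- simulate_founders(cfg)
  G <- simulate_mosaic_genotypes(founders, cfg)
  tab <- simulate_phenotypes(G, cfg)
  list(config = cfg, G = G, table = tab,
       truth = attr(tab, "ground_truth"))
}

# GRM oracle: literal double loop over the standardized-genotype formula
brute_force_grm <- function(dosage) {
  d <- dosage
  for (j in seq_len(ncol(d))) {           # mean-impute per SNP
    m <- mean(d[, j], na.rm = TRUE)
    d[is.na(d[, j]), j] <- m
  }
  p <- colMeans(d) / 2
  keep <- p > 0 & p < 1
  d <- d[, keep, drop = FALSE]; p <- p[keep]
  n <- nrow(d); m <- ncol(d)
  A <- matrix(0, n, n)
  for (j in seq_len(n)) for (k in seq_len(n)) {
    s <- 0
    for (i in seq_len(m))
      s <- s + (d[j, i] - 2 * p[i]) * (d[k, i] - 2 * p[i]) /
        (2 * p[i] * (1 - p[i]))
    A[j, k] <- s / m
  }
  A
}

# dense REML profile log-likelihood in h2 (no eigen shortcut, no shared code)
dense_reml_llik_h2 <- function(h2, y, A, X) {
  n <- length(y)
  V0 <- h2 * A + (1 - h2) * diag(n)
  V0i <- solve(V0)
  XtViX <- t(X) %*% V0i %*% X
  P0 <- V0i - V0i %*% X %*% solve(XtViX) %*% t(X) %*% V0i
  s2 <- drop(t(y) %*% P0 %*% y) / (n - ncol(X))
  V <- s2 * V0
  Vi <- V0i / s2
  XtVX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtVX) %*% t(X) %*% Vi
  -0.5 * (determinant(V)$modulus[1] + determinant(XtVX)$modulus[1] +
            drop(t(y) %*% P %*% y))
}

brute_force_reml_h2 <- function(y, A, X = matrix(1, length(y), 1)) {
  opt <- stats::optimize(dense_reml_llik_h2, c(0, 0.9999), y = y, A = A,
                         X = X, maximum = TRUE, tol = 1e-7)
  opt$maximum
}

# planted-partition SBM graph with known block labels
sbm_graph <- function(n_per_block, K = 3, p_in = 0.3, p_out = 0.05,
                      seed = 1) {
  set.seed(seed)
  n <- n_per_block * K
  z <- rep(seq_len(K), each = n_per_block)
  A <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    p <- if (z[i] == z[j]) p_in else p_out
    A[i, j] <- A[j, i] <- stats::rbinom(1, 1, p)
  }
  ids <- sprintf("n%03d", seq_len(n))
  net <- structure(list(ids = ids, adjacency = A, similarity = NULL,
                        record = list(measure = "planted")),
                   class = "similarity_network")
  list(network = net, labels = z)
}

adjusted_rand <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE))
    mclust::adjustedRandIndex(a, b)
  else ari(a, b)
}

# hand-built scan_result for rule-fidelity fixtures
fake_scan <- function(chrom, pos, nlp, id = sprintf("%s:%d", chrom, pos)) {
  out <- data.frame(id = id, chrom = chrom, pos = pos, effect = 0.1,
                    se = 0.05, neglog10_p = nlp, stringsAsFactors = FALSE)
  class(out) <- c("scan_result", class(out))
  out
}
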