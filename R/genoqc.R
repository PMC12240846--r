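#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom chi-square goodness of fit of observed genotype
#' counts against the p^2 : 2pq : q^2 proportions expected from the sample
#' allele frequency. Monomorphic input returns p = 1 by convention.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (AA = reference homozygote).
#' @return two-sided p-value.
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("need at least one genotype")
  q <- (2 * n_aa + n_Aa) / (2 * n)      # alt allele frequency
  if (q == 0 || q == 1) return(1)
  p <- 1 - q
  expected <- n * c(p^2, 2 * p * q, q^2)
  chi2 <- sum((c(n_AA, n_Aa, n_aa) - expected)^2 / expected)
  stats::pchisq(chi2, df = 1, lower.tail = FALSE)
}

#' Per-SNP quality statistics
#'
#' Computes call rate (non-missing fraction), minor allele frequency among
#' non-missing calls, and the Hardy-Weinberg chi-square p-value, and stores
#' them in the genotype map. All-missing SNPs get call_rate 0 and NA for
#' maf/hwe_p.
#'
#' @param G a [genotype_matrix()].
#' @return `G` with `call_rate`, `maf`, `hwe_p` columns added to `G$map`.
#' @export
snp_stats <- function(G) {
  stopifnot(n_snps(G) > 0)
  d <- G$dosage
  n <- nrow(d)
  n_obs <- colSums(!is.na(d))
  call_rate <- n_obs / n
  p_alt <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(p_alt, 1 - p_alt)
  n0 <- colSums(d == 0, na.rm = TRUE)
  n1 <- colSums(d == 1, na.rm = TRUE)
  n2 <- colSums(d == 2, na.rm = TRUE)
  hwe_p <- vapply(seq_len(ncol(d)), function(j) {
    if (n_obs[j] == 0) return(NA_real_)
    hwe_test(n0[j], n1[j], n2[j])
  }, 0)
  maf[n_obs == 0] <- NA_real_
  G$map$call_rate <- call_rate
  G$map$maf <- maf
  G$map$hwe_p <- hwe_p
  G
}

#' Apply the three SNP filters
#'
#' Retains exactly the SNPs with missingness not above `max_missing`, minor
#' allele frequency no less than `min_maf`, and HWE deviation p-value no less
#' than `min_hwe_p` (all thresholds inclusive). Per-filter removal counts are
#' logged in the `qc_log` attribute and via [message()].
#'
#' @param G a [genotype_matrix()] (stats are computed if absent).
#' @param max_missing maximum missing fraction (default 0.10).
#' @param min_maf minimum minor allele frequency (default 0.005).
#' @param min_hwe_p minimum HWE p-value (default 1e-10).
#' @param quiet suppress the log message.
#' @return the filtered [genotype_matrix()] with a `qc_log` attribute.
#' @export
filter_snps <- function(G, max_missing = 0.10, min_maf = 0.005,
                        min_hwe_p = 1e-10, quiet = FALSE) {
  if (!all(c("call_rate", "maf", "hwe_p") %in% names(G$map))) G <- snp_stats(G)
  miss <- 1 - G$map$call_rate
  fail_miss <- miss > max_missing
  fail_maf <- is.na(G$map$maf) | G$map$maf < min_maf
  fail_hwe <- is.na(G$map$hwe_p) | G$map$hwe_p < min_hwe_p
  keep <- !(fail_miss | fail_maf | fail_hwe)
  log <- list(n_input = n_snps(G),
              removed_missingness = sum(fail_miss),
              removed_maf = sum(fail_maf),
              removed_hwe = sum(fail_hwe),
              n_retained = sum(keep),
              thresholds = c(max_missing = max_missing, min_maf = min_maf,
                             min_hwe_p = min_hwe_p))
  if (!any(keep)) warning("no SNPs pass the filters")
  out <- subset_genotypes(G, snps = which(keep))
  if (!quiet)
    message(sprintf(
      "SNP QC: %d -> %d (failed missingness %d, MAF %d, HWE %d)",
      log$n_input, log$n_retained, log$removed_missingness,
      log$removed_maf, log$removed_hwe))
  attr(out, "qc_log") <- log
  out
}
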