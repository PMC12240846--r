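#' Derive a stage-specific seed from a global seed
#'
#' Fans a single global seed out to per-stage seeds so that pipeline stages
#' are independently reproducible. The derivation hashes the stage name into
#' an integer offset and folds it into the global seed modulo 2^31 - 1.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  codes <- utf8ToInt(stage)
  h <- 0
  for (k in codes) h <- (h * 31 + k) %% 2147483647
  as.integer((abs(seed) + h) %% 2147483647)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items.
#'
#' @param a,b label vectors of equal length.
#' @return numeric ARI in \[-1, 1\].
#' @export
ari <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(0)
  (sum_ij - expected) / (max_idx - expected)
}

# numerically safe -log10 of a p-value (caps at ~ 320 where double underflows)
neglog10 <- function(p) {
  out <- -log10(pmax(p, .Machine$double.xmin))
  out[is.na(p)] <- NA_real_
  out
}
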