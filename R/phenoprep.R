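#' Rank-based inverse-normal (quantile) transform
#'
#' Maps value i to `qnorm((r_i - offset) / (n + 1 - 2*offset))`, with `r_i`
#' the average rank among non-missing entries and `n` their count. The
#' default offset 3/8 is the Blom convention, giving denominator n + 1/4.
#' Missing values are preserved; an all-tied vector maps to zeros.
#'
#' @param values numeric vector, possibly with NA.
#' @param offset rank offset (Blom 3/8 by default).
#' @return transformed vector, same length and NA pattern.
#' @export
quantile_normalize <- function(values, offset = 3 / 8) {
  ok <- !is.na(values)
  if (sum(ok) < 2) stop("need at least 2 non-missing values")
  out <- rep(NA_real_, length(values))
  r <- rank(values[ok], ties.method = "average")
  n <- sum(ok)
  out[ok] <- stats::qnorm((r - offset) / (n + 1 - 2 * offset))
  out
}

#' Fraction of trait variance explained by one covariate
#'
#' R-squared of the univariate least-squares fit of the trait on the
#' covariate over pairwise-complete observations. Categorical covariates are
#' one-hot encoded and the R-squared is taken from the multi-column fit. A
#' constant covariate explains nothing (R-squared 0).
#'
#' @param trait numeric trait vector.
#' @param covariate numeric, factor or character covariate vector.
#' @return R-squared in \[0, 1\].
#' @export
covariate_variance_explained <- function(trait, covariate) {
  ok <- !is.na(trait) & !is.na(covariate)
  if (sum(ok) < 3) stop("need at least 3 paired non-missing observations")
  y <- trait[ok]
  x <- covariate[ok]
  if (length(unique(x)) < 2 || stats::var(y) == 0) return(0)
  if (is.character(x)) x <- factor(x)
  fit <- stats::lm(y ~ x)
  summary(fit)$r.squared
}

#' Prepare a trait for association analysis
#'
#' The two-site preparation scheme: within each site, covariates explaining
#' more than `r2_threshold` of the raw trait variance are regressed out, the
#' residuals are inverse-normal transformed; the per-site vectors are then
#' pooled and inverse-normal transformed once more so that the merged trait
#' is marginally Gaussian and the sites carry equal variance. Missing trait
#' values stay missing.
#'
#' @param table cohort data.frame with `id`, `site` and the columns named.
#' @param trait trait column name.
#' @param candidate_covariates character vector of covariate column names
#'   screened per site (e.g. sex, batch).
#' @param r2_threshold variance-explained screening threshold (default 0.02,
#'   i.e. "more than 2%"; strict inequality).
#' @param offset rank offset passed to [quantile_normalize()].
#' @return numeric vector of prepared values aligned to `table` rows, with a
#'   `provenance` attribute recording per-site covariate selections and
#'   sample sizes.
#' @export
prepare_trait <- function(table, trait, candidate_covariates = character(),
                          r2_threshold = 0.02, offset = 3 / 8) {
  stopifnot(trait %in% names(table), "site" %in% names(table))
  y_raw <- table[[trait]]
  out <- rep(NA_real_, nrow(table))
  prov <- list(trait = trait, r2_threshold = r2_threshold, sites = list())
  for (s in unique(table$site)) {
    rows <- which(table$site == s)
    ys <- y_raw[rows]
    n_ok <- sum(!is.na(ys))
    if (n_ok == 0) {
      prov$sites[[s]] <- list(n = 0, covariates = character(),
                              note = "all trait values missing; site skipped")
      next
    }
    if (n_ok < 10)
      warning("site ", s, " has fewer than 10 non-missing values for ", trait)
    selected <- character()
    for (cv in candidate_covariates) {
      x <- table[[cv]][rows]
      ok <- !is.na(ys) & !is.na(x)
      if (sum(ok) < 3 || length(unique(x[ok])) < 2) next
      if (covariate_variance_explained(ys, x) > r2_threshold)
        selected <- c(selected, cv)
    }
    resid <- ys
    if (length(selected)) {
      df <- data.frame(y = ys, table[rows, selected, drop = FALSE])
      fit <- stats::lm(y ~ ., data = df, na.action = stats::na.exclude)
      resid <- stats::residuals(fit)
    }
    out[rows] <- quantile_normalize(resid, offset = offset)
    prov$sites[[s]] <- list(n = n_ok, covariates = selected)
  }
  if (sum(!is.na(out)) >= 2) out <- quantile_normalize(out, offset = offset)
  attr(out, "provenance") <- prov
  out
}

#' Spearman correlation matrix over prepared traits
#'
#' Pairwise-complete Spearman rank correlations with two-sided p-values and
#' Bonferroni adjustment over all distinct trait pairs. Pairs with fewer than
#' 3 complete cases are marked missing.
#'
#' @param traits data.frame or matrix of trait columns.
#' @return list with matrices `rho`, `p`, `p_adj`, `n` and the pair count `m`.
#' @export
correlation_matrix <- function(traits) {
  traits <- as.data.frame(traits)
  p <- ncol(traits)
  if (p < 2) stop("need at least 2 traits")
  nm <- names(traits)
  rho <- pmat <- nmat <- matrix(NA_real_, p, p, dimnames = list(nm, nm))
  diag(rho) <- 1
  diag(pmat) <- 0
  m <- p * (p - 1) / 2
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    x <- traits[[i]]; y <- traits[[j]]
    ok <- !is.na(x) & !is.na(y)
    nmat[i, j] <- nmat[j, i] <- sum(ok)
    if (sum(ok) < 3) next
    ct <- suppressWarnings(
      stats::cor.test(x[ok], y[ok], method = "spearman", exact = FALSE))
    rho[i, j] <- rho[j, i] <- unname(ct$estimate)
    pmat[i, j] <- pmat[j, i] <- ct$p.value
  }
  p_adj <- pmat
  p_adj[] <- pmin(1, pmat * m)
  diag(p_adj) <- 0
  diag(nmat) <- colSums(!is.na(traits))
  list(rho = rho, p = pmat, p_adj = p_adj, n = nmat, m = m)
}

#' Principal components with varimax rotation
#'
#' Eigendecomposition of the trait correlation matrix over complete cases;
#' components with eigenvalue >= 1 are retained (Kaiser criterion) and their
#' loadings varimax-rotated (with Kaiser normalization). Loadings are
#' displayed where |loading| >= `loading_threshold`.
#'
#' @param traits data.frame or matrix of trait columns.
#' @param loading_threshold display mask threshold (default 0.3).
#' @return list with `eigenvalues`, `n_retained`, `loadings` (rotated),
#'   `mask` (logical |loading| >= threshold), `n_used`.
#' @export
pca_varimax <- function(traits, loading_threshold = 0.3) {
  X <- as.matrix(as.data.frame(traits))
  X <- X[stats::complete.cases(X), , drop = FALSE]
  if (nrow(X) <= ncol(X)) stop("need more complete cases than traits")
  R <- stats::cor(X)
  eig <- eigen(R, symmetric = TRUE)
  keep <- which(eig$values >= 1)
  if (!length(keep)) {
    warning("no component has eigenvalue >= 1")
    return(list(eigenvalues = eig$values, n_retained = 0L,
                loadings = NULL, mask = NULL, n_used = nrow(X)))
  }
  L <- eig$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(eig$values[keep]), length(keep))
  rownames(L) <- colnames(X)
  if (length(keep) > 1) L <- varimax_multistart(L)
  colnames(L) <- paste0("PC", seq_along(keep))
  list(eigenvalues = eig$values, n_retained = length(keep), loadings = L,
       mask = abs(L) >= loading_threshold, n_used = nrow(X))
}

# stats::varimax can stall in a poor local optimum when the unrotated
# loadings sit symmetrically between simple structures; restart it from a
# fixed set of deterministic orthogonal rotations and keep the solution with
# the largest (Kaiser-normalized) varimax criterion.
varimax_multistart <- function(L, n_starts = 10) {
  k <- ncol(L)
  h <- sqrt(rowSums(L^2))
  h[h == 0] <- 1
  crit <- function(M) sum(apply((M / h)^2, 2, stats::var))
  best <- L; best_c <- -Inf
  for (r in seq_len(n_starts)) {
    Rs <- if (r == 1) diag(k)
          else qr.Q(qr(matrix(sin(seq_len(k * k) * r * 1.7 + r), k, k)))
    cand <- tryCatch(
      unclass(stats::varimax(L %*% Rs, normalize = TRUE)$loadings),
      error = function(e) NULL)
    if (is.null(cand)) next
    cc <- crit(cand)
    if (cc > best_c) { best_c <- cc; best <- cand }
  }
  dimnames(best) <- dimnames(L)
  best
}
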