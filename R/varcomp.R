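#' Genetic relatedness matrix from SNP dosages
#'
#' GCTA-style GRM: `A_jk = (1/m) * sum_i (x_ij - 2 p_i)(x_ik - 2 p_i) /
#' (2 p_i (1 - p_i))`, i.e. the cross-product of per-SNP standardized
#' dosages divided by the number of SNPs used. Missing dosages are
#' mean-imputed per SNP; monomorphic SNPs are skipped.
#'
#' @param G a [genotype_matrix()].
#' @param exclude_chrom chromosome label(s) to leave out (or NULL for the
#'   full GRM).
#' @return a `grm` object: list with `A` (n x n symmetric), `ids`, `n_snps`,
#'   `excluded_chrom`.
#' @export
compute_grm <- function(G, exclude_chrom = NULL) {
  keep <- rep(TRUE, n_snps(G))
  if (!is.null(exclude_chrom)) keep <- !(G$map$chrom %in% exclude_chrom)
  if (!any(keep)) stop("all SNPs excluded from the GRM")
  d <- impute_dosage(G$dosage[, keep, drop = FALSE])
  p <- colMeans(d) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic SNPs available for the GRM")
  d <- d[, poly, drop = FALSE]
  p <- p[poly]
  Z <- sweep(d, 2, 2 * p) %*% diag(1 / sqrt(2 * p * (1 - p)), sum(poly))
  m <- ncol(Z)
  structure(list(A = tcrossprod(Z) / m, ids = G$ids, n_snps = m,
                 excluded_chrom = exclude_chrom),
            class = "grm")
}

#' Leave-one-chromosome-out GRMs
#'
#' One GRM per chromosome, each built from all SNPs *except* that
#' chromosome's, so that the polygenic term of a mixed-model scan never
#' absorbs the tested SNP (proximal contamination). The SNP-count-weighted
#' average of the LOCO GRMs reconstructs the full GRM.
#'
#' @param G a [genotype_matrix()] with at least 2 chromosomes.
#' @return list with `full` (the all-SNP `grm`) and `loco` (named list of
#'   `grm`, one per chromosome).
#' @export
compute_loco_grms <- function(G) {
  chroms <- unique(G$map$chrom)
  if (length(chroms) < 2)
    stop("LOCO needs >= 2 chromosomes; use compute_grm() for a full GRM")
  d <- impute_dosage(G$dosage)
  p <- colMeans(d) / 2
  parts <- list()
  counts <- integer(0)
  for (ch in chroms) {
    j <- which(G$map$chrom == ch & p > 0 & p < 1)
    counts[ch] <- length(j)
    if (!length(j)) { parts[[ch]] <- NULL; next }
    Z <- sweep(d[, j, drop = FALSE], 2, 2 * p[j]) %*%
      diag(1 / sqrt(2 * p[j] * (1 - p[j])), length(j))
    parts[[ch]] <- tcrossprod(Z)
  }
  total <- Reduce(`+`, parts)
  m_total <- sum(counts)
  full <- structure(list(A = total / m_total, ids = G$ids, n_snps = m_total,
                         excluded_chrom = NULL), class = "grm")
  loco <- lapply(chroms, function(ch) {
    m_c <- counts[[ch]]
    if (m_total - m_c == 0) stop("excluding ", ch, " leaves no SNPs")
    S <- if (m_c > 0) total - parts[[ch]] else total
    structure(list(A = S / (m_total - m_c), ids = G$ids,
                   n_snps = m_total - m_c, excluded_chrom = ch),
              class = "grm")
  })
  names(loco) <- chroms
  list(full = full, loco = loco)
}

#' Write / read a GRM as TSV (plain-text GCTA-like triplet layout)
#'
#' Lower-triangle triplet table `i j n_snps value` plus an id file, the
#' plain-text sibling of GCTA's grm.bin dialect.
#'
#' @param grm a `grm` object.
#' @param prefix output prefix; writes `prefix.grm.tsv` and `prefix.grm.id`.
#' @return the prefix (write) or a `grm` (read), invisibly.
#' @export
write_grm_tsv <- function(grm, prefix) {
  n <- length(grm$ids)
  idx <- which(lower.tri(grm$A, diag = TRUE), arr.ind = TRUE)
  df <- data.frame(i = idx[, 1], j = idx[, 2], n_snps = grm$n_snps,
                   value = grm$A[idx])
  data.table::fwrite(df, paste0(prefix, ".grm.tsv"), sep = "\t")
  writeLines(grm$ids, paste0(prefix, ".grm.id"))
  invisible(prefix)
}

#' @rdname write_grm_tsv
#' @export
read_grm_tsv <- function(prefix) {
  df <- data.table::fread(paste0(prefix, ".grm.tsv"), data.table = FALSE)
  ids <- readLines(paste0(prefix, ".grm.id"))
  n <- length(ids)
  A <- matrix(0, n, n)
  A[cbind(df$i, df$j)] <- df$value
  A[cbind(df$j, df$i)] <- df$value
  structure(list(A = A, ids = ids, n_snps = df$n_snps[1],
                 excluded_chrom = NULL), class = "grm")
}

# ---- AI-REML core ----------------------------------------------------------
# Works in the eigenbasis of the GRM: with A = U diag(d) U', the model
# y = X b + g + e has V = sg * A + se * I, so in rotated coordinates
# (yt = U'y, Xt = U'X) V is diagonal with entries sg*d + se and every REML
# quantity costs O(n p^2) per iteration. Average-Information updates with EM
# fallback steps; components clamped at a small floor (active set at zero).
aireml_rotated <- function(yt, Xt, d, max_iter = 100, tol = 1e-6,
                           init = NULL) {
  n <- length(yt)
  p <- ncol(Xt)
  vp <- stats::var(yt)
  floor_v <- 1e-6 * vp
  th <- if (is.null(init)) c(g = vp / 2, e = vp / 2) else init

  quantities <- function(th) {
    v <- th[1] * d + th[2]
    vi <- 1 / v
    XtVi <- Xt * vi
    XtVX <- crossprod(Xt, XtVi)
    C <- solve(XtVX)
    Pz <- function(z) vi * z - XtVi %*% (C %*% crossprod(Xt, vi * z))
    Py <- drop(Pz(yt))
    llik <- -0.5 * (sum(log(v)) + determinant(XtVX)$modulus[1] +
                      sum(yt * Py))
    trPK <- function(k) {
      M <- crossprod(Xt, Xt * (k * vi * vi))
      sum(k * vi) - sum(C * t(M))
    }
    list(v = v, Py = Py, Pz = Pz, llik = llik, trPK = trPK)
  }

  em_step <- function(th, q) {
    yPKPy_g <- sum(d * q$Py^2)
    yPKPy_e <- sum(q$Py^2)
    c(g = th[1] + th[1]^2 * (yPKPy_g - q$trPK(d)) / n,
      e = th[2] + th[2]^2 * (yPKPy_e - q$trPK(rep(1, n))) / n)
  }

  q <- quantities(th)
  llik <- q$llik
  converged <- FALSE
  iter <- 0
  grad <- c(NA_real_, NA_real_)
  AI <- matrix(NA_real_, 2, 2)
  for (iter in seq_len(max_iter)) {
    KPy_g <- d * q$Py
    KPy_e <- q$Py
    PKPy_g <- drop(q$Pz(KPy_g))
    PKPy_e <- drop(q$Pz(KPy_e))
    grad <- -0.5 * c(q$trPK(d) - sum(KPy_g * q$Py),
                     q$trPK(rep(1, length(q$Py))) - sum(KPy_e * q$Py))
    AI <- 0.5 * matrix(c(sum(KPy_g * PKPy_g), sum(KPy_g * PKPy_e),
                         sum(KPy_e * PKPy_g), sum(KPy_e * PKPy_e)), 2, 2)
    step <- tryCatch(solve(AI, grad), error = function(e) NULL)
    th_new <- if (is.null(step)) NULL else th + step
    accept <- FALSE
    if (!is.null(th_new) && all(is.finite(th_new)) && all(th_new > 0)) {
      q_new <- quantities(pmax(th_new, floor_v))
      if (is.finite(q_new$llik) && q_new$llik >= llik - 1e-10) accept <- TRUE
    }
    if (!accept) {           # EM fallback: guaranteed uphill, slower
      th_new <- pmax(em_step(th, q), floor_v)
      q_new <- quantities(th_new)
    }
    th <- pmax(th_new, floor_v)
    delta <- q_new$llik - llik
    q <- q_new
    llik <- q$llik
    if (abs(delta) < tol) { converged <- TRUE; break }
  }
  # polish: 1-D profile-REML refinement in h2 = sg / (sg + se), with the
  # total variance profiled out in closed form. The AI iterations get close
  # fast; this pins the optimum to high precision even where the
  # log-likelihood is nearly flat.
  prof <- profile_reml_h2(yt, Xt, d)
  if (prof$llik >= llik - 1e-10) {
    th <- c(g = prof$s2 * prof$h2, e = prof$s2 * (1 - prof$h2))
    llik <- prof$llik
    converged <- TRUE
  }
  # active set: a component resting on the floor is reported as zero
  th_out <- th
  th_out[th <= floor_v * 1.0001] <- 0
  list(sigma2_g = unname(th_out[1]), sigma2_e = unname(th_out[2]),
       llik = llik, iterations = iter, converged = converged,
       grad_norm = sqrt(sum(grad^2)), AI = AI)
}

# profile REML log-likelihood over the heritability ratio, rotated basis
profile_reml_h2 <- function(yt, Xt, d) {
  n <- length(yt); p <- ncol(Xt)
  ll <- function(h2) {
    v0 <- h2 * d + (1 - h2)
    if (any(v0 <= 0)) return(-Inf)
    vi <- 1 / v0
    XtViX <- crossprod(Xt, Xt * vi)
    C <- tryCatch(solve(XtViX), error = function(e) NULL)
    if (is.null(C)) return(-Inf)
    Py0 <- vi * yt - (Xt * vi) %*% (C %*% crossprod(Xt, vi * yt))
    s2 <- sum(yt * Py0) / (n - p)
    -0.5 * (sum(log(v0)) + (n - p) * log(s2) +
              determinant(XtViX)$modulus[1] + (n - p))
  }
  opt <- stats::optimize(ll, c(0, 1 - 1e-9), maximum = TRUE, tol = 1e-10)
  h2 <- opt$maximum
  # the boundary h2 = 0 can beat an interior local optimum
  if (ll(0) >= opt$objective) h2 <- 0
  v0 <- h2 * d + (1 - h2)
  vi <- 1 / v0
  XtViX <- crossprod(Xt, Xt * vi)
  C <- solve(XtViX)
  Py0 <- vi * yt - (Xt * vi) %*% (C %*% crossprod(Xt, vi * yt))
  s2 <- max(sum(yt * Py0) / (n - p), .Machine$double.eps)
  list(h2 = h2, s2 = s2, llik = ll(h2))
}

# REML log-likelihood of the sigma2_g = 0 null (same constant convention)
null_reml_llik <- function(y, X) {
  qrX <- qr(X)
  res <- qr.resid(qrX, y)
  n <- length(y); p <- ncol(X)
  s2 <- sum(res^2) / (n - p)
  ldXX <- determinant(crossprod(X))$modulus[1]
  list(llik = -0.5 * ((n - p) * log(s2) + ldXX + (n - p)), sigma2_e = s2)
}

#' Precompute and cache a GRM's eigendecomposition
#'
#' [fit_greml()] works in the GRM's eigenbasis; when many traits (or many
#' simulated replicates) are fitted against one GRM, caching the
#' decomposition once avoids repeating the O(n^3) step. The cache is only
#' used when the fit runs on the full id set (no incomplete cases).
#'
#' @param grm a `grm` object.
#' @return the same `grm` with an `eigen` attribute.
#' @export
cache_grm_eigen <- function(grm) {
  attr(grm, "eigen") <- eigen(grm$A, symmetric = TRUE)
  grm
}

#' SNP heritability by AI-REML (single-GRM GREML)
#'
#' Fits `y = X b + g + e` with `g ~ N(0, sigma2_g A)` and
#' `e ~ N(0, sigma2_e I)` by restricted maximum likelihood using
#' Average-Information updates with EM fallback steps, variance components
#' constrained nonnegative. Reports `h2 = sigma2_g / (sigma2_g + sigma2_e)`
#' with a delta-method standard error from the inverse AI matrix, and a
#' likelihood-ratio test against `h2 = 0` referred to the boundary
#' 0.5 chi^2_0 + 0.5 chi^2_1 mixture.
#'
#' @param y numeric phenotype vector (NAs dropped as incomplete cases).
#' @param grm a `grm` from [compute_grm()] whose ids align with `y` (y must
#'   be ordered like `grm$ids`).
#' @param covariates optional numeric matrix / data.frame of fixed-effect
#'   covariates (an intercept is always included).
#' @param max_iter,tol convergence controls (log-likelihood change < tol).
#' @return a `varcomp_fit` list: `sigma2_g`, `sigma2_e`, `h2`, `se_h2`,
#'   `log_likelihood`, `null_log_likelihood`, `lrt`, `lrt_p`, `n`,
#'   `converged`, `iterations`, `grad_norm`, `note`.
#' @export
fit_greml <- function(y, grm, covariates = NULL, max_iter = 100, tol = 1e-6) {
  stopifnot(inherits(grm, "grm"), length(y) == length(grm$ids))
  X <- cbind(intercept = rep(1, length(y)))
  if (!is.null(covariates)) {
    cv <- as.data.frame(covariates)
    mm <- stats::model.matrix(~ ., data = cv)
    X <- mm  # model.matrix already carries the intercept
  }
  ok <- !is.na(y) & stats::complete.cases(X)
  y0 <- y[ok]; X0 <- X[ok, , drop = FALSE]; A <- grm$A[ok, ok]
  n <- length(y0)
  if (qr(X0)$rank < ncol(X0)) stop("singular covariate design")
  if (n <= ncol(X0) + 2) stop("too few complete cases")
  eig <- attr(grm, "eigen")
  if (is.null(eig) || !all(ok)) eig <- eigen(A, symmetric = TRUE)
  note <- character()
  if (stats::sd(eig$values) < 1e-8)
    note <- c(note, "GRM is (near) identity: sigma2_g and sigma2_e are not separately identifiable")
  yt <- drop(crossprod(eig$vectors, y0))
  Xt <- crossprod(eig$vectors, X0)
  fit <- aireml_rotated(yt, Xt, eig$values, max_iter = max_iter, tol = tol)
  if (!fit$converged) note <- c(note, "REML did not converge")
  null <- null_reml_llik(y0, X0)
  lrt <- max(0, 2 * (fit$llik - null$llik))
  lrt_p <- if (lrt <= 0) 1 else 0.5 * stats::pchisq(lrt, 1, lower.tail = FALSE)
  s <- fit$sigma2_g + fit$sigma2_e
  h2 <- if (s > 0) fit$sigma2_g / s else 0
  se_h2 <- NA_real_
  Cai <- tryCatch(solve(fit$AI), error = function(e) NULL)
  if (!is.null(Cai) && all(is.finite(Cai))) {
    gr <- c(fit$sigma2_e, -fit$sigma2_g) / s^2
    v <- drop(t(gr) %*% Cai %*% gr)
    if (is.finite(v) && v >= 0) se_h2 <- sqrt(v)
  }
  structure(list(sigma2_g = fit$sigma2_g, sigma2_e = fit$sigma2_e, h2 = h2,
                 se_h2 = se_h2, log_likelihood = fit$llik,
                 null_log_likelihood = null$llik, lrt = lrt, lrt_p = lrt_p,
                 n = n, converged = fit$converged, iterations = fit$iterations,
                 grad_norm = fit$grad_norm, note = note),
            class = "varcomp_fit")
}

#' @export
print.varcomp_fit <- function(x, ...) {
  cat(sprintf("GREML fit (n = %d): h2 = %.3f (SE %.3f), LRT p = %.3g\n",
              x$n, x$h2, x$se_h2, x$lrt_p))
  cat(sprintf("  sigma2_g = %.4f, sigma2_e = %.4f, %d iterations%s\n",
              x$sigma2_g, x$sigma2_e, x$iterations,
              if (x$converged) "" else " (NOT converged)"))
  if (length(x$note)) cat("  note:", paste(x$note, collapse = "; "), "\n")
  invisible(x)
}
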