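# Mixed-model association machinery. The per-chromosome strategy follows the
# MLMA-LOCO convention: variance components are estimated once per left-out
# chromosome under that chromosome's LOCO GRM and then held fixed across the
# chromosome's SNPs; each SNP is tested by generalized least squares in the
# whitened model, with the residual scale re-estimated per SNP so the test is
# a t-test with df = n - p - 1. In the sigma2_g = 0 limit the whitening is a
# scalar and every statistic reduces exactly to ordinary least squares.

# builds the design matrix: intercept + covariates + conditioning dosages
scan_design <- function(n, covariates = NULL, cond_dosage = NULL) {
  X <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  if (!is.null(covariates)) {
    cv <- as.data.frame(covariates)
    X <- stats::model.matrix(~ ., data = cv)
  }
  if (!is.null(cond_dosage)) X <- cbind(X, cond_dosage)
  X
}

# per-chromosome rotations that do not depend on the phenotype: eigen of the
# LOCO GRM, rotated genotypes and rotated design. Reused across permutations.
scan_prep <- function(G, loco_grms, covariates = NULL,
                      conditioning_snps = character()) {
  n <- n_individuals(G)
  cond <- NULL
  if (length(conditioning_snps)) {
    cond <- impute_dosage(
      G$dosage[, match(conditioning_snps, G$map$id), drop = FALSE])
    colnames(cond) <- paste0("cond_", conditioning_snps)
  }
  X <- scan_design(n, covariates, cond)
  if (qr(X)$rank < ncol(X)) stop("singular covariate/conditioning design")
  dos <- impute_dosage(G$dosage)
  chroms <- intersect(unique(G$map$chrom), names(loco_grms))
  if (!length(chroms)) stop("loco_grms has no entry for any chromosome in G")
  prep <- lapply(chroms, function(ch) {
    idx <- which(G$map$chrom == ch)
    grm <- loco_grms[[ch]]
    stopifnot(inherits(grm, "grm"), identical(grm$ids, G$ids))
    eig <- eigen(grm$A, symmetric = TRUE)
    list(chrom = ch, idx = idx, d = eig$values, U = eig$vectors,
         Gt = crossprod(eig$vectors, dos[, idx, drop = FALSE]),
         Xt = crossprod(eig$vectors, X))
  })
  names(prep) <- chroms
  list(chrom_prep = prep, X = X, map = G$map, n = n)
}

# scan a prepared cohort for one phenotype vector (complete, aligned)
scan_with_y <- function(prep, y, var_components = NULL) {
  n <- prep$n
  p <- ncol(prep$X)
  out <- data.frame(id = prep$map$id, chrom = prep$map$chrom,
                    pos = prep$map$pos, effect = NA_real_, se = NA_real_,
                    neglog10_p = NA_real_, stringsAsFactors = FALSE)
  vc_used <- list()
  for (cp in prep$chrom_prep) {
    yt <- drop(crossprod(cp$U, y))
    if (is.null(var_components)) {
      fit <- aireml_rotated(yt, cp$Xt, cp$d)
      vc <- c(g = fit$sigma2_g, e = fit$sigma2_e)
    } else vc <- c(g = var_components$sigma2_g, e = var_components$sigma2_e)
    vc_used[[cp$chrom]] <- vc
    w <- 1 / sqrt(pmax(vc["g"] * cp$d + vc["e"], 1e-12))
    ys <- yt * w
    Xs <- cp$Xt * w
    Gs <- cp$Gt * w
    Q <- qr.Q(qr(Xs))
    ry <- ys - Q %*% crossprod(Q, ys)
    RG <- Gs - Q %*% crossprod(Q, Gs)
    ss <- colSums(RG^2)
    testable <- ss > 1e-8 * n
    b <- se <- tstat <- rep(NA_real_, length(ss))
    df <- n - p - 1
    sy <- colSums(RG * drop(ry))
    b[testable] <- sy[testable] / ss[testable]
    rss <- sum(ry^2) - b^2 * ss
    s2 <- pmax(rss, 0) / df
    se[testable] <- sqrt(s2[testable] / ss[testable])
    tstat <- b / se
    pv <- 2 * stats::pt(-abs(tstat), df)
    out$effect[cp$idx] <- b
    out$se[cp$idx] <- se
    out$neglog10_p[cp$idx] <- neglog10(pv)
  }
  attr(out, "var_components") <- vc_used
  out
}

#' LOCO mixed-model association scan
#'
#' For each SNP on chromosome c, tests the SNP's additive fixed effect in the
#' model `y = X b + s beta + g + e`, `g ~ N(0, sigma2_g A_loco(c))`, with the
#' variance components estimated once per left-out chromosome by AI-REML and
#' held fixed across that chromosome's SNPs. Conditioning SNP dosages enter
#' the design as fixed covariates. SNPs collinear with the design (including
#' the conditioning SNPs themselves) are marked untestable (NA).
#'
#' @param y numeric phenotype aligned with `G$ids`; NAs are dropped as
#'   incomplete cases.
#' @param G a filtered [genotype_matrix()].
#' @param loco_grms named list of per-chromosome `grm` objects (the `loco`
#'   element of [compute_loco_grms()]).
#' @param covariates optional data.frame/matrix of fixed covariates.
#' @param conditioning_snps character vector of SNP ids to condition on.
#' @param var_components optional `list(sigma2_g =, sigma2_e =)` overriding
#'   REML estimation (applied to every chromosome).
#' @param trait trait name recorded on the result.
#' @return a `scan_result` data.frame: `id`, `chrom`, `pos`, `effect`, `se`,
#'   `neglog10_p`, sorted by (chrom, pos), with attributes `trait`,
#'   `conditioning_snps` and per-chromosome `var_components`.
#' @export
assoc_scan <- function(y, G, loco_grms, covariates = NULL,
                       conditioning_snps = character(),
                       var_components = NULL, trait = "trait") {
  ok <- !is.na(y)
  if (!is.null(covariates))
    ok <- ok & stats::complete.cases(as.data.frame(covariates))
  if (!all(ok)) {
    G <- subset_genotypes(G, individuals = which(ok))
    loco_grms <- lapply(loco_grms, function(g) {
      g$A <- g$A[ok, ok]; g$ids <- g$ids[ok]; g
    })
    if (!is.null(covariates))
      covariates <- as.data.frame(covariates)[ok, , drop = FALSE]
    y <- y[ok]
  }
  prep <- scan_prep(G, loco_grms, covariates, conditioning_snps)
  out <- scan_with_y(prep, y, var_components)
  attr(out, "trait") <- trait
  attr(out, "conditioning_snps") <- conditioning_snps
  class(out) <- c("scan_result", class(out))
  out
}

#' Permutation-derived genome-wide significance threshold
#'
#' Shuffles the prepared phenotype across individuals (relatedness ignored,
#' which the within-site inverse-normal preparation is argued to justify),
#' reruns the full LOCO scan per permutation, and takes the empirical
#' (1 - alpha) quantile (linear interpolation, R quantile type 7) of the
#' genome-wide maximum -log10 p values.
#'
#' @param y prepared phenotype aligned with `G$ids`.
#' @param G filtered [genotype_matrix()].
#' @param loco_grms named list of per-chromosome `grm` objects.
#' @param n_perm number of permutations (>= 20).
#' @param alpha family-wise error target (default 0.05).
#' @param seed integer seed for the shuffles.
#' @param covariates optional fixed covariates (kept fixed; only y is
#'   shuffled).
#' @return a `significance_threshold` list: `alpha`, `n_perm`, `value`
#'   (-log10 p scale), `maxima` (the per-permutation maxima), `seed`.
#' @export
permutation_threshold <- function(y, G, loco_grms, n_perm = 100,
                                  alpha = 0.05, seed = 1L,
                                  covariates = NULL) {
  if (n_perm < 20) stop("n_perm must be >= 20")
  if (n_perm * alpha < 1)
    warning(sprintf(
      "n_perm = %d cannot resolve alpha = %g; smallest achievable alpha is %g",
      n_perm, alpha, 1 / n_perm))
  ok <- !is.na(y)
  if (!all(ok)) {
    G <- subset_genotypes(G, individuals = which(ok))
    loco_grms <- lapply(loco_grms, function(g) {
      g$A <- g$A[ok, ok]; g$ids <- g$ids[ok]; g
    })
    if (!is.null(covariates))
      covariates <- as.data.frame(covariates)[ok, , drop = FALSE]
    y <- y[ok]
  }
  prep <- scan_prep(G, loco_grms, covariates)
  set.seed(seed)
  maxima <- vapply(seq_len(n_perm), function(b) {
    res <- scan_with_y(prep, y[sample.int(length(y))])
    max(res$neglog10_p, na.rm = TRUE)
  }, 0)
  structure(list(alpha = alpha, n_perm = n_perm,
                 value = unname(stats::quantile(maxima, 1 - alpha, type = 7)),
                 maxima = maxima, seed = seed),
            class = "significance_threshold")
}

#' Linkage-disequilibrium r-squared between two SNPs
#'
#' Squared Pearson correlation of the dosage vectors over pairwise-complete
#' individuals. Undefined (NA) when either SNP is monomorphic among the
#' complete pairs or fewer than 3 pairs exist.
#'
#' @param G a [genotype_matrix()].
#' @param snp_a,snp_b SNP ids.
#' @return r-squared in \[0, 1\] or NA.
#' @export
ld_r2 <- function(G, snp_a, snp_b) {
  a <- snp_dosage(G, snp_a)
  b <- snp_dosage(G, snp_b)
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 3) return(NA_real_)
  if (stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) return(NA_real_)
  stats::cor(a[ok], b[ok])^2
}

# r2 of many SNPs against one peak (vectorized; NA where undefined)
ld_r2_vec <- function(dos_mat, peak) {
  apply(dos_mat, 2, function(x) {
    ok <- !is.na(x) & !is.na(peak)
    if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(peak[ok]) == 0)
      return(NA_real_)
    stats::cor(x[ok], peak[ok])^2
  })
}

#' Call candidate QTL peaks from a scan
#'
#' Among SNPs exceeding the significance threshold, the most significant SNP
#' per chromosome is a candidate peak; it is reported only if at least one
#' *other* SNP lies within `support_window` bp and has -log10 p no more than
#' `support_delta` units below the peak (both bounds inclusive). Ties on
#' -log10 p are broken by lower bp, then lexicographic SNP id.
#'
#' @param scan a `scan_result` from [assoc_scan()].
#' @param threshold numeric -log10 p threshold (or a `significance_threshold`).
#' @param support_window support search radius in bp (default 500000).
#' @param support_delta support significance margin in -log10 units
#'   (default 2).
#' @return data.frame of peaks: `chrom`, `id`, `pos`, `neglog10_p`,
#'   `n_support` (possibly zero rows).
#' @export
call_qtls <- function(scan, threshold, support_window = 5e5,
                      support_delta = 2.0) {
  if (inherits(threshold, "significance_threshold")) threshold <- threshold$value
  hits <- scan[!is.na(scan$neglog10_p) & scan$neglog10_p > threshold, ,
               drop = FALSE]
  peaks <- list()
  for (ch in unique(hits$chrom)) {
    sub <- hits[hits$chrom == ch, , drop = FALSE]
    sub <- sub[order(-sub$neglog10_p, sub$pos, sub$id), , drop = FALSE]
    peak <- sub[1, ]
    allch <- scan[scan$chrom == ch & !is.na(scan$neglog10_p), , drop = FALSE]
    support <- allch$id != peak$id &
      abs(allch$pos - peak$pos) <= support_window &
      allch$neglog10_p >= peak$neglog10_p - support_delta
    if (sum(support) >= 1)
      peaks[[ch]] <- data.frame(chrom = ch, id = peak$id, pos = peak$pos,
                                neglog10_p = peak$neglog10_p,
                                n_support = sum(support),
                                stringsAsFactors = FALSE)
  }
  if (!length(peaks))
    return(data.frame(chrom = character(), id = character(), pos = integer(),
                      neglog10_p = numeric(), n_support = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, peaks)
  rownames(out) <- NULL
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' LD-defined QTL interval around a peak SNP
#'
#' The interval spans from the leftmost to the rightmost SNP within
#' `search_window` bp of the peak whose r-squared with the peak is at least
#' `r2_min`. The peak always qualifies (r-squared 1 with itself), so the
#' interval always contains it; contiguity is not required (an isolated
#' distal SNP in strong LD extends the interval).
#'
#' @param G a [genotype_matrix()].
#' @param peak_snp peak SNP id.
#' @param r2_min LD threshold (default 0.6).
#' @param search_window search radius in bp (default 10 Mb).
#' @return closed interval `c(start_bp, end_bp)`.
#' @export
qtl_interval <- function(G, peak_snp, r2_min = 0.6, search_window = 1e7) {
  j <- match(peak_snp, G$map$id)
  if (is.na(j)) stop("peak SNP not found: ", peak_snp)
  ch <- G$map$chrom[j]; ppos <- G$map$pos[j]
  cand <- which(G$map$chrom == ch & abs(G$map$pos - ppos) <= search_window)
  r2 <- ld_r2_vec(G$dosage[, cand, drop = FALSE], G$dosage[, j])
  qual <- cand[!is.na(r2) & r2 >= r2_min]
  qual <- union(qual, j)
  c(start_bp = min(G$map$pos[qual]), end_bp = max(G$map$pos[qual]))
}

#' Iterative conditional mapping of QTLs
#'
#' Per chromosome: call the peak, add its dosage as a fixed covariate,
#' re-scan that chromosome, and repeat until no SNP passes the threshold plus
#' support rule. Each QTL records the conditioning round at which it was
#' found (0 = unconditional) and its LD interval.
#'
#' @inheritParams assoc_scan
#' @param threshold -log10 p threshold (or `significance_threshold`).
#' @param scan optional precomputed unconditional `scan_result`.
#' @param support_window,support_delta passed to [call_qtls()].
#' @param r2_min,search_window passed to [qtl_interval()].
#' @param max_rounds safety cap per chromosome (default 10).
#' @return data.frame of QTLs: `trait`, `chrom`, `id`, `pos`, `neglog10_p`,
#'   `n_support`, `interval_start_bp`, `interval_end_bp`,
#'   `conditioning_round`.
#' @export
iterative_conditional_mapping <- function(y, G, loco_grms, threshold,
                                          covariates = NULL, scan = NULL,
                                          support_window = 5e5,
                                          support_delta = 2.0,
                                          r2_min = 0.6, search_window = 1e7,
                                          max_rounds = 10,
                                          trait = "trait") {
  if (inherits(threshold, "significance_threshold")) threshold <- threshold$value
  if (is.null(scan))
    scan <- assoc_scan(y, G, loco_grms, covariates, trait = trait)
  qtls <- list()
  for (ch in unique(scan$chrom)) {
    records <- scan[scan$chrom == ch, , drop = FALSE]
    conditioning <- character()
    round <- 0L
    repeat {
      peaks <- call_qtls(records, threshold, support_window, support_delta)
      if (nrow(peaks) == 0) break
      if (round >= max_rounds)
        stop("conditional mapping exceeded ", max_rounds, " rounds on ", ch,
             "; suspect collinearity among conditioning SNPs")
      iv <- qtl_interval(G, peaks$id[1], r2_min, search_window)
      qtls[[length(qtls) + 1L]] <- data.frame(
        trait = trait, chrom = ch, id = peaks$id[1], pos = peaks$pos[1],
        neglog10_p = peaks$neglog10_p[1], n_support = peaks$n_support[1],
        interval_start_bp = unname(iv[1]), interval_end_bp = unname(iv[2]),
        conditioning_round = round, stringsAsFactors = FALSE)
      conditioning <- c(conditioning, peaks$id[1])
      round <- round + 1L
      Gc <- subset_genotypes(G, snps = which(G$map$chrom == ch))
      records <- assoc_scan(y, Gc, loco_grms[ch], covariates,
                            conditioning_snps = conditioning, trait = trait)
    }
  }
  if (!length(qtls))
    return(data.frame(trait = character(), chrom = character(),
                      id = character(), pos = integer(),
                      neglog10_p = numeric(), n_support = integer(),
                      interval_start_bp = integer(),
                      interval_end_bp = integer(),
                      conditioning_round = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, qtls)
  rownames(out) <- NULL
  out
}

#' Colocate a QTL peak with expression/coding annotations
#'
#' For each annotation SNP (eQTL, sQTL or coding variant) within `window` bp
#' of the peak, reports its LD r-squared with the peak and flags strong LD
#' (r-squared >= 0.6, the interval convention). Annotation SNPs absent from
#' the genotypes are emitted with r-squared undefined-marked (NA).
#'
#' @param peak one-row data.frame (or list) with `chrom`, `id`, `pos` of the
#'   peak SNP.
#' @param annotation data.frame with columns `feature_id`, `tissue`,
#'   `modality` (eQTL/sQTL/coding), `snp_id`, `chrom`, `pos`.
#' @param G a [genotype_matrix()] for LD computation.
#' @param window colocation window in bp (default 3 Mb).
#' @return data.frame of colocation records with `r2`, `distance_bp`,
#'   `strong_ld`.
#' @export
colocate <- function(peak, annotation, G, window = 3e6) {
  keep <- annotation$chrom == peak$chrom &
    abs(annotation$pos - peak$pos) <= window
  ann <- annotation[keep, , drop = FALSE]
  if (!nrow(ann))
    return(cbind(ann, r2 = numeric(0), distance_bp = integer(0),
                 strong_ld = logical(0)))
  ann$r2 <- vapply(ann$snp_id, function(s) {
    if (!s %in% G$map$id) return(NA_real_)
    ld_r2(G, peak$id, s)
  }, 0)
  ann$distance_bp <- abs(ann$pos - peak$pos)
  ann$strong_ld <- !is.na(ann$r2) & ann$r2 >= 0.6
  rownames(ann) <- NULL
  ann[order(-ifelse(is.na(ann$r2), -1, ann$r2)), , drop = FALSE]
}

#' Phenome-wide lookup of one SNP across trait scans
#'
#' Extracts the peak SNP's association record from every supplied scan,
#' sorted by decreasing significance. Scans lacking the SNP contribute an
#' undefined-marked row.
#'
#' @param peak_snp SNP id.
#' @param other_scans named list of `scan_result` objects (names = traits; an
#'   unnamed list falls back to each scan's `trait` attribute).
#' @return data.frame with `trait`, `neglog10_p`, `effect`, `se`.
#' @export
phewas_lookup <- function(peak_snp, other_scans) {
  nms <- names(other_scans)
  if (is.null(nms))
    nms <- vapply(other_scans, function(s) {
      t <- attr(s, "trait"); if (is.null(t)) NA_character_ else t
    }, "")
  rows <- lapply(seq_along(other_scans), function(i) {
    s <- other_scans[[i]]
    j <- match(peak_snp, s$id)
    if (is.na(j))
      return(data.frame(trait = nms[i], neglog10_p = NA_real_,
                        effect = NA_real_, se = NA_real_,
                        stringsAsFactors = FALSE))
    data.frame(trait = nms[i], neglog10_p = s$neglog10_p[j],
               effect = s$effect[j], se = s$se[j], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-ifelse(is.na(out$neglog10_p), -Inf, out$neglog10_p)), ,
      drop = FALSE]
}
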