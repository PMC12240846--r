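#' Standardize traits within sex-by-site cells
#'
#' Centers and scales each trait to zero mean / unit variance within every
#' sex x site cell, so that clustering reflects within-group individual
#' differences rather than site or sex offsets. Missing values are excluded
#' from the moments and propagated; a zero-variance cell-trait maps to zeros
#' with a warning.
#'
#' @param table cohort data.frame.
#' @param traits character vector of trait column names.
#' @param by grouping columns (default sex and site).
#' @return numeric matrix (individuals x traits) with rownames = ids.
#' @export
standardize_within_group <- function(table, traits, by = c("sex", "site")) {
  stopifnot(all(traits %in% names(table)), all(by %in% names(table)))
  cell <- interaction(table[by], drop = TRUE)
  if (any(tabulate(cell) < 2))
    stop("every ", paste(by, collapse = "x"), " cell needs >= 2 individuals")
  Z <- matrix(NA_real_, nrow(table), length(traits),
              dimnames = list(table$id, traits))
  for (g in levels(cell)) {
    rows <- which(cell == g)
    for (t in traits) {
      x <- table[[t]][rows]
      s <- stats::sd(x, na.rm = TRUE)
      if (is.na(s)) { Z[rows, t] <- NA_real_; next }
      if (s == 0) {
        warning("trait ", t, " constant in cell ", g, "; standardized to 0")
        Z[rows, t] <- ifelse(is.na(x), NA_real_, 0)
      } else Z[rows, t] <- (x - mean(x, na.rm = TRUE)) / s
    }
  }
  Z
}

#' Build a rat-rat similarity network
#'
#' Pairwise similarity is the Pearson correlation between two individuals'
#' standardized trait vectors over their shared non-missing traits; an edge
#' is present iff the similarity reaches the `edge_quantile` quantile of all
#' pairwise similarities. Individuals with fewer than 2 usable traits become
#' isolated nodes and are flagged.
#'
#' @param Z standardized trait matrix from [standardize_within_group()].
#' @param edge_quantile quantile of the similarity distribution above which
#'   an edge is drawn (default 0.8, i.e. the top 20% of pairs).
#' @return a `similarity_network` list: `ids`, `adjacency` (binary symmetric,
#'   zero diagonal), `similarity`, `record`.
#' @export
build_similarity_network <- function(Z, edge_quantile = 0.8) {
  n <- nrow(Z)
  if (n < 3) stop("need at least 3 individuals")
  usable <- rowSums(!is.na(Z)) >= 2
  S <- suppressWarnings(stats::cor(t(Z), use = "pairwise.complete.obs"))
  diag(S) <- NA
  thr <- stats::quantile(S[upper.tri(S)], edge_quantile, na.rm = TRUE, type = 7)
  A <- (!is.na(S) & S >= thr) * 1L
  A[!usable, ] <- 0L
  A[, !usable] <- 0L
  diag(A) <- 0L
  A <- pmax(A, t(A))   # guard symmetry against pairwise-NA asymmetries
  structure(list(ids = rownames(Z), adjacency = A, similarity = S,
                 record = list(measure = "pearson", edge_rule = "quantile",
                               edge_quantile = edge_quantile,
                               threshold = unname(thr),
                               isolated = rownames(Z)[!usable])),
            class = "similarity_network")
}

# collapsed log-evidence contribution of a block pair: Beta(1,1) conjugacy
lbeta_term <- function(edges, pairs) lbeta(edges + 1, pairs - edges + 1)

#' Fit a Bayesian stochastic block model by collapsed Gibbs sampling
#'
#' Single-layer binary SBM with a Dirichlet(1) prior on block proportions and
#' Beta(1, 1) priors on every block-pair edge probability, both integrated
#' out so the sampler sweeps only over node assignments. The chain is
#' initialised from spectral k-means on the adjacency matrix's leading
#' eigenvectors; after burn-in, sweeps are label-aligned (best of the K!
#' permutations against the running reference) and the point estimate is each
#' node's posterior-mode block.
#'
#' @param network a `similarity_network`.
#' @param K number of blocks (default 3).
#' @param n_sweeps total Gibbs sweeps (default 300).
#' @param burn_in sweeps discarded before the posterior summary (default 100).
#' @param seed integer seed.
#' @return a `blockmodel_fit` list: `K`, `assignment` (1..K per node),
#'   `confidence` (posterior fraction at the modal block), `edge_prob`
#'   (K x K posterior-mean edge probabilities), `log_posterior` trace,
#'   `ids`, `seed`.
#' @export
fit_sbm <- function(network, K = 3, n_sweeps = 300, burn_in = 100, seed = 1L) {
  A <- network$adjacency
  n <- nrow(A)
  if (K > n) stop("K exceeds the number of nodes")
  if (sum(A) == 0) stop("network has no edges")
  if (n_sweeps <= burn_in) stop("n_sweeps must exceed burn_in")
  set.seed(derive_seed(seed, "sbm"))

  # spectral initialisation
  eig <- eigen(A, symmetric = TRUE)
  emb <- eig$vectors[, seq_len(min(K, n)), drop = FALSE]
  km <- tryCatch(stats::kmeans(emb, centers = K, nstart = 10),
                 error = function(e) NULL)
  z <- if (is.null(km)) sample.int(K, n, replace = TRUE) else km$cluster
  if (length(unique(z)) < K) z[sample.int(n, K)] <- seq_len(K)

  # sufficient statistics: block sizes and between/within-block edge counts
  nk <- tabulate(z, K)
  E <- matrix(0, K, K)
  for (k in 1:K) for (l in k:K) {
    ek <- if (k == l) sum(A[z == k, z == k]) / 2 else sum(A[z == k, z == l])
    E[k, l] <- E[l, k] <- ek
  }
  pairs_mat <- function(nk) {
    P <- outer(nk, nk)
    diag(P) <- nk * (nk - 1) / 2
    P
  }

  log_post <- function(nk, E) {
    P <- pairs_mat(nk)
    ut <- upper.tri(E, diag = TRUE)
    sum(lbeta_term(E[ut], P[ut])) + sum(lgamma(nk + 1))
  }

  draws <- matrix(0L, n_sweeps - burn_in, n)
  lp_trace <- numeric(n_sweeps)
  perms <- perms_of(K)
  ref <- NULL
  Dmat <- matrix(0, K, K)  # row k: di, reused buffer
  for (sweep in seq_len(n_sweeps)) {
    for (i in seq_len(n)) {
      zi <- z[i]
      nbr <- which(A[i, ] == 1L)
      di <- tabulate(z[nbr], K)  # A[i,i] = 0, so i itself never counts
      # remove node i from the sufficient statistics
      nk[zi] <- nk[zi] - 1L
      E[zi, ] <- E[zi, ] - di
      E[, zi] <- E[zi, ]
      # collapsed conditional over candidate blocks, vectorized on the
      # K x K (block pair) grid: only pairs involving the candidate change
      Dmat[] <- rep(di, each = K)           # Dmat[k, l] = di[l]
      pairs_old <- outer(nk, nk)
      diag(pairs_old) <- nk * (nk - 1) / 2
      pairs_new <- outer(nk + 1, nk)
      diag(pairs_new) <- (nk + 1) * nk / 2
      Enew <- E + Dmat
      logw <- log(nk + 1) +
        rowSums(lbeta_term(Enew, pairs_new) - lbeta_term(E, pairs_old))
      logw <- logw - max(logw)
      znew <- sample.int(K, 1L, prob = exp(logw))
      nk[znew] <- nk[znew] + 1L
      E[znew, ] <- E[znew, ] + di
      E[, znew] <- E[znew, ]
      z[i] <- znew
    }
    lp_trace[sweep] <- log_post(nk, E)
    if (sweep > burn_in) {
      if (is.null(ref)) ref <- z
      draws[sweep - burn_in, ] <- align_labels(z, ref, perms)
    }
  }
  counts <- apply(draws, 2, tabulate, nbins = K)
  assignment <- apply(counts, 2, which.max)
  confidence <- counts[cbind(assignment, seq_len(n))] / nrow(draws)
  nk_f <- tabulate(assignment, K)
  P <- pairs_mat(nk_f)
  Ef <- matrix(0, K, K)
  for (k in 1:K) for (l in k:K) {
    ek <- if (k == l) sum(A[assignment == k, assignment == k]) / 2
          else sum(A[assignment == k, assignment == l])
    Ef[k, l] <- Ef[l, k] <- ek
  }
  edge_prob <- (Ef + 1) / (P + 2)   # posterior mean under Beta(1,1)
  edge_prob[P == 0] <- NA
  structure(list(K = K, assignment = assignment, confidence = confidence,
                 edge_prob = edge_prob, log_posterior = lp_trace,
                 ids = network$ids, seed = seed, n_sweeps = n_sweeps,
                 burn_in = burn_in),
            class = "blockmodel_fit")
}

# all permutations of 1..K (K is tiny, 3 by design)
perms_of <- function(K) {
  if (K == 1) return(matrix(1L, 1, 1))
  sub <- perms_of(K - 1)
  out <- matrix(0L, 0, K)
  for (pos in 1:K) {
    block <- cbind(sub[, seq_len(pos - 1), drop = FALSE], K,
                   sub[, seq(pos, K - 1)[seq_len(K - pos)], drop = FALSE])
    out <- rbind(out, block)
  }
  out
}

# relabel z by the permutation maximizing agreement with the reference
align_labels <- function(z, ref, perms) {
  best <- z; best_agree <- -1
  for (r in seq_len(nrow(perms))) {
    zz <- perms[r, ][z]
    agree <- sum(zz == ref)
    if (agree > best_agree) { best_agree <- agree; best <- zz }
  }
  best
}

#' Label SBM blocks by addiction severity
#'
#' Ranks blocks by their members' mean composite severity score (the mean of
#' z-scored heroin taking/seeking traits; higher = more severe): the highest
#' block becomes "vulnerable", the lowest "resilient", the middle
#' "intermediate". Ties are broken deterministically by block size (larger
#' first) with a warning.
#'
#' @param fit a `blockmodel_fit` with K = 3.
#' @param table cohort data.frame aligned with `fit$ids`.
#' @param severity_traits character vector of severity trait columns.
#' @return the fit with `labels` (per-node character) and `label_map` added.
#' @export
label_clusters <- function(fit, table, severity_traits) {
  stopifnot(fit$K == 3, all(severity_traits %in% names(table)))
  tab <- table[match(fit$ids, table$id), , drop = FALSE]
  Zs <- scale(as.matrix(tab[, severity_traits, drop = FALSE]))
  composite <- rowMeans(Zs, na.rm = TRUE)
  means <- vapply(1:3, function(k)
    mean(composite[fit$assignment == k], na.rm = TRUE), 0)
  if (anyNA(means)) means[is.na(means)] <- -Inf
  if (anyDuplicated(round(means, 12))) {
    warning("tied block severity means; breaking ties by block size")
    sizes <- tabulate(fit$assignment, 3)
    ord <- order(means, sizes)
  } else ord <- order(means)
  label_map <- character(3)
  label_map[ord] <- c("resilient", "intermediate", "vulnerable")
  fit$label_map <- label_map
  fit$labels <- label_map[fit$assignment]
  fit$severity_means <- means
  fit
}

#' One-vs-rest cluster contrast phenotypes
#'
#' @param fit a labeled `blockmodel_fit` (see [label_clusters()]).
#' @return data.frame with `id` and three 0/1 columns `vulnerable_vs_rest`,
#'   `intermediate_vs_rest`, `resilient_vs_rest` (each individual sums to 1
#'   across the three).
#' @export
cluster_contrasts <- function(fit) {
  if (is.null(fit$labels)) stop("fit must be labeled; see label_clusters()")
  out <- data.frame(id = fit$ids, stringsAsFactors = FALSE)
  for (lab in c("vulnerable", "intermediate", "resilient")) {
    v <- as.integer(fit$labels == lab)
    if (sum(v) == 0) warning("empty cluster: ", lab)
    out[[paste0(lab, "_vs_rest")]] <- v
  }
  out
}

#' Chi-square test of cluster composition across peak-SNP variants
#'
#' Contingency test of genotype group against a one-vs-rest cluster
#' contrast. Default grouping contrasts major-allele homozygotes with
#' minor-allele carriers (2 x 2, df = 1); `grouping = "genotype"` uses the
#' full three-genotype table (df = 2). Pearson chi-square without continuity
#' correction.
#'
#' @param peak_genotypes dosage vector at the peak SNP (alt-allele count).
#' @param contrast 0/1 contrast vector aligned with the genotypes.
#' @param grouping "carrier" (default) or "genotype".
#' @return list with `chi2`, `df`, `p`, `table`, `n`, `warning` (TRUE when
#'   any expected cell < 1).
#' @export
allele_by_cluster_test <- function(peak_genotypes, contrast,
                                   grouping = c("carrier", "genotype")) {
  grouping <- match.arg(grouping)
  ok <- !is.na(peak_genotypes) & !is.na(contrast)
  g <- peak_genotypes[ok]; y <- contrast[ok]
  if (grouping == "carrier") {
    p_alt <- mean(g) / 2
    minor_is_alt <- p_alt <= 0.5
    grp <- if (minor_is_alt) ifelse(g >= 1, "carrier", "major_hom")
           else ifelse(g <= 1, "carrier", "major_hom")
  } else grp <- factor(g, levels = 0:2)
  tab <- table(group = grp, cluster = y)
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("need at least 2 genotype groups and both contrast levels")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, table = tab, n = sum(tab),
       warning = any(ct$expected < 1))
}
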