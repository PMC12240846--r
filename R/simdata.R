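#' Configuration for a synthetic heterogeneous-stock-like cohort
#'
#' HS rodent colonies descend from a small panel of inbred founders (8 for
#' the rat HS colony), so every genome is a fine-grained founder mosaic. The
#' simulator emulates that structure: binary founder haplotypes, recombinant
#' mosaic diplotypes, and traits composed of planted additive QTLs, a
#' polygenic background, site and sex effects, and residual noise.
#'
#' @param seed integer seed; all simulator randomness derives from it.
#' @param n_individuals number of animals.
#' @param n_founders number of founder strains (>= 2; default 8, the HS panel
#'   size).
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @param snp_density SNPs per Mb.
#' @param recomb_rate expected crossovers per Mb per meiosis-equivalent
#'   (uniform genetic map, no interference). The default 0.5 reflects the
#'   recombination accumulated over the many breeding generations of an HS
#'   colony (~50 generations at ~1 cM/Mb), giving founder segments of a few
#'   Mb; a single-meiosis rate (~0.01) would leave unrealistically long
#'   segments and pervasive long-range LD.
#' @param founder_maf_dist founder allele-frequency distribution: either
#'   `list(type = "uniform", min, max)`, `list(type = "beta", shape1, shape2)`
#'   or `list(type = "point", value)`.
#' @param founder_block_snps mean number of consecutive SNPs sharing one
#'   founder allele pattern (geometric run lengths). Real SNPs arise on
#'   shared haplotype backgrounds, so neighboring SNPs are correlated across
#'   the founder panel; without this, no SNP could tag its neighbors at high
#'   r2 no matter how dense the panel. 1 = independent patterns per SNP.
#' @param founder_mutation per-founder probability that a copied pattern
#'   entry flips from one SNP to the next within a block (partial LD).
#' @param qtl_specs list of planted QTLs from [planted_qtl()].
#' @param h2_poly polygenic variance fraction in \[0, 1).
#' @param site_effect list with `shift` and `scale`, each length-2 named
#'   numeric (sites "site1", "site2"): additive shift and SD multiplier
#'   applied to the trait within site.
#' @param sex_effect additive shift applied to males (females are reference).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_individuals = 400L,
                       n_founders = 8L,
                       chrom_lengths = c(chr1 = 50e6, chr2 = 50e6,
                                         chr3 = 50e6, chr4 = 50e6),
                       snp_density = 25,
                       recomb_rate = 0.5,
                       founder_maf_dist = list(type = "uniform",
                                               min = 0.1, max = 0.5),
                       founder_block_snps = 8,
                       founder_mutation = 0.01,
                       qtl_specs = list(),
                       h2_poly = 0.25,
                       site_effect = list(shift = c(site1 = 0, site2 = 0.5),
                                          scale = c(site1 = 1, site2 = 1.3)),
                       sex_effect = 0.2) {
  cfg <- list(seed = as.integer(seed), n_individuals = as.integer(n_individuals),
              n_founders = as.integer(n_founders),
              chrom_lengths = chrom_lengths, snp_density = snp_density,
              recomb_rate = recomb_rate, founder_maf_dist = founder_maf_dist,
              founder_block_snps = founder_block_snps,
              founder_mutation = founder_mutation,
              qtl_specs = qtl_specs, h2_poly = h2_poly,
              site_effect = site_effect, sex_effect = sex_effect)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' Specify a planted additive QTL
#'
#' Effect sizes default to the 2.5--3% band of trait variance that HS rat
#' cohorts of ~1000 animals are powered to detect.
#'
#' @param chrom chromosome label (must exist in the config).
#' @param pos target position in bp; snapped to the nearest simulated SNP.
#' @param variance_fraction fraction of trait variance in (0, 1).
#' @return a `planted_qtl` list.
#' @export
planted_qtl <- function(chrom, pos, variance_fraction = 0.03) {
  stopifnot(variance_fraction > 0, variance_fraction < 1, pos >= 1)
  structure(list(chrom = as.character(chrom), pos = pos,
                 variance_fraction = variance_fraction),
            class = "planted_qtl")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_founders < 2L) stop("config error: n_founders must be >= 2")
  if (cfg$n_individuals < 1L) stop("config error: n_individuals must be >= 1")
  if (is.null(names(cfg$chrom_lengths)) || any(cfg$chrom_lengths <= 0))
    stop("config error: chrom_lengths must be named and positive")
  if (cfg$h2_poly < 0 || cfg$h2_poly >= 1)
    stop("config error: h2_poly must lie in [0, 1)")
  if (cfg$snp_density <= 0) stop("config error: snp_density must be positive")
  if (cfg$recomb_rate < 0) stop("config error: recomb_rate must be >= 0")
  vf <- sum(vapply(cfg$qtl_specs, function(q) q$variance_fraction, 0))
  if (cfg$h2_poly + vf >= 1)
    stop("config error: h2_poly + sum of QTL variance fractions must be < 1")
  for (q in cfg$qtl_specs) {
    if (!q$chrom %in% names(cfg$chrom_lengths))
      stop("config error: QTL chromosome not in chrom_lengths: ", q$chrom)
    if (q$pos > cfg$chrom_lengths[[q$chrom]])
      stop("config error: QTL position beyond chromosome end")
  }
  if (!cfg$founder_maf_dist$type %in% c("uniform", "beta", "point"))
    stop("config error: unknown founder_maf_dist type")
  if (cfg$founder_block_snps < 1)
    stop("config error: founder_block_snps must be >= 1")
  if (cfg$founder_mutation < 0 || cfg$founder_mutation > 0.5)
    stop("config error: founder_mutation must lie in [0, 0.5]")
  invisible(cfg)
}

draw_founder_freqs <- function(dist, n) {
  switch(dist$type,
    uniform = stats::runif(n, dist$min, dist$max),
    beta    = stats::rbeta(n, dist$shape1, dist$shape2),
    point   = rep(dist$value, n))
}

#' Simulate founder haplotypes
#'
#' Lays SNPs down uniformly at the configured density (positions strictly
#' increasing within chromosome) and draws binary founder alleles. Founder
#' allele patterns come in geometric runs of mean length
#' `founder_block_snps`: at a block start the pattern is drawn fresh at an
#' allele frequency from `founder_maf_dist`; within a block each SNP copies
#' the previous pattern with per-founder flip probability `founder_mutation`.
#' Runs never cross chromosome boundaries. This mimics the haplotype-block
#' correlation of real variant panels, which is what lets dense markers tag
#' each other at high r2.
#'
#' @param config a [sim_config()].
#' @return list with `haplotypes` (n_founders x n_snps binary matrix),
#'   `map` (SNP metadata data.frame) and `pool_freq` (realized founder-pool
#'   frequencies).
#' @export
simulate_founders <- function(config) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, "founders"))
  maps <- lapply(names(config$chrom_lengths), function(ch) {
    len <- config$chrom_lengths[[ch]]
    m <- max(1L, round(len / 1e6 * config$snp_density))
    pos <- sort(sample.int(len, m))
    data.frame(chrom = ch, pos = pos, stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, maps)
  map$id <- sprintf("%s:%d", map$chrom, map$pos)
  map$ref <- "A"
  map$alt <- "C"
  m <- nrow(map)
  nf <- config$n_founders
  freqs <- draw_founder_freqs(config$founder_maf_dist, m)
  new_block <- stats::runif(m) < 1 / config$founder_block_snps
  new_block[match(unique(map$chrom), map$chrom)] <- TRUE
  hap <- matrix(0L, nf, m)
  for (j in seq_len(m)) {
    if (new_block[j]) {
      hap[, j] <- stats::rbinom(nf, 1L, freqs[j])
    } else {
      flips <- stats::rbinom(nf, 1L, config$founder_mutation)
      hap[, j] <- bitwXor(hap[, j - 1L], flips)
    }
  }
  colnames(hap) <- map$id
  list(haplotypes = hap, map = map, pool_freq = colMeans(hap))
}

# one mosaic haplotype along a chromosome: founder segments delimited by a
# Poisson crossover process at recomb_rate per Mb
mosaic_haplotype <- function(pos, len_bp, founder_hap_block, recomb_rate,
                             n_founders) {
  n_break <- stats::rpois(1L, recomb_rate * len_bp / 1e6)
  if (n_break == 0L) {
    f <- sample.int(n_founders, 1L)
    return(list(allele = founder_hap_block[f, ], origin = rep(f, length(pos))))
  }
  breaks <- sort(stats::runif(n_break, 0, len_bp))
  founders <- sample.int(n_founders, n_break + 1L, replace = TRUE)
  seg <- findInterval(pos, breaks) + 1L
  origin <- founders[seg]
  allele <- founder_hap_block[cbind(origin, seq_along(pos))]
  list(allele = allele, origin = origin)
}

#' Simulate mosaic genotypes from founder haplotypes
#'
#' Each individual carries two haplotypes per chromosome; each haplotype is a
#' founder mosaic whose breakpoints follow a Poisson process at `recomb_rate`
#' crossovers per Mb. Dosage is the sum of the two haplotype alleles; there
#' are no missing values.
#'
#' @param founders output of [simulate_founders()].
#' @param config the same [sim_config()].
#' @param return_origins if TRUE, attach founder-origin matrices as the
#'   `origins` attribute (two n x m integer matrices).
#' @return a [genotype_matrix()].
#' @export
simulate_mosaic_genotypes <- function(founders, config, return_origins = FALSE) {
  stopifnot(nrow(founders$map) > 0)
  set.seed(derive_seed(config$seed, "mosaic"))
  n <- config$n_individuals
  map <- founders$map
  m <- nrow(map)
  dosage <- matrix(0L, n, m)
  orig1 <- if (return_origins) matrix(0L, n, m) else NULL
  orig2 <- if (return_origins) matrix(0L, n, m) else NULL
  for (ch in names(config$chrom_lengths)) {
    idx <- which(map$chrom == ch)
    if (!length(idx)) next
    block <- founders$haplotypes[, idx, drop = FALSE]
    pos <- map$pos[idx]
    len <- config$chrom_lengths[[ch]]
    for (i in seq_len(n)) {
      h1 <- mosaic_haplotype(pos, len, block, config$recomb_rate, config$n_founders)
      h2 <- mosaic_haplotype(pos, len, block, config$recomb_rate, config$n_founders)
      dosage[i, idx] <- h1$allele + h2$allele
      if (return_origins) {
        orig1[i, idx] <- h1$origin
        orig2[i, idx] <- h2$origin
      }
    }
  }
  ids <- sprintf("ind%04d", seq_len(n))
  rownames(dosage) <- ids
  G <- genotype_matrix(dosage, map, ids)
  if (return_origins) attr(G, "origins") <- list(orig1, orig2)
  G
}

#' Simulate a behavioral trait over a genotyped cohort
#'
#' Builds `y = site effect + sex effect + sum_k beta_k x_k + u + e`, where the
#' planted QTL dosages `x_k` are standardized so `beta_k = sqrt(vf_k)` injects
#' the configured variance fraction, the polygenic term `u` is a weighted sum
#' of standardized non-causal SNPs rescaled to `h2_poly`, and `e` is Gaussian
#' noise carrying the remaining variance. Site shift/scale and the male sex
#' shift are applied on top, so downstream preparation has real structure to
#' remove. Ground truth (realized QTL SNPs and betas) is attached as the
#' `ground_truth` attribute.
#'
#' @param G a [genotype_matrix()] from [simulate_mosaic_genotypes()].
#' @param config the [sim_config()].
#' @param trait_name column name for the simulated trait.
#' @param cohort optional data.frame with `id`, `site`, `sex`, `batch` from a
#'   previous call, so several traits share one cohort layout.
#' @return data.frame (cohort table) with columns `id`, `site`, `sex`,
#'   `batch` and the trait.
#' @export
simulate_phenotypes <- function(G, config, trait_name = "trait",
                                cohort = NULL) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, paste0("pheno:", trait_name)))
  n <- n_individuals(G)
  vf <- vapply(config$qtl_specs, function(q) q$variance_fraction, 0)
  if (config$h2_poly + sum(vf) >= 1)
    stop("config error: variance fractions infeasible")

  # snap each planted QTL to the nearest polymorphic SNP on its chromosome
  # (a monomorphic marker cannot carry an effect)
  qtl_idx <- integer(0)
  truth <- NULL
  if (length(config$qtl_specs)) {
    snp_sd <- apply(G$dosage, 2, stats::sd)
    qtl_idx <- vapply(config$qtl_specs, function(q) {
      on_ch <- which(G$map$chrom == q$chrom & snp_sd > 0)
      if (!length(on_ch)) stop("no polymorphic SNPs on QTL chromosome ", q$chrom)
      on_ch[which.min(abs(G$map$pos[on_ch] - q$pos))]
    }, 0L)
    truth <- data.frame(chrom = G$map$chrom[qtl_idx],
                        pos = G$map$pos[qtl_idx],
                        snp_id = G$map$id[qtl_idx],
                        variance_fraction = vf,
                        stringsAsFactors = FALSE)
  }

  g_qtl <- rep(0, n)
  betas <- numeric(0)
  if (length(qtl_idx)) {
    X <- G$dosage[, qtl_idx, drop = FALSE]
    sds <- apply(X, 2, stats::sd)
    if (any(sds == 0))
      stop("planted QTL snapped to a monomorphic SNP; increase MAF or density")
    Xs <- scale(X)
    betas <- sqrt(vf)
    g_qtl <- drop(Xs %*% betas)
    truth$beta_std <- betas
  }

  u <- rep(0, n)
  if (config$h2_poly > 0) {
    bg_idx <- setdiff(seq_len(n_snps(G)), qtl_idx)
    Xb <- impute_dosage(G$dosage[, bg_idx, drop = FALSE])
    sds <- apply(Xb, 2, stats::sd)
    Xb <- Xb[, sds > 0, drop = FALSE]
    w <- stats::rnorm(ncol(Xb)) / sqrt(ncol(Xb))
    u <- drop(scale(Xb) %*% w)
    # background SNPs in LD with the planted QTLs would otherwise leak a
    # random increment into each QTL effect; orthogonalize so the configured
    # variance fractions are realized
    if (length(qtl_idx))
      u <- qr.resid(qr(cbind(1, scale(G$dosage[, qtl_idx, drop = FALSE]))), u)
    u <- u / stats::sd(u) * sqrt(config$h2_poly)
  }

  e_var <- 1 - config$h2_poly - sum(vf)
  e <- stats::rnorm(n, 0, sqrt(e_var))

  if (is.null(cohort)) {
    site <- rep(c("site1", "site2"), length.out = n)[sample.int(n)]
    sex <- rep(c("F", "M"), length.out = n)[sample.int(n)]
    batch <- sample(paste0("batch", 1:4), n, replace = TRUE)
  } else {
    stopifnot(identical(cohort$id, G$ids))
    site <- cohort$site; sex <- cohort$sex; batch <- cohort$batch
  }

  y <- g_qtl + u + e + ifelse(sex == "M", config$sex_effect, 0)
  y <- y * config$site_effect$scale[site] + config$site_effect$shift[site]

  out <- data.frame(id = G$ids, site = site, sex = sex, batch = batch,
                    stringsAsFactors = FALSE)
  out[[trait_name]] <- y
  attr(out, "ground_truth") <- list(qtls = truth, h2_poly = config$h2_poly,
                                    residual_var = e_var)
  out
}

#' Progressive-ratio response-requirement ladder
#'
#' The operant progressive-ratio schedule raises the lever-press requirement
#' for the n-th reward as `5 * exp(0.2 * n) - 5`, rounded to the nearest
#' integer with a floor of 1 press. The last requirement completed is the
#' break point, an index of motivation.
#'
#' @param n_max number of steps (>= 1).
#' @return integer vector of response requirements, monotone nondecreasing.
#' @export
progressive_ratio_schedule <- function(n_max) {
  if (!is.numeric(n_max) || length(n_max) != 1L || n_max < 1)
    stop("n_max must be a single integer >= 1")
  n <- seq_len(n_max)
  req <- pmax(1L, as.integer(round(5 * exp(0.2 * n) - 5)))
  cummax(req)
}

#' Simulate a cohort with planted severity clusters
#'
#' Emulates the vulnerable / intermediate / resilient addiction-severity
#' structure. Each cluster's trait-mean vector combines a severity *level*
#' (resilient `-separation`, intermediate 0, vulnerable `+separation`, in
#' within-cluster SD units) with a cluster-specific zero-mean *profile shape*
#' whose SD across traits also equals `separation`. The shape component is
#' what an individual-by-individual correlation network can see (a uniform
#' shift across all traits cancels when each animal's trait vector is
#' centered), so `separation` directly sets the cluster separation along the
#' dimension the network uses; the level component orders the clusters for
#' severity labeling. `separation = 0` removes all structure.
#'
#' @param n_per_cluster animals per cluster.
#' @param traits character vector of at least 4 trait names; the default is a
#'   12-measure battery mirroring heroin taking, extinction, seeking and
#'   pre/post anxiety and nociception readouts.
#' @param separation cluster separation in within-cluster SD units.
#' @param seed integer seed.
#' @return data.frame with `id`, `site`, `sex`, trait columns and the
#'   ground-truth `true_cluster` column.
#' @export
simulate_clustered_cohort <- function(n_per_cluster,
                                      traits = c("consumption",
                                                 "escalation_h1",
                                                 "escalation_total",
                                                 "break_point", "ext_burst",
                                                 "ext_prime", "ext_day6",
                                                 "ext_deescalation",
                                                 "prime_rein", "cued_rein",
                                                 "tf_baseline", "epm_open"),
                                      separation = 3, seed = 1L) {
  stopifnot(separation >= 0, n_per_cluster >= 1, length(traits) >= 4)
  set.seed(derive_seed(seed, "clustered_cohort"))
  labels <- rep(c("resilient", "intermediate", "vulnerable"),
                each = n_per_cluster)
  cluster_k <- rep(1:3, each = n_per_cluster)
  level <- c(-1, 0, 1) * separation
  n <- length(labels)
  T_ <- length(traits)
  S <- cluster_shapes(T_)
  mu <- sapply(seq_len(T_), function(t)
    level[cluster_k] + separation * S[t, cluster_k])
  X <- mu + matrix(stats::rnorm(n * T_), n, T_)
  colnames(X) <- traits
  out <- data.frame(id = sprintf("ind%04d", seq_len(n)),
                    site = sample(rep(c("site1", "site2"), length.out = n)),
                    sex = sample(rep(c("F", "M"), length.out = n)),
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(X))
  out$true_cluster <- labels
  out
}

# three deterministic zero-mean, unit-SD, mutually orthogonal trait profiles;
# balanced +/-1 sign patterns where the trait count allows (equal per-trait
# magnitude, so per-trait rescaling cannot distort any one profile), else an
# orthonormalized cosine basis
cluster_shapes <- function(T_) {
  if (T_ %% 4 == 0) {
    S <- cbind(rep(c(1, -1), T_ / 2),
               rep(c(1, 1, -1, -1), T_ / 4),
               rep(c(1, -1, -1, 1), T_ / 4))
  } else {
    base <- sapply(1:3, function(k) cos(2 * pi * seq_len(T_) * k / T_ + k / 2))
    base <- scale(base, center = TRUE, scale = FALSE)
    S <- qr.Q(qr(base))
  }
  S <- sweep(S, 2, apply(S, 2, stats::sd), "/")
  scale(S, center = TRUE, scale = FALSE)
}
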