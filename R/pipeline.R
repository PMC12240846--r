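#' Configuration for an end-to-end pipeline run
#'
#' Bundles every stage's parameters: the cohort source (a [sim_config()] or
#' genotype/phenotype file paths), QC thresholds, trait preparation, GWAS
#' significance levels and permutation count, the QTL-calling rule constants,
#' clustering parameters, a global seed (fanned out to per-stage seeds via
#' [derive_seed()]) and the output directory.
#'
#' @param sim a [sim_config()] for a synthetic cohort, or NULL when reading
#'   files.
#' @param genotype_path,genotype_format,pheno_path input files (used when
#'   `sim` is NULL).
#' @param traits character vector of trait columns to analyse.
#' @param covariates candidate covariate columns screened per site.
#' @param qc named list of filter thresholds.
#' @param alphas significance levels (genome-wide, suggestive).
#' @param n_perm permutations for the threshold (0 skips thresholding).
#' @param qtl_rule list with `support_window`, `support_delta`, `r2_min`,
#'   `coloc_window`.
#' @param clustering list with `traits` (NULL = all traits), `K`,
#'   `edge_quantile`, `n_sweeps`, `burn_in`.
#' @param seed global integer seed.
#' @param out_dir output directory.
#' @return a `run_config` list.
#' @export
run_config <- function(sim = NULL, genotype_path = NULL,
                       genotype_format = "plink", pheno_path = NULL,
                       traits = "trait", covariates = c("sex", "batch"),
                       qc = list(max_missing = 0.10, min_maf = 0.005,
                                 min_hwe_p = 1e-10),
                       alphas = c(0.05, 0.10), n_perm = 100,
                       qtl_rule = list(support_window = 5e5,
                                       support_delta = 2.0, r2_min = 0.6,
                                       coloc_window = 3e6),
                       clustering = list(traits = NULL, K = 3,
                                         edge_quantile = 0.8,
                                         n_sweeps = 300, burn_in = 100),
                       seed = 1L, out_dir = tempfile("hsqtl_run_")) {
  if (is.null(sim) && (is.null(genotype_path) || is.null(pheno_path)))
    stop("config error: provide either a sim config or input paths")
  stopifnot(all(alphas > 0 & alphas <= 1), n_perm >= 0)
  structure(list(sim = sim, genotype_path = genotype_path,
                 genotype_format = genotype_format, pheno_path = pheno_path,
                 traits = traits, covariates = covariates, qc = qc,
                 alphas = alphas, n_perm = n_perm, qtl_rule = qtl_rule,
                 clustering = clustering, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

write_stage <- function(obj, path) {
  if (is.data.frame(obj)) data.table::fwrite(obj, path, sep = "\t", na = "NA")
  else jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                            pretty = TRUE, force = TRUE)
  path
}

#' Run the full phenotype-to-QTL pipeline
#'
#' Stages, in dependency order: simulate or ingest genotypes/phenotypes; SNP
#' QC; per-trait preparation; SNP heritability (GREML); LOCO association
#' scans; permutation threshold (skipped with a manifest note when
#' `n_perm = 0`); QTL calling with conditional mapping and LD intervals;
#' similarity-network clustering with severity labels and cluster-contrast
#' phenotypes. Every artifact is written under `config$out_dir` and listed
#' in the returned manifest with an md5 content hash; reruns under the same
#' config are identical.
#'
#' @param config a [run_config()].
#' @return the manifest (list), invisibly also written as `manifest.json`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  artifacts <- character()
  notes <- character()

  # stage: cohort
  if (!is.null(config$sim)) {
    founders <- simulate_founders(config$sim)
    G <- simulate_mosaic_genotypes(founders, config$sim)
    pheno <- NULL
    for (tr in config$traits) {
      tab <- simulate_phenotypes(G, config$sim, trait_name = tr,
                                 cohort = pheno)
      pheno <- if (is.null(pheno)) tab else cbind(pheno, tab[, tr, drop = FALSE])
    }
    gt <- attr(tab, "ground_truth")
    artifacts <- c(artifacts, write_stage(gt, out("ground_truth.json")))
  } else {
    G <- read_genotypes(config$genotype_path, config$genotype_format)
    pheno <- read_pheno_tsv(config$pheno_path)
  }
  write_plink(G, out("genotypes"))
  artifacts <- c(artifacts, out("genotypes.bed"), out("genotypes.bim"),
                 out("genotypes.fam"),
                 write_stage(pheno, out("phenotypes.tsv")))

  # stage: QC
  G <- filter_snps(G, config$qc$max_missing, config$qc$min_maf,
                   config$qc$min_hwe_p, quiet = TRUE)
  qc_log <- attr(G, "qc_log")
  artifacts <- c(artifacts, write_stage(qc_log, out("qc_log.json")))

  # stage: preparation
  pheno <- pheno[match(G$ids, pheno$id), , drop = FALSE]
  prepared <- data.frame(id = pheno$id, stringsAsFactors = FALSE)
  for (tr in config$traits)
    prepared[[tr]] <- prepare_trait(pheno, tr, config$covariates)
  artifacts <- c(artifacts, write_stage(prepared, out("prepared.tsv")))

  # stage: heritability
  grms <- compute_loco_grms(G)
  h2 <- do.call(rbind, lapply(config$traits, function(tr) {
    y <- prepared[[tr]]
    ok <- !is.na(y)
    g <- grms$full; g$A <- g$A[ok, ok]; g$ids <- g$ids[ok]
    fit <- fit_greml(y[ok], g)
    data.frame(trait = tr, h2 = fit$h2, se_h2 = fit$se_h2,
               lrt_p = fit$lrt_p, n = fit$n,
               converged = fit$converged, stringsAsFactors = FALSE)
  }))
  artifacts <- c(artifacts, write_stage(h2, out("heritability.tsv")))

  # stage: scans
  scans <- list()
  for (tr in config$traits) {
    scans[[tr]] <- assoc_scan(prepared[[tr]], G, grms$loco, trait = tr)
    artifacts <- c(artifacts,
                   write_stage(scans[[tr]], out(paste0("scan_", tr, ".tsv"))))
  }

  # stage: threshold
  threshold <- NULL
  if (config$n_perm > 0) {
    threshold <- permutation_threshold(
      prepared[[config$traits[1]]], G, grms$loco, n_perm = config$n_perm,
      alpha = config$alphas[1], seed = derive_seed(config$seed, "threshold"))
    artifacts <- c(artifacts,
                   write_stage(threshold[c("alpha", "n_perm", "value", "seed")],
                               out("threshold.json")))
  } else notes <- c(notes, "n_perm = 0: permutation thresholding skipped")

  # stage: QTLs
  qtls <- NULL
  if (!is.null(threshold)) {
    qtls <- do.call(rbind, lapply(config$traits, function(tr)
      iterative_conditional_mapping(
        prepared[[tr]], G, grms$loco, threshold, scan = scans[[tr]],
        support_window = config$qtl_rule$support_window,
        support_delta = config$qtl_rule$support_delta,
        r2_min = config$qtl_rule$r2_min, trait = tr)))
    artifacts <- c(artifacts, write_stage(qtls, out("qtls.tsv")))
  }

  # stage: clustering
  cl_traits <- config$clustering$traits
  if (is.null(cl_traits)) cl_traits <- config$traits
  cluster_out <- NULL
  if (length(cl_traits) >= 2) {
    Z <- standardize_within_group(pheno, cl_traits)
    net <- build_similarity_network(Z, config$clustering$edge_quantile)
    fit <- fit_sbm(net, K = config$clustering$K,
                   n_sweeps = config$clustering$n_sweeps,
                   burn_in = config$clustering$burn_in,
                   seed = derive_seed(config$seed, "cluster"))
    fit <- label_clusters(fit, pheno, cl_traits)
    contrasts <- cluster_contrasts(fit)
    cluster_out <- data.frame(id = fit$ids, block = fit$assignment,
                              label = fit$labels,
                              confidence = fit$confidence,
                              stringsAsFactors = FALSE)
    artifacts <- c(artifacts, write_stage(cluster_out, out("clusters.tsv")),
                   write_stage(contrasts, out("cluster_contrasts.tsv")))
  } else notes <- c(notes, "fewer than 2 clustering traits: clustering skipped")

  manifest <- list(seed = config$seed,
                   parameters = config[c("traits", "covariates", "qc",
                                         "alphas", "n_perm", "qtl_rule")],
                   notes = notes,
                   artifacts = lapply(artifacts, function(f)
                     list(file = basename(f),
                          md5 = unname(tools::md5sum(f)))))
  write_stage(manifest, out("manifest.json"))
  invisible(list(manifest = manifest, genotypes = G, prepared = prepared,
                 heritability = h2, scans = scans, threshold = threshold,
                 qtls = qtls, clusters = cluster_out,
                 out_dir = config$out_dir))
}
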