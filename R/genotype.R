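#' Construct a genotype matrix object
#'
#' Container for biallelic SNP dosages: individuals in rows, SNPs in columns.
#' Dosage is the count of the alternate allele (0, 1, 2 or NA for missing).
#' SNPs are kept sorted by (chromosome, position); the dosage columns are
#' reordered accordingly so SNP ids always track their column.
#'
#' @param dosage numeric matrix, individuals x SNPs, entries in {0,1,2,NA}.
#' @param map data.frame with columns `chrom`, `pos` (1-based bp), `id`,
#'   `ref`, `alt`, one row per SNP (extra per-SNP statistic columns such as
#'   `call_rate`, `maf`, `hwe_p` are carried along).
#' @param ids character vector of individual ids (defaults to rownames).
#' @return an object of class `genotype_matrix` with elements `dosage`,
#'   `map`, `ids`.
#' @export
genotype_matrix <- function(dosage, map, ids = rownames(dosage)) {
  dosage <- as.matrix(dosage)
  if (is.null(ids)) ids <- paste0("ind", seq_len(nrow(dosage)))
  ids <- as.character(ids)
  stopifnot(nrow(map) == ncol(dosage), length(ids) == nrow(dosage))
  needed <- c("chrom", "pos", "id", "ref", "alt")
  missing_cols <- setdiff(needed, names(map))
  if (length(missing_cols))
    stop("map lacks columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(ids)) stop("duplicate individual ids")
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  map$chrom <- as.character(map$chrom)
  map$id <- as.character(map$id)
  ord <- order(map$chrom, map$pos, map$id)
  map <- map[ord, , drop = FALSE]
  dosage <- dosage[, ord, drop = FALSE]
  rownames(map) <- NULL
  dimnames(dosage) <- list(ids, map$id)
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && (min(bad) < 0 || max(bad) > 2))
    stop("dosages must lie in [0, 2]")
  structure(list(dosage = dosage, map = map, ids = ids),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d SNPs on %d chromosome(s)\n",
              length(x$ids), nrow(x$map), length(unique(x$map$chrom))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Number of individuals / SNPs in a genotype matrix
#' @param G a `genotype_matrix`.
#' @return integer count.
#' @export
n_individuals <- function(G) length(G$ids)

#' @rdname n_individuals
#' @export
n_snps <- function(G) nrow(G$map)

#' Subset a genotype matrix
#'
#' @param G a `genotype_matrix`.
#' @param individuals ids or indices of individuals to keep (NULL = all).
#' @param snps SNP ids or logical/integer index over map rows (NULL = all).
#' @return a `genotype_matrix`.
#' @export
subset_genotypes <- function(G, individuals = NULL, snps = NULL) {
  ri <- seq_along(G$ids)
  if (!is.null(individuals)) {
    ri <- if (is.character(individuals)) match(individuals, G$ids) else ri[individuals]
    if (anyNA(ri)) stop("unknown individual id(s)")
  }
  ci <- seq_len(nrow(G$map))
  if (!is.null(snps)) {
    ci <- if (is.character(snps)) match(snps, G$map$id) else ci[snps]
    if (anyNA(ci)) stop("unknown SNP id(s)")
  }
  genotype_matrix(G$dosage[ri, ci, drop = FALSE],
                  G$map[ci, , drop = FALSE], G$ids[ri])
}

#' Extract a single SNP's dosage vector
#' @param G a `genotype_matrix`.
#' @param snp_id SNP id.
#' @return named numeric vector of dosages.
#' @export
snp_dosage <- function(G, snp_id) {
  j <- match(snp_id, G$map$id)
  if (is.na(j)) stop("SNP not found: ", snp_id)
  G$dosage[, j]
}

# mean-impute missing dosages per SNP (used by GRM / association paths)
impute_dosage <- function(dosage) {
  nas <- which(colSums(is.na(dosage)) > 0L)
  for (j in nas) {
    x <- dosage[, j]
    m <- mean(x, na.rm = TRUE)
    if (is.nan(m)) m <- 0
    x[is.na(x)] <- m
    dosage[, j] <- x
  }
  dosage
}
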