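#' Read genotypes from PLINK or VCF files
#'
#' Dosages are oriented as the count of the alternate (bim A1 / VCF ALT)
#' allele; missing calls are preserved as NA. SNPs are sorted by
#' (chromosome, position) on load with a stable id mapping.
#'
#' @param path PLINK prefix (for `format = "plink"`) or VCF path.
#' @param format "plink" or "vcf".
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("plink", "vcf")) {
  format <- match.arg(format)
  switch(format, plink = read_plink(path), vcf = read_vcf(path))
}

#' Write genotypes to PLINK or VCF files
#'
#' @param G a [genotype_matrix()].
#' @param path PLINK prefix or VCF path.
#' @param format "plink" or "vcf".
#' @return invisibly, the path(s) written.
#' @export
write_genotypes <- function(G, path, format = c("plink", "vcf")) {
  format <- match.arg(format)
  switch(format, plink = write_plink(G, path), vcf = write_vcf(G, path))
}

# ---- PLINK bed/bim/fam -----------------------------------------------------
# bed is the variant-major v1.00 binary layout (magic 6c 1b 01); each SNP
# packs 4 individuals/byte, 2 bits each: 00 = hom A1 (dosage 2), 10 = het,
# 11 = hom A2 (dosage 0), 01 = missing. A1 carries the alt allele here.

#' @rdname read_genotypes
#' @param prefix PLINK fileset prefix (reads/writes prefix.bed/.bim/.fam).
#' @export
read_plink <- function(prefix) {
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam))
    if (!file.exists(f)) stop("parse error: missing file ", f)
  bim_df <- data.table::fread(bim, header = FALSE, data.table = FALSE,
                              colClasses = list(character = c(1, 2, 5, 6)))
  if (ncol(bim_df) != 6) stop("parse error: ", bim, " must have 6 columns")
  names(bim_df) <- c("chrom", "id", "cm", "pos", "a1", "a2")
  fam_df <- data.table::fread(fam, header = FALSE, data.table = FALSE,
                              colClasses = list(character = 2))
  if (ncol(fam_df) != 6) stop("parse error: ", fam, " must have 6 columns")
  ids <- as.character(fam_df[[2]])
  n <- length(ids); m <- nrow(bim_df)
  bpv <- ceiling(n / 4)
  raw <- readBin(bed, "raw", n = 3 + as.double(m) * bpv)
  if (length(raw) != 3 + m * bpv)
    stop("consistency error: ", bed, " size does not match bim/fam (",
         m, " SNPs x ", n, " individuals)")
  if (!identical(as.integer(raw[1:3]), c(0x6cL, 0x1bL, 0x01L)))
    stop("parse error: ", bed, " lacks the variant-major v1.00 magic bytes")
  ints <- as.integer(raw[-(1:3)])
  codes <- matrix(0L, 4L * bpv, m)
  body <- matrix(ints, bpv, m)
  for (k in 0:3)
    codes[seq(k + 1L, 4L * bpv, by = 4L), ] <-
      bitwAnd(bitwShiftR(body, 2L * k), 3L)
  codes <- codes[seq_len(n), , drop = FALSE]
  lut <- c(2, NA, 1, 0)  # code 0,1,2,3 -> dosage of A1 (alt)
  dosage <- matrix(lut[codes + 1L], n, m)
  map <- data.frame(chrom = bim_df$chrom, pos = bim_df$pos, id = bim_df$id,
                    ref = bim_df$a2, alt = bim_df$a1, stringsAsFactors = FALSE)
  genotype_matrix(dosage, map, ids)
}

#' @rdname write_genotypes
#' @export
write_plink <- function(G, prefix) {
  n <- n_individuals(G); m <- n_snps(G)
  bpv <- ceiling(n / 4)
  code <- matrix(1L, 4L * bpv, m)          # pad + missing -> code 01
  d <- G$dosage
  code[seq_len(n), ] <- ifelse(is.na(d), 1L, c(3L, 2L, 0L)[d + 1L])
  body <- matrix(0L, bpv, m)
  for (k in 0:3)
    body <- body + bitwShiftL(code[seq(k + 1L, 4L * bpv, by = 4L), ,
                                   drop = FALSE], 2L * k)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(body), con)
  data.table::fwrite(data.frame(G$map$chrom, G$map$id, 0, G$map$pos,
                                G$map$alt, G$map$ref),
                     paste0(prefix, ".bim"), sep = "\t", col.names = FALSE)
  data.table::fwrite(data.frame(G$ids, G$ids, 0, 0, 0, -9),
                     paste0(prefix, ".fam"), sep = "\t", col.names = FALSE)
  invisible(paste0(prefix, c(".bed", ".bim", ".fam")))
}

# ---- VCF 4.2 ---------------------------------------------------------------

#' @rdname read_genotypes
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("parse error: missing file ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  fix <- vcfR::getFIX(v)
  alt_count <- function(g) {
    if (is.na(g) || g %in% c("./.", ".|.", ".")) return(NA_real_)
    sum(as.integer(strsplit(g, "[/|]")[[1]]) > 0)
  }
  dosage <- matrix(vapply(gt, alt_count, 0), nrow = nrow(gt))  # variants x samples
  ids <- colnames(gt)
  map <- data.frame(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                    id = fix[, "ID"], ref = fix[, "REF"], alt = fix[, "ALT"],
                    stringsAsFactors = FALSE)
  blank <- is.na(map$id) | map$id == "."
  map$id[blank] <- sprintf("%s:%d", map$chrom[blank], map$pos[blank])
  genotype_matrix(t(dosage), map, ids)
}

#' @rdname write_genotypes
#' @export
write_vcf <- function(G, path) {
  gt_code <- c("0/0", "0/1", "1/1")
  body <- apply(G$dosage, 2, function(col) {
    out <- rep("./.", length(col))
    ok <- !is.na(col)
    out[ok] <- gt_code[col[ok] + 1L]
    out
  })
  body <- matrix(body, nrow = n_individuals(G))
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", G$ids), collapse = "\t"))
  rows <- paste(G$map$chrom, G$map$pos, G$map$id, G$map$ref, G$map$alt,
                ".", "PASS", ".", "GT",
                apply(body, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(lines, rows), path)
  invisible(path)
}

#' Write/read a phenotype table as TSV
#'
#' Header convention: `id site sex <covariates/traits...>`.
#'
#' @param table cohort data.frame.
#' @param path TSV path.
#' @return the table (read) or the path, invisibly (write).
#' @export
write_pheno_tsv <- function(table, path) {
  data.table::fwrite(table, path, sep = "\t", na = "NA")
  invisible(path)
}

#' @rdname write_pheno_tsv
#' @export
read_pheno_tsv <- function(path) {
  data.table::fread(path, sep = "\t", data.table = FALSE, na.strings = "NA")
}
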