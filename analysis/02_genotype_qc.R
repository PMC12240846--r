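#!/usr/bin/env Rscript
# Stage 2: read the cohort genotypes back from disk and apply the three SNP
# filters (missingness <= 10%, MAF >= 0.5%, HWE p >= 1e-10, all inclusive).
# The filtered set is written as a fresh PLINK fileset plus a per-SNP
# statistics table and a QC log with per-filter removal counts.

library(hsqtl)

in_dir <- "results/cohort"
out_dir <- "results/qc"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

G <- read_genotypes(file.path(in_dir, "genotypes"), format = "plink")
G <- snp_stats(G)
data.table::fwrite(G$map, file.path(out_dir, "snp_stats.tsv"), sep = "\t")

Gf <- filter_snps(G)   # logs the removal counts
log <- attr(Gf, "qc_log")
jsonlite::write_json(log, file.path(out_dir, "qc_log.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
write_plink(Gf, file.path(out_dir, "genotypes_filtered"))
message(sprintf("QC: retained %d of %d SNPs", log$n_retained, log$n_input))
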