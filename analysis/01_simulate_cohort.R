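#!/usr/bin/env Rscript
# Stage 1: build the synthetic heterogeneous-stock cohort that the rest of
# the workflow analyses. Two behavioral traits are simulated over mosaic
# genomes: "consumption" carries two planted QTLs (3% of variance each, the
# effect size HS cohorts of this design are powered for) and "break_point"
# carries one; both sit on a 25% polygenic background with site and sex
# structure. Genotypes go out as a PLINK fileset, phenotypes as TSV, and the
# planted truth as JSON so later stages can be checked against it.

library(hsqtl)

out_dir <- "results/cohort"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
seed <- 20260925

cfg <- sim_config(
  seed = seed,
  n_individuals = 400,
  chrom_lengths = c(chr1 = 30e6, chr2 = 30e6, chr3 = 30e6, chr4 = 30e6),
  snp_density = 25,
  qtl_specs = list(planted_qtl("chr1", 12e6, 0.03),
                   planted_qtl("chr2", 20e6, 0.03)),
  h2_poly = 0.25)

founders <- simulate_founders(cfg)
G <- simulate_mosaic_genotypes(founders, cfg)
message(sprintf("simulated %d animals x %d SNPs over %d chromosomes",
                n_individuals(G), n_snps(G), length(cfg$chrom_lengths)))

pheno <- simulate_phenotypes(G, cfg, trait_name = "consumption")
truth_consumption <- attr(pheno, "ground_truth")

cfg_bp <- cfg
cfg_bp$qtl_specs <- list(planted_qtl("chr3", 15e6, 0.03))
bp <- simulate_phenotypes(G, cfg_bp, trait_name = "break_point",
                          cohort = pheno)
truth_break_point <- attr(bp, "ground_truth")
pheno$break_point <- bp$break_point

write_plink(G, file.path(out_dir, "genotypes"))
write_vcf(G, file.path(out_dir, "genotypes.vcf"))
write_pheno_tsv(pheno, file.path(out_dir, "phenotypes.tsv"))
jsonlite::write_json(
  list(seed = seed,
       consumption = truth_consumption, break_point = truth_break_point),
  file.path(out_dir, "ground_truth.json"),
  auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)

# a synthetic local annotation table (labelled synthetic: there is no live
# expression-QTL resource here): a few eQTL/sQTL/coding entries near the
# planted consumption QTL plus distant decoys
truth_snp <- truth_consumption$qtls$snp_id[1]
near <- G$map[G$map$chrom == "chr1" &
                abs(G$map$pos - truth_consumption$qtls$pos[1]) < 1e6, ]
ann <- data.frame(
  feature_id = c("GeneA", "GeneB", "GeneC", "GeneD"),
  tissue = c("NAcc", "PrL", "BLA", "OFC"),
  modality = c("eQTL", "sQTL", "coding", "eQTL"),
  snp_id = c(near$id[1], near$id[nrow(near)], truth_snp, "chr1:29000000"),
  chrom = "chr1",
  pos = c(near$pos[1], near$pos[nrow(near)],
          truth_consumption$qtls$pos[1], 29000000),
  stringsAsFactors = FALSE)
data.table::fwrite(ann, file.path(out_dir, "annotation_synthetic.tsv"),
                   sep = "\t")
message("wrote cohort files under ", out_dir)
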