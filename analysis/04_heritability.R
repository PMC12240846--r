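#!/usr/bin/env Rscript
# Stage 4: SNP heritability. Builds the full and leave-one-chromosome-out
# genetic relatedness matrices from the filtered genotypes and fits the
# single-component GREML model to each prepared trait, reporting h2 with its
# standard error and the boundary likelihood-ratio p-value against h2 = 0.

library(hsqtl)

out_dir <- "results/h2"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

G <- read_genotypes("results/qc/genotypes_filtered", format = "plink")
prepared <- read_pheno_tsv("results/pheno/prepared.tsv")
stopifnot(identical(prepared$id, G$ids))

grms <- compute_loco_grms(G)
write_grm_tsv(grms$full, file.path(out_dir, "grm_full"))

h2_tab <- do.call(rbind, lapply(c("consumption", "break_point"), function(tr) {
  fit <- fit_greml(prepared[[tr]], grms$full)
  message(sprintf("%s: h2 = %.3f (SE %.3f), LRT p = %.3g%s", tr, fit$h2,
                  fit$se_h2, fit$lrt_p,
                  if (fit$lrt_p < 0.05) " *" else ""))
  data.frame(trait = tr, h2 = fit$h2, se_h2 = fit$se_h2, lrt_p = fit$lrt_p,
             sigma2_g = fit$sigma2_g, sigma2_e = fit$sigma2_e, n = fit$n,
             converged = fit$converged)
}))
data.table::fwrite(h2_tab, file.path(out_dir, "heritability.tsv"), sep = "\t")
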