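#!/usr/bin/env Rscript
# Assemble the three report grids (counts with percents, full-set R2,
# resampled mean +/- SD) and the headline summary: proportion of variance
# explained by all markers vs covariates only, and the percent of
# covariate-adjusted variance attributable to the marker regression.

library(wgrpart)

out <- "results/analysis"

per_set <- read.delim(file.path(out, "per_set_r2.tsv"))
resample <- read.delim(file.path(out, "resample_summary.tsv"))
ann <- read.delim(file.path(out, "variant_annotation.tsv"))
ann$maf_class <- factor(ann$maf_class,
                        levels = c("very_rare", "rare", "common"))
ann$region_class <- factor(ann$region_class,
                           levels = c("genic", "flanking", "outside"))
sets <- build_marker_sets(ann)

res_list <- lapply(seq_len(nrow(resample)), function(i)
  list(r2_mean = resample$r2_mean[i], r2_sd = resample$r2_sd[i]))
names(res_list) <- resample$set_name

tabs <- report_tables(per_set, res_list, sets,
                      dir = file.path(out, "report"))
cat("\nVariant counts (percent of grand total):\n")
print(tabs$counts, row.names = FALSE)
cat("\nFull-set R2:\n")
print(tabs$r2_full, row.names = FALSE)
cat("\nResampled R2 (mean +/- SD):\n")
print(tabs$r2_resampled, row.names = FALSE)

r2_cov <- per_set$r2_full[per_set$set_name == "covariates_only"]
r2_all <- per_set$r2_full[per_set$set_name == "all_all"]
cat(sprintf("\nR2 covariates only: %.3f\nR2 all markers:     %.3f\n",
            r2_cov, r2_all))
cat(sprintf("Percent of covariate-adjusted variance from markers: %.1f%%\n",
            variance_explained_ratio(r2_all, r2_cov)))
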