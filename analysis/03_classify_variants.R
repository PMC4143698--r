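#!/usr/bin/env Rscript
# QC/biallelic filter, minor-allele frequency on the analysis cohort, and
# genic vs +/- 50 kb flanking annotation; builds the 12 marker sets and the
# region-by-MAF cross-tabulation.

library(wgrpart)

dat <- "results/analysis/data"
out <- "results/analysis"

vc <- read_genotype_vcf(file.path(dat, "genotypes.vcf"))
genes <- read_bed(file.path(dat, "genes.bed"))
cohort_tab <- read.delim(file.path(out, "cohort.tsv"))

flt <- filter_variants(vc$variants)
cat(sprintf("variants: %d in = %d retained + %d excluded (%s)\n",
            nrow(vc$variants), nrow(flt$variants), flt$n_excluded,
            paste(names(flt$reasons), flt$reasons, sep = "=",
                  collapse = ", ")))

G <- vc$genotypes[match(cohort_tab$subject_id, rownames(vc$genotypes)),
                  flt$idx, drop = FALSE]
ann <- annotate_variants(flt$variants, G, genes, flank_bp = 50000)
sets <- build_marker_sets(ann)
print(sets)

write.table(ann, file.path(out, "variant_annotation.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(sets$crosstab, file.path(out, "crosstab.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
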