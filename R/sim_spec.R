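#' Default minor-allele-frequency mixture
#'
#' Three MAF classes with target fractions matching the frequency spectrum of
#' a deep-sequenced blood-pressure gene panel: 64% very rare (MAF < 1%),
#' 13% rare (1--5%) and 23% common (> 5%). True allele frequencies are drawn
#' uniformly from ranges pulled slightly inside the class boundaries so that
#' generating labels are recoverable from realized sample frequencies.
#'
#' @return A data.frame with columns `class`, `fraction`, `lo`, `hi`.
#' @export
default_maf_mix <- function() {
  data.frame(
    class    = c("very_rare", "rare", "common"),
    fraction = c(0.64, 0.13, 0.23),
    lo       = c(0.0010, 0.0120, 0.0600),
    hi       = c(0.0090, 0.0480, 0.4500),
    stringsAsFactors = FALSE
  )
}

#' Simulation specification
#'
#' Bundles every parameter of the synthetic-data generator. Defaults emulate
#' the study conditions of a family cohort with deep sequence in and around
#' 31 hypertension-pathway genes: n = 395 subjects, ~50k variants whose MAF
#' spectrum is dominated by very rare alleles, variants placed inside genes
#' (34%) or within +/- 50 kb flanks (66%), a log-normal systolic blood
#' pressure driven by age, sex, smoking and medication plus additive marker
#' effects at a chosen variance share, and up to 4 longitudinal visits with
#' missingness.
#'
#' @param n_subjects Number of subjects.
#' @param n_genes Number of gene models to place.
#' @param gene_length_bp Length of each gene body, bp.
#' @param flank_bp Flank width on each side of a gene, bp.
#' @param chrom_length_bp Length of the single synthetic chromosome, bp.
#' @param maf_mix data.frame (`class`, `fraction`, `lo`, `hi`) of MAF classes;
#'   fractions must sum to 1 and ranges must be disjoint subintervals of
#'   (0, 0.5].
#' @param n_variants Total number of variants.
#' @param genic_fraction,flanking_fraction Target fractions of variants placed
#'   inside gene bodies and inside flanks; any remainder is placed outside
#'   both.
#' @param n_causal Number of causal markers (`NULL` = all markers causal).
#' @param h2_markers Variance share of the additive marker term on the log
#'   scale, in \[0, 1).
#' @param covariate_effects Named vector of true covariate effects on logSBP
#'   (age per year, sex, smoking, medication). Defaults give a covariate
#'   variance share of about 0.19.
#' @param resid_sd Residual SD of logSBP (log-mmHg).
#' @param mu_log Baseline mean of logSBP; default `log(120)` mmHg.
#' @param n_visits Number of longitudinal visits (max 4 used downstream).
#' @param visit_missing_prob Probability that a (subject, visit) SBP record is
#'   missing; a scalar or one probability per visit.
#' @param geno_missing_prob Probability that a genotype call is missing.
#' @param qc_fail_frac Fraction of variants flagged as failing QC.
#' @param triallelic_frac Fraction of variants flagged as having > 2 alleles.
#'   Together with `qc_fail_frac` this emulates the ~8% of variants dropped
#'   by the QC/biallelic filter.
#' @param pedigree_mode If `TRUE`, genotypes are gene-dropped through generic
#'   nuclear families instead of being drawn iid under Hardy-Weinberg.
#' @param family_kids Number of offspring per nuclear family in pedigree mode.
#' @param seed Integer seed; required for reproducible generation.
#'
#' @return A list of class `sim_spec`.
#' @export
sim_spec <- function(n_subjects = 395,
                     n_genes = 31,
                     gene_length_bp = 50000,
                     flank_bp = 50000,
                     chrom_length_bp = 1e7,
                     maf_mix = default_maf_mix(),
                     n_variants = 49839,
                     genic_fraction = 0.34,
                     flanking_fraction = 0.66,
                     n_causal = NULL,
                     h2_markers = 0.3,
                     covariate_effects = c(age = 0.0048, sex = 0.066,
                                           smoke = 0.054, bpmed = 0.060),
                     resid_sd = 0.12,
                     mu_log = log(120),
                     n_visits = 4,
                     visit_missing_prob = 0.10,
                     geno_missing_prob = 0.005,
                     qc_fail_frac = 0.06,
                     triallelic_frac = 0.023,
                     pedigree_mode = FALSE,
                     family_kids = 3,
                     seed = 1L) {
  stopifnot(is.data.frame(maf_mix),
            all(c("class", "fraction", "lo", "hi") %in% names(maf_mix)))
  if (abs(sum(maf_mix$fraction) - 1) > 1e-12)
    stop("maf_mix fractions must sum to 1 (within 1e-12)")
  if (any(maf_mix$lo <= 0) || any(maf_mix$hi > 0.5) ||
      any(maf_mix$lo >= maf_mix$hi))
    stop("maf_mix ranges must be subintervals of (0, 0.5]")
  o <- order(maf_mix$lo)
  if (any(maf_mix$lo[o][-1] < maf_mix$hi[o][-nrow(maf_mix)]))
    stop("maf_mix ranges must be disjoint")
  if (h2_markers < 0 || h2_markers >= 1)
    stop("h2_markers must lie in [0, 1)")
  if (resid_sd <= 0) stop("resid_sd must be positive")
  if (genic_fraction < 0 || flanking_fraction < 0 ||
      genic_fraction + flanking_fraction > 1 + 1e-12)
    stop("genic_fraction + flanking_fraction must not exceed 1")
  if (!is.null(n_causal) && (n_causal < 0 || n_causal > n_variants))
    stop("n_causal must lie in [0, n_variants]")
  if (length(covariate_effects) != 4)
    stop("covariate_effects must have 4 entries (age, sex, smoke, bpmed)")

  spec <- list(
    n_subjects = as.integer(n_subjects), n_genes = as.integer(n_genes),
    gene_length_bp = as.integer(gene_length_bp),
    flank_bp = as.integer(flank_bp),
    chrom_length_bp = as.numeric(chrom_length_bp),
    maf_mix = maf_mix, n_variants = as.integer(n_variants),
    genic_fraction = genic_fraction, flanking_fraction = flanking_fraction,
    n_causal = if (is.null(n_causal)) as.integer(n_variants)
               else as.integer(n_causal),
    h2_markers = h2_markers, covariate_effects = covariate_effects,
    resid_sd = resid_sd, mu_log = mu_log,
    n_visits = as.integer(n_visits),
    visit_missing_prob = visit_missing_prob,
    geno_missing_prob = geno_missing_prob,
    qc_fail_frac = qc_fail_frac, triallelic_frac = triallelic_frac,
    pedigree_mode = isTRUE(pedigree_mode),
    family_kids = as.integer(family_kids),
    seed = as.integer(seed)
  )
  class(spec) <- "sim_spec"
  spec
}

# Analytic covariate variances under the generator's covariate distributions:
# age ~ U(30, 70), sex ~ Bern(0.5), smoking ~ Bern(0.2), medication ~
# Bern(0.3). Used to solve the marker effect-size scale for a target h2.
covariate_variances <- function() {
  c(age = (70 - 30)^2 / 12, sex = 0.25, smoke = 0.2 * 0.8, bpmed = 0.3 * 0.7)
}

#' @export
print.sim_spec <- function(x, ...) {
  cat("Simulation spec:", x$n_subjects, "subjects,", x$n_variants,
      "variants,", x$n_genes, "genes (+/-", x$flank_bp, "bp flanks)\n")
  cat("  MAF mix:",
      paste(sprintf("%s %.0f%%", x$maf_mix$class, 100 * x$maf_mix$fraction),
            collapse = ", "), "\n")
  cat("  marker variance share:", x$h2_markers,
      "| residual sd(logSBP):", x$resid_sd, "\n")
  invisible(x)
}

# Deterministic allocation of class counts: round(fraction * n) with the
# rounding remainder assigned to the largest class, so counts are exact.
allocate_counts <- function(fractions, n) {
  counts <- round(fractions * n)
  counts[which.max(fractions)] <- counts[which.max(fractions)] + (n - sum(counts))
  as.integer(counts)
}
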