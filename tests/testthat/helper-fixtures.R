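# Small in-code fixtures shared across test files.

# A compact simulated data set: 150 subjects, 600 variants around 4 genes.
small_spec <- function(seed = 42, ...) {
  sim_spec(n_subjects = 150, n_variants = 600, n_genes = 4,
           gene_length_bp = 20000, flank_bp = 50000,
           chrom_length_bp = 1e6, n_causal = 150, seed = seed, ...)
}

# Clean spec for estimation tests: no QC failures, no genotype missingness,
# every marker causal.
clean_spec <- function(n_subjects, n_variants, seed, ...) {
  args <- list(n_subjects = n_subjects, n_variants = n_variants,
               n_genes = 3, gene_length_bp = 20000, flank_bp = 50000,
               chrom_length_bp = 1e6, n_causal = n_variants,
               qc_fail_frac = 0, triallelic_frac = 0, geno_missing_prob = 0,
               visit_missing_prob = 0, seed = seed)
  args <- utils::modifyList(args, list(...))
  do.call(sim_spec, args)
}

# Hand-built longitudinal phenotype rows.
pheno_row <- function(subject, visit, sbp, age = 50, sex = 1, smoke = 0,
                      bpmed = 0) {
  data.frame(subject_id = subject, visit = visit, SBP = sbp, age = age,
             sex = sex, smoke = smoke, bpmed = bpmed,
             stringsAsFactors = FALSE)
}

# Brute-force region classifier: per-variant scan over all genes.
# Gene intervals 0-based half-open; variant positions 1-based.
brute_force_region <- function(pos, genes, flank_bp) {
  vapply(pos, function(p) {
    genic <- any(p >= genes$start + 1 & p <= genes$end)
    if (genic) return("genic")
    near <- any(p >= genes$start + 1 - flank_bp & p <= genes$end + flank_bp)
    if (near) "flanking" else "outside"
  }, character(1))
}

# Ridge / mixed-model-equations solution with fixed effects unpenalized and
# markers penalized by lambda = sigma_eps2 / sigma_beta2.
ridge_solution <- function(y, W, X, lambda) {
  M <- cbind(W, X)
  q <- ncol(W)
  A <- crossprod(M)
  diag(A)[(q + 1):ncol(M)] <- diag(A)[(q + 1):ncol(M)] + lambda
  drop(solve(A, crossprod(M, y)))
}
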