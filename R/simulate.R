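#' Place non-overlapping gene models on a synthetic chromosome
#'
#' Genes are dropped into equal-width slots so that each gene body plus its
#' two flanks fits entirely inside its slot; genic and flanking footprints of
#' different genes therefore never overlap. Intervals are 0-based half-open
#' (BED convention).
#'
#' @param spec A [sim_spec()].
#' @return A data.frame (`chrom`, `start`, `end`, `name`); empty if
#'   `n_genes == 0`.
#' @export
simulate_gene_models <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  if (spec$n_genes == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      stringsAsFactors = FALSE))
  slot <- floor(spec$chrom_length_bp / spec$n_genes)
  footprint <- spec$gene_length_bp + 2 * spec$flank_bp
  if (footprint > slot)
    stop(sprintf(paste0("cannot pack %d genes of %d bp with %d bp flanks on ",
                        "a %.0f bp chromosome (need %d bp per gene, have %d)"),
                 spec$n_genes, spec$gene_length_bp, spec$flank_bp,
                 spec$chrom_length_bp, footprint, slot))
  # uniform jitter of the gene body within the flank-padded slot
  offset <- spec$flank_bp +
    floor(stats::runif(spec$n_genes) * (slot - footprint + 1))
  start <- (seq_len(spec$n_genes) - 1) * slot + offset
  data.frame(
    chrom = "chrS1",
    start = as.integer(start),
    end   = as.integer(start + spec$gene_length_bp),
    name  = sprintf("GENE%03d", seq_len(spec$n_genes)),
    stringsAsFactors = FALSE
  )
}

# Map flat offsets into per-gene genic positions (0-based).
# pool: for each gene, gene_length_bp consecutive offsets.
genic_position <- function(offsets, genes, gene_length) {
  g <- (offsets - 1) %/% gene_length + 1
  genes$start[g] + (offsets - 1) %% gene_length
}

# Map flat offsets into flank positions (0-based): for each gene, first the
# left flank [start - flank, start), then the right flank [end, end + flank).
flank_position <- function(offsets, genes, flank) {
  per_gene <- 2 * flank
  g <- (offsets - 1) %/% per_gene + 1
  within <- (offsets - 1) %% per_gene
  left <- within < flank
  ifelse(left, genes$start[g] - flank + within,
               genes$end[g] + (within - flank))
}

#' Simulate genotypes and a variant table
#'
#' Allocates exact per-class variant counts (MAF class and region class are
#' rounded deterministically, remainder to the largest class), draws true
#' allele frequencies uniformly within each class's range, places variants
#' at distinct positions inside gene bodies, inside flanks, or outside both,
#' and draws dosages either iid under Hardy-Weinberg equilibrium or by
#' gene-dropping through generic nuclear pedigrees. Generating labels (true
#' MAF class, true region class, true frequency) are retained for round-trip
#' tests. QC-fail and triallelic flags are sprinkled at the spec's rates.
#'
#' @param spec A [sim_spec()].
#' @param genes Gene-interval table from [simulate_gene_models()].
#' @return A list with `genotypes` (n_subjects x n_variants integer matrix of
#'   dosages 0/1/2 with `NA` for missing calls) and `variants` (data.frame
#'   with positions, alleles, true frequencies and generating labels).
#' @export
simulate_genotypes <- function(spec, genes) {
  stopifnot(inherits(spec, "sim_spec"))
  if (spec$n_subjects <= 0) stop("n_subjects must be positive")
  if (nrow(spec$maf_mix) == 0) stop("maf_mix is empty")
  if (any(spec$maf_mix$lo <= 0))
    stop("maf_mix ranges must not touch 0")
  n <- spec$n_variants

  maf_counts <- allocate_counts(spec$maf_mix$fraction, n)
  maf_class <- rep(spec$maf_mix$class, maf_counts)

  region_frac <- c(genic = spec$genic_fraction,
                   flanking = spec$flanking_fraction,
                   outside = max(0, 1 - spec$genic_fraction -
                                      spec$flanking_fraction))
  region_counts <- allocate_counts(region_frac, n)
  region <- sample(rep(names(region_frac), region_counts))

  # distinct positions within each region pool
  pos0 <- integer(n)
  gene_of <- rep(NA_character_, n)
  if (region_counts[1] > 0) {
    if (nrow(genes) == 0) stop("genic variants requested but no genes")
    pool <- nrow(genes) * spec$gene_length_bp
    if (region_counts[1] > pool) stop("more genic variants than genic bp")
    off <- sample.int(pool, region_counts[1])
    idx <- which(region == "genic")
    pos0[idx] <- genic_position(off, genes, spec$gene_length_bp)
    gene_of[idx] <- genes$name[(off - 1) %/% spec$gene_length_bp + 1]
  }
  if (region_counts[2] > 0) {
    if (nrow(genes) == 0) stop("flanking variants requested but no genes")
    pool <- nrow(genes) * 2 * spec$flank_bp
    if (region_counts[2] > pool) stop("more flanking variants than flank bp")
    off <- sample.int(pool, region_counts[2])
    idx <- which(region == "flanking")
    pos0[idx] <- flank_position(off, genes, spec$flank_bp)
    gene_of[idx] <- genes$name[(off - 1) %/% (2 * spec$flank_bp) + 1]
  }
  if (region_counts[3] > 0) {
    # complement of all footprints, as a flat pool
    fp_start <- genes$start - spec$flank_bp
    fp_end <- genes$end + spec$flank_bp
    gap_start <- c(0, fp_end)
    gap_end <- c(fp_start, spec$chrom_length_bp)
    keep <- gap_end > gap_start
    gap_start <- gap_start[keep]; gap_end <- gap_end[keep]
    gap_len <- gap_end - gap_start
    if (region_counts[3] > sum(gap_len))
      stop("more outside variants than available outside bp")
    off <- sample.int(sum(gap_len), region_counts[3])
    cum <- cumsum(gap_len)
    gp <- findInterval(off - 1, c(0, cum), rightmost.closed = FALSE)
    pos0[region == "outside"] <- gap_start[gp] + (off - 1) -
      c(0, cum)[gp]
  }

  freq <- numeric(n)
  for (k in seq_len(nrow(spec$maf_mix))) {
    idx <- maf_class == spec$maf_mix$class[k]
    freq[idx] <- stats::runif(sum(idx), spec$maf_mix$lo[k],
                              spec$maf_mix$hi[k])
  }

  G <- if (spec$pedigree_mode) {
    gene_drop_genotypes(spec$n_subjects, freq, spec$family_kids)
  } else {
    matrix(stats::rbinom(spec$n_subjects * n, 2, rep(freq, each = spec$n_subjects)),
           nrow = spec$n_subjects, ncol = n)
  }
  if (spec$geno_missing_prob > 0) {
    G[stats::runif(length(G)) < spec$geno_missing_prob] <- NA_integer_
  }

  qc_pass <- stats::runif(n) >= spec$qc_fail_frac
  biallelic <- stats::runif(n) >= spec$triallelic_frac

  ord <- order(pos0)
  variants <- data.frame(
    variant_id = sprintf("V%06d", seq_len(n)),
    chrom = "chrS1",
    pos = pos0[ord] + 1L,           # 1-based for VCF
    ref = "A", alt = "G",
    true_freq = freq[ord],
    true_maf_class = maf_class[ord],
    true_region = region[ord],
    true_gene = gene_of[ord],
    qc_pass = qc_pass[ord],
    biallelic = biallelic[ord],
    stringsAsFactors = FALSE
  )
  G <- G[, ord, drop = FALSE]
  dimnames(G) <- list(sprintf("S%04d", seq_len(spec$n_subjects)),
                      variants$variant_id)
  list(genotypes = G, variants = variants)
}

# Gene-dropping through nuclear families: founders (2 per family) drawn under
# HWE, each offspring receives one uniformly chosen allele from each parent,
# independently per variant. Induces sib/parent-offspring relatedness only.
gene_drop_genotypes <- function(n_subjects, freq, kids) {
  fam_size <- 2L + kids
  n_fam <- ceiling(n_subjects / fam_size)
  p <- length(freq)
  G <- matrix(0L, nrow = n_fam * fam_size, ncol = p)
  for (f in seq_len(n_fam)) {
    rows <- (f - 1L) * fam_size
    mo <- stats::rbinom(p, 2, freq)
    fa <- stats::rbinom(p, 2, freq)
    G[rows + 1L, ] <- mo
    G[rows + 2L, ] <- fa
    for (k in seq_len(fam_size - 2L)) {
      # transmitted allele is 1 w.p. dosage/2
      G[rows + 2L + k, ] <- stats::rbinom(p, 1, mo / 2) +
        stats::rbinom(p, 1, fa / 2)
    }
  }
  G[seq_len(n_subjects), , drop = FALSE]
}

#' Build the generating (true) model for a simulated genotype matrix
#'
#' Selects `n_causal` markers and draws their effects from
#' `N(0, sigma_beta_true^2)`, with the effect variance solved so that the
#' expected marker variance share of logSBP equals `h2_markers`:
#' `sigma_beta^2 = V_m / sum_l var(x_l)` over causal markers, where
#' `V_m = h2 / (1 - h2) * (V_covariates + resid_sd^2)` and the column
#' variances are the realized variances of the centered dosages.
#'
#' @param spec A [sim_spec()].
#' @param X Dosage matrix from [simulate_genotypes()].
#' @return A list of class `true_model` (`mu_true`, `gamma_true`,
#'   `beta_true`, `sigma_eps_true`, `causal_idx`, `sigma_beta_true`).
#' @export
make_true_model <- function(spec, X) {
  stopifnot(inherits(spec, "sim_spec"))
  p <- ncol(X)
  if (p != spec$n_variants)
    stop("X has ", p, " columns but spec expects ", spec$n_variants)
  beta <- numeric(p)
  causal <- integer(0)
  sigma_beta <- 0
  if (spec$h2_markers > 0 && spec$n_causal > 0) {
    var_cov <- sum(spec$covariate_effects^2 * covariate_variances())
    v_target <- spec$h2_markers / (1 - spec$h2_markers) *
      (var_cov + spec$resid_sd^2)
    causal <- sort(sample.int(p, spec$n_causal))
    cv <- apply(X[, causal, drop = FALSE], 2,
                function(g) stats::var(g[!is.na(g)]))
    sum_cv <- sum(cv)
    if (sum_cv <= 0) stop("causal markers are all monomorphic")
    sigma_beta <- sqrt(v_target / sum_cv)
    beta[causal] <- stats::rnorm(spec$n_causal, 0, sigma_beta)
  }
  structure(list(mu_true = spec$mu_log,
                 gamma_true = spec$covariate_effects,
                 beta_true = beta,
                 sigma_eps_true = spec$resid_sd,
                 causal_idx = causal,
                 sigma_beta_true = sigma_beta),
            class = "true_model")
}

#' Simulate longitudinal phenotypes
#'
#' Draws covariates (age uniform on 30--70 years, sex/smoking/medication
#' Bernoulli with rates 0.5/0.2/0.3), computes the log-scale response
#' `logSBP = mu + Z gamma + X_c beta + eps` with `eps ~ N(0, sigma_eps^2)`
#' drawn independently per visit, exponentiates to SBP in mmHg, and applies
#' visit-level missingness. Age advances one year per visit. Genotypes are
#' centered on twice the realized allele-1 frequency (missing calls imputed
#' to the mean) before the marker term is formed.
#'
#' @param spec A [sim_spec()].
#' @param model A [make_true_model()] result.
#' @param X Dosage matrix conformable with `model$beta_true`.
#' @return A list: `phenotypes` (long data.frame `subject_id`, `visit`,
#'   `SBP`, `age`, `sex`, `smoke`, `bpmed`), and `realized` holding the
#'   per-subject linear-predictor components, per-visit residuals, and the
#'   realized marker variance share at visit 1.
#' @export
simulate_phenotypes <- function(spec, model, X) {
  stopifnot(inherits(spec, "sim_spec"), inherits(model, "true_model"))
  if (model$sigma_eps_true <= 0) stop("resid_sd must be positive")
  if (length(model$beta_true) != ncol(X))
    stop("beta_true not conformable with genotype matrix")
  n <- nrow(X)

  age <- round(stats::runif(n, 30, 70), 1)
  sex <- stats::rbinom(n, 1, 0.5)
  smoke <- stats::rbinom(n, 1, 0.2)
  bpmed <- stats::rbinom(n, 1, 0.3)

  cg <- center_genotypes(X)
  g_mark <- as.numeric(cg$centered %*% model$beta_true)

  visits <- seq_len(spec$n_visits)
  p_miss <- rep(spec$visit_missing_prob, length.out = spec$n_visits)
  resid <- matrix(stats::rnorm(n * spec$n_visits, 0, model$sigma_eps_true),
                  nrow = n)
  rows <- vector("list", spec$n_visits)
  for (v in visits) {
    age_v <- age + (v - 1)
    Zg <- model$gamma_true[1] * age_v + model$gamma_true[2] * sex +
      model$gamma_true[3] * smoke + model$gamma_true[4] * bpmed
    log_sbp <- model$mu_true + Zg + g_mark + resid[, v]
    sbp <- exp(log_sbp)
    sbp[stats::runif(n) < p_miss[v]] <- NA_real_
    rows[[v]] <- data.frame(subject_id = rownames(X) %||%
                              sprintf("S%04d", seq_len(n)),
                            visit = v, SBP = sbp, age = age_v, sex = sex,
                            smoke = smoke, bpmed = bpmed,
                            stringsAsFactors = FALSE)
  }
  pheno <- do.call(rbind, rows)

  Zg1 <- model$gamma_true[1] * age + model$gamma_true[2] * sex +
    model$gamma_true[3] * smoke + model$gamma_true[4] * bpmed
  y1 <- model$mu_true + Zg1 + g_mark + resid[, 1]
  realized <- list(
    linpred_cov = Zg1, linpred_markers = g_mark, resid = resid,
    var_markers = stats::var(g_mark), var_cov = stats::var(Zg1),
    var_resid = stats::var(resid[, 1]),
    marker_share = stats::var(g_mark) / stats::var(y1),
    log_sbp_visit1 = y1
  )
  list(phenotypes = pheno, realized = realized)
}

#' One-call synthetic data set
#'
#' Runs [simulate_gene_models()], [simulate_genotypes()],
#' [make_true_model()] and [simulate_phenotypes()] under a single seed.
#'
#' @param spec A [sim_spec()].
#' @return A list: `genes`, `genotypes`, `variants`, `phenotypes`, `truth`
#'   (the true model) and `realized`.
#' @export
simulate_dataset <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  genes <- simulate_gene_models(spec)
  geno <- simulate_genotypes(spec, genes)
  truth <- make_true_model(spec, geno$genotypes)
  ph <- simulate_phenotypes(spec, truth, geno$genotypes)
  list(genes = genes, genotypes = geno$genotypes, variants = geno$variants,
       phenotypes = ph$phenotypes, truth = truth, realized = ph$realized)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
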