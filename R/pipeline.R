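#' Default pipeline configuration
#'
#' Mirrors the headline analysis settings: 50 kb flanks, 40,000 Gibbs
#' iterations with 15,000 burn-in, and 500-marker x 500-replicate
#' resampling. `ci_profile = TRUE` scales the stochastic stages down
#' (2,000/500 chains, 50-marker x 20-replicate resampling) for quick runs.
#'
#' @param outdir Output directory.
#' @param master_seed Master seed; every random stage receives a sub-seed
#'   derived from it.
#' @param simulate A [sim_spec()] describing the synthetic data, or `NULL`
#'   to read `paths` instead.
#' @param paths List with `vcf`, `genes`, `phenotypes` file paths (used when
#'   `simulate` is `NULL`).
#' @param flank_bp Flank width for region annotation.
#' @param prior List: `df`, `partition_r2` for [default_prior()].
#' @param mcmc [mcmc_config()] for the per-set fits.
#' @param resample List: `size`, `reps`, `mcmc` for [resample_fixed_size()].
#' @param maf_cohort `"analysis"` (MAF computed on the analysis cohort,
#'   default) or `"all"` (all genotyped subjects).
#' @param drop_monomorphic Drop variants with MAF 0 (they contribute nothing
#'   after centering); default keeps them.
#' @param ci_profile Scale MCMC and resampling down for quick runs.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir, master_seed = 1L, simulate = NULL,
                            paths = NULL, flank_bp = 50000,
                            prior = list(df = 5, partition_r2 = 0.5),
                            mcmc = mcmc_config(),
                            resample = list(size = 500, reps = 500,
                                            mcmc = mcmc_config(n_iter = 5000,
                                                               burn_in = 1000)),
                            maf_cohort = c("analysis", "all"),
                            drop_monomorphic = FALSE,
                            ci_profile = FALSE) {
  maf_cohort <- match.arg(maf_cohort)
  if (isTRUE(ci_profile)) {
    mcmc <- mcmc_config(n_iter = 2000, burn_in = 500)
    resample <- list(size = 50, reps = 20,
                     mcmc = mcmc_config(n_iter = 2000, burn_in = 500))
  }
  cfg <- list(outdir = outdir, master_seed = as.integer(master_seed),
              simulate = simulate, paths = paths, flank_bp = flank_bp,
              prior = prior, mcmc = mcmc, resample = resample,
              maf_cohort = maf_cohort,
              drop_monomorphic = isTRUE(drop_monomorphic),
              ci_profile = isTRUE(ci_profile))
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
  cfg
}

#' Load a pipeline configuration from YAML
#' @param path YAML file mirroring the [pipeline_config()] fields; a
#'   `simulate` block holds [sim_spec()] arguments.
#' @return A validated `pipeline_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim <- if (!is.null(raw$simulate)) do.call(sim_spec, raw$simulate)
  mc <- if (!is.null(raw$mcmc)) do.call(mcmc_config, raw$mcmc)
        else mcmc_config()
  res <- raw$resample %||% list(size = 500, reps = 500)
  res$mcmc <- if (!is.null(res$mcmc)) do.call(mcmc_config, res$mcmc)
              else mcmc_config(n_iter = 5000, burn_in = 1000)
  pipeline_config(outdir = raw$outdir %||% "results",
                  master_seed = raw$master_seed %||% 1L,
                  simulate = sim, paths = raw$paths,
                  flank_bp = raw$flank_bp %||% 50000,
                  prior = raw$prior %||% list(df = 5, partition_r2 = 0.5),
                  mcmc = mc, resample = res,
                  maf_cohort = raw$maf_cohort %||% "analysis",
                  drop_monomorphic = raw$drop_monomorphic %||% FALSE,
                  ci_profile = raw$ci_profile %||% FALSE)
}

validate_config <- function(cfg) {
  problems <- character(0)
  need <- function(cond, path, msg)
    if (!cond) problems <<- c(problems, paste0(path, ": ", msg))
  need(is.character(cfg$outdir) && nzchar(cfg$outdir), "outdir",
       "must be a non-empty path")
  need(is.integer(cfg$master_seed), "master_seed", "must be an integer")
  if (is.null(cfg$simulate)) {
    need(!is.null(cfg$paths$vcf), "paths.vcf",
         "required when no simulate block is given")
    need(!is.null(cfg$paths$genes), "paths.genes",
         "required when no simulate block is given")
    need(!is.null(cfg$paths$phenotypes), "paths.phenotypes",
         "required when no simulate block is given")
  } else {
    need(inherits(cfg$simulate, "sim_spec"), "simulate",
         "must be a sim_spec")
  }
  need(cfg$flank_bp >= 0, "flank_bp", "must be non-negative")
  need(inherits(cfg$mcmc, "mcmc_config"), "mcmc", "must be an mcmc_config")
  need(is.numeric(cfg$resample$size) && cfg$resample$size >= 1,
       "resample.size", "must be a positive count")
  need(is.numeric(cfg$resample$reps) && cfg$resample$reps >= 1,
       "resample.reps", "must be a positive count")
  pr <- cfg$prior$partition_r2 %||% 0.5
  need(pr > 0 && pr < 1, "prior.partition_r2", "must lie in (0, 1)")
  if (length(problems))
    stop("invalid pipeline config:\n  ",
         paste(problems, collapse = "\n  "))
  invisible(cfg)
}

#' Run the full analysis pipeline
#'
#' simulate (or load) -> phenotype preparation -> QC filter -> MAF/region
#' classification and marker sets -> per-set whole-genome regression ->
#' fixed-size resampling -> report tables. Every stage is timed and logged;
#' the configuration is echoed into the output directory; variant and
#' subject attrition is book-kept at each filter.
#'
#' @param config A [pipeline_config()] or path to a YAML config file.
#' @param resample_sets Names of marker sets to resample (default: every
#'   set at least as large as `resample$size`).
#' @return A list with all stage outputs (`cohort`, `annotations`,
#'   `marker_sets`, `per_set`, `resampled`, `tables`, `log`), invisibly;
#'   files are written under `config$outdir`.
#' @export
run_pipeline <- function(config, resample_sets = NULL) {
  if (is.character(config)) config <- read_config(config)
  validate_config(config)
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  say <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    paste0(...))
    log_lines <<- c(log_lines, line)
    message(line)
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- force(expr)
    say(sprintf("stage %-10s done in %.1f s", name,
                proc.time()[["elapsed"]] - t0))
    out
  }
  echo_config(config, file.path(outdir, "config_echo.yaml"))

  data <- stage("simulate", {
    if (!is.null(config$simulate)) {
      sim <- simulate_dataset(config$simulate)
      write_vcf(sim, file.path(outdir, "genotypes.vcf"))
      write_bed(sim$genes, file.path(outdir, "genes.bed"))
      write_phenotypes(sim$phenotypes, file.path(outdir, "phenotypes.tsv"))
      write_true_model(sim$truth, file.path(outdir, "true_model.json"))
      sim
    } else {
      vc <- read_genotype_vcf(config$paths$vcf)
      list(genotypes = vc$genotypes, variants = vc$variants,
           genes = read_bed(config$paths$genes),
           phenotypes = read_phenotypes(config$paths$phenotypes))
    }
  })

  cohort <- stage("prep", prepare_cohort(data$phenotypes))
  say(sprintf("cohort: %d subjects retained, %d dropped (no complete visit)",
              nrow(cohort$records), cohort$n_dropped))

  keep_subj <- match(cohort$records$subject_id, rownames(data$genotypes))
  if (anyNA(keep_subj))
    stop("phenotype subjects missing from genotype matrix")
  G_cohort <- data$genotypes[keep_subj, , drop = FALSE]

  flt <- stage("filter", filter_variants(data$variants))
  stopifnot(nrow(data$variants) == nrow(flt$variants) + flt$n_excluded)
  say(sprintf("variants: %d in = %d retained + %d excluded (%s)",
              nrow(data$variants), nrow(flt$variants), flt$n_excluded,
              paste(names(flt$reasons), flt$reasons, sep = "=",
                    collapse = ", ")))
  G_maf <- if (config$maf_cohort == "analysis") {
    G_cohort[, flt$idx, drop = FALSE]
  } else {
    data$genotypes[, flt$idx, drop = FALSE]
  }

  ann <- stage("classify", {
    a <- annotate_variants(flt$variants, G_maf, data$genes,
                           config$flank_bp)
    if (config$drop_monomorphic) {
      n_mono <- sum(a$maf == 0)
      a <- a[a$maf > 0, , drop = FALSE]
      say(sprintf("dropped %d monomorphic variants", n_mono))
    }
    utils::write.table(a, file.path(outdir, "variant_annotation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    a
  })
  sets <- build_marker_sets(ann)
  utils::write.table(sets$crosstab, file.path(outdir, "crosstab.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  Xc <- center_genotypes(
    G_cohort[, flt$idx[match(ann$variant_id, flt$variants$variant_id)],
             drop = FALSE])$centered

  fit_mcmc <- config$mcmc
  fit_mcmc$seed <- derive_seed(config$master_seed, 1000L)
  per_set <- stage("fit", run_per_set(cohort$y, cohort$Z, Xc, sets,
                                      mcmc = fit_mcmc))
  utils::write.table(per_set, file.path(outdir, "per_set_r2.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  eligible <- names(sets$sets)[
    vapply(sets$sets, length, integer(1)) >= config$resample$size]
  if (!is.null(resample_sets)) eligible <- intersect(resample_sets, eligible)
  resampled <- stage("resample", {
    out <- list()
    for (k in seq_along(eligible)) {
      nm <- eligible[k]
      out[[nm]] <- resample_fixed_size(
        cohort$y, cohort$Z, Xc, sets$sets[[nm]], set_name = nm,
        size = config$resample$size, reps = config$resample$reps,
        mcmc = config$resample$mcmc,
        seed = derive_seed(config$master_seed, 2000L + k))
      reps_df <- data.frame(replicate = seq_len(out[[nm]]$n_reps),
                            r2 = out[[nm]]$r2_reps)
      utils::write.table(reps_df,
                         file.path(outdir, paste0("resample_", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    out
  })

  tables <- report_tables(per_set, resampled, sets, dir = outdir)
  summary <- list(
    n_subjects = nrow(cohort$records), n_dropped = cohort$n_dropped,
    variants_in = nrow(data$variants), variants_excluded = flt$n_excluded,
    r2_covariates_only =
      per_set$r2_full[per_set$set_name == "covariates_only"],
    r2_all_markers = per_set$r2_full[per_set$set_name == "all_all"],
    master_seed = config$master_seed)
  summary$marker_variance_ratio_pct <- variance_explained_ratio(
    summary$r2_all_markers, summary$r2_covariates_only)
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(log_lines, file.path(outdir, "pipeline.log"))
  invisible(list(cohort = cohort, annotations = ann, marker_sets = sets,
                 per_set = per_set, resampled = resampled, tables = tables,
                 summary = summary, log = log_lines))
}

echo_config <- function(cfg, path) {
  flat <- list(outdir = cfg$outdir, master_seed = cfg$master_seed,
               flank_bp = cfg$flank_bp, prior = cfg$prior,
               mcmc = unclass(cfg$mcmc),
               resample = list(size = cfg$resample$size,
                               reps = cfg$resample$reps,
                               mcmc = unclass(cfg$resample$mcmc)),
               maf_cohort = cfg$maf_cohort,
               drop_monomorphic = cfg$drop_monomorphic,
               ci_profile = cfg$ci_profile,
               simulate = if (!is.null(cfg$simulate)) {
                 s <- unclass(cfg$simulate)
                 s$maf_mix <- as.list(s$maf_mix)
                 s$covariate_effects <- as.list(s$covariate_effects)
                 s
               },
               paths = cfg$paths)
  yaml::write_yaml(flat, path)
  invisible(path)
}
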