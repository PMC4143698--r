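#' Derive a reproducible sub-seed from a master seed and a counter
#'
#' Counter-based scheme (a Lehmer step on the master seed plus a large
#' prime stride per counter, reduced modulo 2^31 - 1), so each stage and
#' replicate gets its own stream position independently of execution order.
#'
#' @param master Master seed (integer).
#' @param counter Non-negative integer counter.
#' @return Positive integer seed below 2^31.
#' @export
derive_seed <- function(master, counter) {
  m <- 2147483647
  s <- (as.double(master) %% m) * 48271 %% m
  as.integer((s + as.double(counter) * 104729) %% m + 1)
}

#' Fit the whole-genome regression on each marker set
#'
#' One [gibbs_fit()] per marker set, all sharing the response and covariate
#' matrix, plus a covariates-only baseline (no markers). Each set gets its
#' own [default_prior()] (the prior marker-variance scale depends on the
#' set's total genotypic variance) and a sub-seed derived from
#' `mcmc$seed`. Empty sets are skipped with a warning.
#'
#' @param y Standardized response.
#' @param Z Covariate matrix.
#' @param Xc Full centered marker matrix; sets index its columns.
#' @param marker_sets A [build_marker_sets()] object, or a named list of
#'   column-index vectors.
#' @param mcmc A [mcmc_config()]; its seed is the master seed.
#' @param prior Optional fixed [wgr_prior()] used for every set (default:
#'   per-set [default_prior()]).
#' @param keep_fits Keep the full posterior objects (memory).
#' @return data.frame (`set_name`, `n_markers`, `r2_full`,
#'   `sigma_eps2`, `ess_sigma_eps2`), baseline row first; if `keep_fits`,
#'   the posteriors are attached as attribute `"fits"`.
#' @export
run_per_set <- function(y, Z, Xc, marker_sets, mcmc = mcmc_config(),
                        prior = NULL, keep_fits = FALSE) {
  sets <- if (inherits(marker_sets, "marker_sets")) marker_sets$sets
          else marker_sets
  if (anyDuplicated(names(sets))) stop("duplicate marker-set names")
  master <- mcmc$seed %||% 1L
  fits <- list()
  rows <- list()

  base_mcmc <- mcmc; base_mcmc$seed <- derive_seed(master, 0L)
  base <- gibbs_fit(y, Z, NULL, prior = default_prior(stats::var(y)),
                    mcmc = base_mcmc)
  rows[["covariates_only"]] <- data.frame(
    set_name = "covariates_only", n_markers = 0L, r2_full = base$r_squared,
    sigma_eps2 = base$post_mean_sigma_eps2,
    ess_sigma_eps2 = base$ess[["sigma_eps2"]], stringsAsFactors = FALSE)
  if (keep_fits) fits[["covariates_only"]] <- base

  for (k in seq_along(sets)) {
    nm <- names(sets)[k]
    idx <- sets[[k]]
    if (length(idx) == 0) {
      warning("marker set '", nm, "' is empty; skipped")
      next
    }
    set_mcmc <- mcmc; set_mcmc$seed <- derive_seed(master, k)
    Xs <- Xc[, idx, drop = FALSE]
    pr <- prior %||% default_prior(stats::var(y), Xs)
    fit <- gibbs_fit(y, Z, Xs, prior = pr, mcmc = set_mcmc)
    rows[[nm]] <- data.frame(
      set_name = nm, n_markers = length(idx), r2_full = fit$r_squared,
      sigma_eps2 = fit$post_mean_sigma_eps2,
      ess_sigma_eps2 = fit$ess[["sigma_eps2"]], stringsAsFactors = FALSE)
    if (keep_fits) fits[[nm]] <- fit
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  if (keep_fits) attr(out, "fits") <- fits
  out
}

#' Draw the replicate marker subsets for a resampling run
#'
#' Each replicate draws `size` markers from the set without replacement,
#' under its own sub-seed ([derive_seed()] of the master seed and the
#' replicate counter), so replicates are reproducible and independent of
#' execution order.
#'
#' @param set_indices Integer vector of marker column indices.
#' @param size Markers per replicate.
#' @param reps Number of replicates.
#' @param seed Master seed.
#' @return `reps` x `size` integer matrix of column indices.
#' @export
draw_replicate_indices <- function(set_indices, size, reps, seed) {
  if (length(set_indices) < size)
    stop("set has ", length(set_indices), " markers, fewer than size ", size)
  out <- matrix(0L, nrow = reps, ncol = size)
  for (r in seq_len(reps)) {
    set.seed(derive_seed(seed, 2L * r))
    out[r, ] <- sort(sample(set_indices, size))
  }
  out
}

#' Fixed-size marker resampling
#'
#' Fits the whole-genome regression `reps` times, each time on `size`
#' markers drawn at random (without replacement) from the set, and reports
#' the mean and SD (denominator n - 1) of the replicate R-squared values.
#' This controls comparisons between marker categories for the number of
#' markers in each category.
#'
#' @param y,Z,Xc As in [run_per_set()].
#' @param set_indices Column indices of the marker set.
#' @param set_name Label for messages and output.
#' @param size Markers per replicate (default 500).
#' @param reps Number of replicates (default 500).
#' @param mcmc Per-replicate [mcmc_config()]; replicate chains may be much
#'   shorter than the headline fit (default 5,000 iterations, 1,000
#'   burn-in).
#' @param prior Optional fixed prior; default per-replicate
#'   [default_prior()].
#' @param seed Master seed for subset draws and replicate chains.
#' @return A list of class `subset_result`: `set_name`, `n_markers`,
#'   `n_resample`, `n_reps`, `r2_reps`, `r2_mean`, `r2_sd`, `seed`.
#' @export
resample_fixed_size <- function(y, Z, Xc, set_indices, set_name = "set",
                                size = 500, reps = 500,
                                mcmc = mcmc_config(n_iter = 5000,
                                                   burn_in = 1000),
                                prior = NULL, seed = 1L) {
  if (length(set_indices) < size)
    stop("marker set '", set_name, "' has ", length(set_indices),
         " markers, fewer than the resampling size ", size)
  idx_mat <- draw_replicate_indices(set_indices, size, reps, seed)
  r2 <- numeric(reps)
  for (r in seq_len(reps)) {
    Xs <- Xc[, idx_mat[r, ], drop = FALSE]
    rep_mcmc <- mcmc; rep_mcmc$seed <- derive_seed(seed, 2L * r + 1L)
    pr <- prior %||% default_prior(stats::var(y), Xs)
    r2[r] <- gibbs_fit(y, Z, Xs, prior = pr, mcmc = rep_mcmc)$r_squared
  }
  structure(list(set_name = set_name, n_markers = length(set_indices),
                 n_resample = as.integer(size), n_reps = as.integer(reps),
                 r2_reps = r2, r2_mean = mean(r2), r2_sd = stats::sd(r2),
                 seed = as.integer(seed)),
            class = "subset_result")
}

#' Mean and SD of replicate R-squared values
#' @param r2_reps Numeric vector of per-replicate R-squared values.
#' @return list(`mean`, `sd`) with the n - 1 SD.
#' @export
summarize_replicates <- function(r2_reps) {
  list(mean = mean(r2_reps), sd = stats::sd(r2_reps))
}

#' @export
print.subset_result <- function(x, ...) {
  cat(sprintf("Resampled R^2 for '%s': %s over %d replicates of %d/%d markers\n",
              x$set_name, format_mean_sd(x$r2_mean, x$r2_sd), x$n_reps,
              x$n_resample, x$n_markers))
  invisible(x)
}
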