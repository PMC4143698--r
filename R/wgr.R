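#' Center genotypes on twice the allele-1 frequency
#'
#' Each marker column becomes the deviation from the average genotype,
#' `x_il - 2 f_l`, where `f_l` is the (unfolded) frequency of the allele
#' coded 1, computed over non-missing calls. Missing dosages are imputed to
#' the column mean `2 f_l`, i.e. to 0 after centering.
#'
#' @param X Subjects x variants dosage matrix (0/1/2, `NA` missing).
#' @return A list: `centered` (numeric matrix, column means 0 when there is
#'   no missingness), `freq` (allele-1 frequencies).
#' @export
center_genotypes <- function(X) {
  n_obs <- colSums(!is.na(X))
  if (any(n_obs == 0)) stop("variant(s) with all calls missing")
  f <- colSums(X, na.rm = TRUE) / (2 * n_obs)
  Xc <- sweep(X, 2, 2 * f)
  Xc[is.na(Xc)] <- 0
  storage.mode(Xc) <- "double"
  list(centered = Xc, freq = f)
}

#' Scaled-inverse-chi-square prior for the two variance components
#'
#' @param df_beta,scale_beta Degrees of freedom and scale for the marker
#'   effect variance `sigma_beta^2`. `scale_beta` may be `NA` for a
#'   covariates-only model.
#' @param df_eps,scale_eps Degrees of freedom and scale for the residual
#'   variance `sigma_eps^2`.
#' @return A list of class `wgr_prior`.
#' @export
wgr_prior <- function(df_beta, scale_beta, df_eps, scale_eps) {
  if (df_beta <= 0 || df_eps <= 0)
    stop("prior degrees of freedom must be positive")
  if (!is.na(scale_beta) && scale_beta <= 0)
    stop("scale_beta must be positive")
  if (scale_eps <= 0) stop("scale_eps must be positive")
  structure(list(df_beta = df_beta, scale_beta = scale_beta,
                 df_eps = df_eps, scale_eps = scale_eps),
            class = "wgr_prior")
}

#' Weakly informative default prior
#'
#' Both variances get scaled-inverse-chi-square densities with `df` degrees
#' of freedom. The scales encode a prior split of the phenotypic variance:
#' the prior mode of `sigma_eps^2` is set to `(1 - partition_r2) * var_y`,
#' and `scale_beta` is solved so that the implied prior marker variance
#' `sum_l var(x_l) * E[sigma_beta^2]` equals `partition_r2 * var_y`. With
#' `df = 5` the densities are proper but mild; the likelihood dominates at
#' the sample sizes of interest.
#'
#' @param var_y Variance of the response (1 after standardization).
#' @param Xc Centered marker matrix (or `NULL` for covariates-only).
#' @param partition_r2 Prior variance share assigned to markers, in (0, 1).
#' @param df Prior degrees of freedom for both components.
#' @return A `wgr_prior`.
#' @export
default_prior <- function(var_y = 1, Xc = NULL, partition_r2 = 0.5, df = 5) {
  if (partition_r2 <= 0 || partition_r2 >= 1)
    stop("partition_r2 must lie in (0, 1)")
  scale_eps <- (1 - partition_r2) * var_y * (df + 2) / df
  scale_beta <- NA_real_
  if (!is.null(Xc) && ncol(Xc) > 0) {
    sum_var <- sum(apply(Xc, 2, stats::var))
    if (sum_var <= 0) stop("all markers monomorphic; cannot set scale_beta")
    if (df <= 2) stop("df must exceed 2 so E[sigma_beta^2] exists")
    scale_beta <- partition_r2 * var_y * (df - 2) / (df * sum_var)
  }
  wgr_prior(df_beta = df, scale_beta = scale_beta,
            df_eps = df, scale_eps = scale_eps)
}

#' MCMC configuration
#'
#' Defaults: 40,000 iterations with the first 15,000 discarded as burn-in
#' and no thinning, leaving 25,000 kept samples.
#'
#' @param n_iter Total Gibbs iterations.
#' @param burn_in Iterations discarded before summarizing.
#' @param thin Keep every `thin`-th post-burn-in sample.
#' @param seed Integer seed (set before sampling if not `NULL`).
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iter = 40000, burn_in = 15000, thin = 1,
                        seed = NULL) {
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter")
  if (thin < 1) stop("thin must be >= 1")
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "mcmc_config")
}

#' Draw from a scaled-inverse-chi-square distribution
#'
#' `df * scale / X` with `X ~ chi-square(df)`; mean `df*scale/(df-2)` for
#' `df > 2`, mode `df*scale/(df+2)`.
#'
#' @param n Number of draws.
#' @param df Degrees of freedom (> 0).
#' @param scale Scale (> 0).
#' @return Numeric vector of positive draws.
#' @export
sample_scaled_inv_chi2 <- function(n, df, scale) {
  if (df <= 0 || scale <= 0) stop("df and scale must be positive")
  cpp_rscaled_inv_chi2(n, df, scale)
}

#' Fit the Bayesian whole-genome regression by Gibbs sampling
#'
#' Model: `y_i = mu + sum_j Z_ij gamma_j + sum_l x_il beta_l + eps_i`, with
#' flat priors on the intercept and covariate effects, iid
#' `N(0, sigma_beta^2)` priors on marker effects, scaled-inverse-chi-square
#' priors on both variances, and iid normal residuals. All full
#' conditionals are standard conjugate forms and are sampled scalar-wise
#' with incremental residual updates.
#'
#' @param y Response; expected to be standardized to unit variance (a
#'   warning is issued otherwise).
#' @param Z Covariate matrix (may be `NULL` for an intercept-only fit).
#' @param Xc Centered marker matrix from [center_genotypes()], or `NULL` /
#'   zero-column for a covariates-only model.
#' @param prior A [wgr_prior()]; default [default_prior()] on `var(y)`.
#' @param mcmc A [mcmc_config()].
#' @param fix_sigma_beta2,fix_sigma_eps2 Clamp a variance at this value
#'   instead of sampling it (used for closed-form cross-checks).
#' @param save_beta_chains Keep the full per-marker chains (memory: kept x
#'   L); otherwise only running posterior means of beta are stored.
#' @param estimator Posterior summary for the residual variance entering
#'   R-squared: `"mean"` (default) or `"median"`.
#' @param trace_dir If non-`NULL`, write PNG trace plots of the scalar
#'   chains there.
#' @return A list of class `wgr_posterior`: `chains` (data.frame of kept
#'   scalar samples), `beta_postmean`, `post_mean_sigma_eps2`,
#'   `post_mean_sigma_beta2`, `r_squared`, `ess`, `rhat_sigma_eps2`,
#'   `trace_files`, and the echoed configuration.
#' @export
gibbs_fit <- function(y, Z = NULL, Xc = NULL, prior = NULL,
                      mcmc = mcmc_config(),
                      fix_sigma_beta2 = NULL, fix_sigma_eps2 = NULL,
                      save_beta_chains = FALSE, estimator = c("mean", "median"),
                      trace_dir = NULL) {
  estimator <- match.arg(estimator)
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(Z)) Z <- matrix(numeric(0), nrow = n, ncol = 0)
  Z <- as.matrix(Z)
  if (is.null(Xc)) Xc <- matrix(numeric(0), nrow = n, ncol = 0)
  Xc <- as.matrix(Xc)
  if (nrow(Z) != n || nrow(Xc) != n) stop("non-conformable inputs")
  if (n < ncol(Z) + 2)
    stop("need more observations than fixed effects (n >= ncol(Z) + 2)")
  if (abs(stats::var(y) - 1) > 0.05)
    warning("response variance is ", signif(stats::var(y), 3),
            "; R-squared assumes a unit-variance response")
  L <- ncol(Xc)
  if (is.null(prior)) prior <- default_prior(stats::var(y), Xc)
  if (L > 0 && is.na(prior$scale_beta) && is.null(fix_sigma_beta2))
    stop("prior lacks scale_beta but markers are present")
  W <- cbind(`(Intercept)` = 1, Z)

  if (!is.null(mcmc$seed)) set.seed(mcmc$seed)
  fit <- cpp_wgr_gibbs(y, W, Xc,
                       prior$df_beta,
                       if (is.na(prior$scale_beta)) 1 else prior$scale_beta,
                       prior$df_eps, prior$scale_eps,
                       mcmc$n_iter, mcmc$burn_in, mcmc$thin,
                       if (is.null(fix_sigma_beta2)) -1 else fix_sigma_beta2,
                       if (is.null(fix_sigma_eps2)) -1 else fix_sigma_eps2,
                       save_beta_chains)

  chains <- as.data.frame(fit$alpha_chain)
  names(chains) <- c("mu", colnames(Z) %||% character(0))
  if (ncol(Z) > 0 && is.null(colnames(Z)))
    names(chains) <- c("mu", paste0("gamma", seq_len(ncol(Z))))
  chains$sigma_beta2 <- fit$sigma_beta2_chain
  chains$sigma_eps2 <- fit$sigma_eps2_chain
  if (L == 0) chains$sigma_beta2 <- NULL

  est <- switch(estimator,
                mean = mean(chains$sigma_eps2),
                median = stats::median(chains$sigma_eps2))
  post <- structure(list(
    chains = chains,
    beta_postmean = as.numeric(fit$beta_postmean),
    beta_chain = if (save_beta_chains) fit$beta_chain else NULL,
    post_mean_sigma_eps2 = est,
    post_mean_sigma_beta2 = if (L > 0) mean(chains$sigma_beta2) else NA_real_,
    r_squared = 1 - est,
    ess = vapply(chains, ess_spectral, numeric(1)),
    rhat_sigma_eps2 = split_rhat(chains$sigma_eps2),
    n_obs = n, n_markers = L,
    prior = prior, mcmc = mcmc, estimator = estimator,
    trace_files = character(0)
  ), class = "wgr_posterior")
  if (!is.null(trace_dir))
    post$trace_files <- write_trace_plots(post, trace_dir)
  post
}

#' Proportion of variance explained
#'
#' For a unit-variance response, `R^2 = 1 - sigma_eps_hat^2`, where the
#' residual variance estimate is the posterior mean (or median) of its
#' chain.
#'
#' @param x A `wgr_posterior`, or directly the estimated residual variance.
#' @return R-squared.
#' @export
r_squared <- function(x) UseMethod("r_squared")

#' @rdname r_squared
#' @export
r_squared.wgr_posterior <- function(x) x$r_squared

#' @rdname r_squared
#' @export
r_squared.default <- function(x) 1 - x

#' Percent of covariate-adjusted variance explained by markers
#'
#' `100 * (r2_full - r2_cov) / (1 - r2_cov)`: the share of the phenotypic
#' variance remaining after nongenetic effects that is picked up by the
#' marker regression.
#'
#' @param r2_full R-squared of the covariates-plus-markers model.
#' @param r2_cov R-squared of the covariates-only model.
#' @return Percent (0--100 scale).
#' @export
variance_explained_ratio <- function(r2_full, r2_cov) {
  100 * (r2_full - r2_cov) / (1 - r2_cov)
}

#' @export
print.wgr_posterior <- function(x, ...) {
  cat("Whole-genome regression posterior (", x$n_obs, " obs, ",
      x$n_markers, " markers)\n", sep = "")
  cat(sprintf("  sigma_eps^2 = %.4f (ESS %.0f, split R-hat %.3f)\n",
              x$post_mean_sigma_eps2, x$ess[["sigma_eps2"]],
              x$rhat_sigma_eps2))
  if (x$n_markers > 0)
    cat(sprintf("  sigma_beta^2 = %.3e\n", x$post_mean_sigma_beta2))
  cat(sprintf("  R^2 = 1 - sigma_eps^2 = %.4f\n", x$r_squared))
  invisible(x)
}

write_trace_plots <- function(post, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (nm in names(post$chains)) {
    f <- file.path(dir, paste0("trace_", nm, ".png"))
    grDevices::png(f, width = 700, height = 350)
    graphics::plot(post$chains[[nm]], type = "l", xlab = "kept iteration",
                   ylab = nm, main = paste("Trace:", nm))
    grDevices::dev.off()
    files <- c(files, f)
  }
  files
}
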