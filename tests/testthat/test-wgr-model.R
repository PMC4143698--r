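test_that("genotype centering subtracts 2f and mean-imputes missing", {
  X <- cbind(c(0, 1, 2), c(0, 0, 0), c(0, NA, 2))
  cg <- center_genotypes(X)
  expect_equal(cg$centered[, 1], c(-1, 0, 1))
  expect_equal(cg$centered[, 2], c(0, 0, 0))
  expect_equal(cg$centered[, 3], c(-1, 0, 1))
  expect_equal(cg$freq, c(0.5, 0, 0.5))
  # column means are zero without missingness
  set.seed(2)
  Xr <- matrix(rbinom(500, 2, 0.3), nrow = 50)
  expect_true(all(abs(colMeans(center_genotypes(Xr)$centered)) < 1e-10))
  expect_error(center_genotypes(cbind(c(NA_integer_, NA_integer_))),
               "missing")
})

test_that("scaled-inverse-chi-square sampler has the analytic law", {
  set.seed(101)
  x <- sample_scaled_inv_chi2(1e5, df = 4, scale = 2)
  ks <- ks.test(x, function(q) 1 - pchisq(4 * 2 / q, df = 4))
  expect_gt(ks$p.value, 0.001)

  set.seed(102)
  y <- sample_scaled_inv_chi2(1e6, df = 4, scale = 1)
  expect_lt(abs(mean(y) - 4 * 1 / (4 - 2)), 3 * sd(y) / sqrt(1e6))

  # df -> infinity: concentration at the scale
  set.seed(103)
  z <- sample_scaled_inv_chi2(1e4, df = 1e6, scale = 3)
  expect_lt(max(abs(z - 3)), 0.1)

  # heavy-tailed df = 1: median from the quantile transform
  set.seed(104)
  w <- sample_scaled_inv_chi2(1e5, df = 1, scale = 1)
  expect_lt(abs(median(w) - 1 / qchisq(0.5, 1)), 0.06)

  expect_error(sample_scaled_inv_chi2(10, df = 0, scale = 1), "positive")
  expect_error(sample_scaled_inv_chi2(10, df = 1, scale = -1), "positive")
})

test_that("default prior encodes the variance partition", {
  Xc <- matrix(rnorm(200), nrow = 20)
  pr <- default_prior(var_y = 1, Xc = Xc, partition_r2 = 0.5, df = 5)
  # prior mode of sigma_eps^2: df*scale/(df+2) = 0.5
  expect_equal(pr$df_eps * pr$scale_eps / (pr$df_eps + 2), 0.5)
  # implied prior marker variance matches the partition
  sum_var <- sum(apply(Xc, 2, var))
  expect_equal(sum_var * pr$df_beta * pr$scale_beta / (pr$df_beta - 2), 0.5)
  # scaling law: doubling column variances halves scale_beta
  pr2 <- default_prior(var_y = 1, Xc = sqrt(2) * Xc)
  expect_equal(pr2$scale_beta, pr$scale_beta / 2)
  # covariates-only: no marker scale
  expect_true(is.na(default_prior(1, NULL)$scale_beta))
  expect_error(default_prior(1, Xc, partition_r2 = 1.2), "partition_r2")
})

test_that("MCMC defaults leave 25,000 kept samples", {
  mc <- mcmc_config()
  expect_equal((mc$n_iter - mc$burn_in) / mc$thin, 25000)
  expect_error(mcmc_config(n_iter = 100, burn_in = 200), "burn_in")
  expect_error(mcmc_config(thin = 0), "thin")
})

test_that("covariates-only posterior means agree with least squares", {
  set.seed(201)
  n <- 150
  Z <- cbind(age = runif(n, 30, 70), sex = rbinom(n, 1, 0.5))
  y <- drop(scale(0.01 * Z[, 1] + 0.2 * Z[, 2] + rnorm(n, 0, 0.8)))
  fit <- gibbs_fit(y, Z, NULL, mcmc = mcmc_config(6000, 1000, seed = 202))
  ols <- coef(lm(y ~ Z))
  for (k in 1:3) {
    ch <- fit$chains[[k]]
    expect_lt(abs(mean(ch) - ols[k]), 3 * mc_se(ch) + 1e-8)
  }
  # sigma_eps2 chain length honours the config
  expect_equal(nrow(fit$chains), 5000)
  expect_equal(fit$r_squared, 1 - fit$post_mean_sigma_eps2)
})

test_that("same seed reproduces bit-identical chains", {
  sim <- simulate_dataset(clean_spec(80, 60, seed = 61))
  cohort <- prepare_cohort(sim$phenotypes)
  Xc <- center_genotypes(sim$genotypes[match(cohort$records$subject_id,
                                             rownames(sim$genotypes)), ]
                         )$centered
  f1 <- gibbs_fit(cohort$y, cohort$Z, Xc, mcmc = mcmc_config(500, 100,
                                                             seed = 7))
  f2 <- gibbs_fit(cohort$y, cohort$Z, Xc, mcmc = mcmc_config(500, 100,
                                                             seed = 7))
  expect_identical(f1$chains, f2$chains)
  expect_identical(f1$beta_postmean, f2$beta_postmean)
})

test_that("R-squared follows 1 - residual variance", {
  expect_equal(r_squared(1.0), 0.0)
  expect_equal(r_squared(0.762), 0.238)
  post <- structure(list(r_squared = 0.25), class = "wgr_posterior")
  expect_equal(r_squared(post), 0.25)
  expect_equal(variance_explained_ratio(0.238, 0.191),
               100 * (0.238 - 0.191) / (1 - 0.191))
})

test_that("overfitting on pure-noise data stays bounded", {
  set.seed(301)
  sim <- simulate_dataset(clean_spec(400, 500, seed = 301, h2_markers = 0,
                                     covariate_effects = c(0, 0, 0, 0)))
  cohort <- prepare_cohort(sim$phenotypes)
  Xc <- center_genotypes(sim$genotypes[match(cohort$records$subject_id,
                                             rownames(sim$genotypes)), ]
                         )$centered
  full <- gibbs_fit(cohort$y, cohort$Z, Xc,
                    mcmc = mcmc_config(4000, 1000, seed = 302))
  cov <- gibbs_fit(cohort$y, cohort$Z, NULL,
                   mcmc = mcmc_config(4000, 1000, seed = 303))
  expect_lt(full$r_squared - cov$r_squared, 0.15)
})

test_that("residual-variance chain is stationary on the standard fixture", {
  sim <- simulate_dataset(clean_spec(300, 150, seed = 71))
  cohort <- prepare_cohort(sim$phenotypes)
  Xc <- center_genotypes(sim$genotypes[match(cohort$records$subject_id,
                                             rownames(sim$genotypes)), ]
                         )$centered
  fit <- gibbs_fit(cohort$y, cohort$Z, Xc,
                   mcmc = mcmc_config(10000, 2000, seed = 72))
  expect_lt(fit$rhat_sigma_eps2, 1.05)
  expect_gt(fit$ess[["sigma_eps2"]], 50)
})

test_that("degenerate fits are rejected, L = 0 is legal", {
  y <- rnorm(3)
  expect_error(gibbs_fit(y, cbind(1:3, c(2, 1, 3)), NULL), "observations")
  fit <- suppressWarnings(gibbs_fit(drop(scale(rnorm(30))), NULL, NULL,
                                    mcmc = mcmc_config(400, 100, seed = 1)))
  expect_false("sigma_beta2" %in% names(fit$chains))
})

test_that("trace plots are written when requested", {
  y <- drop(scale(rnorm(40)))
  td <- tempfile()
  fit <- gibbs_fit(y, NULL, NULL, mcmc = mcmc_config(400, 100, seed = 2),
                   trace_dir = td)
  expect_true(all(file.exists(fit$trace_files)))
  expect_gt(length(fit$trace_files), 0)
  unlink(td, recursive = TRUE)
})
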