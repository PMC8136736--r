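# Sampler contract: conjugate-toy moments, prior recovery, determinism,
# and convergence diagnostics.

test_that("adaptive RW kernel recovers a conjugate beta-binomial posterior", {
  # y = 18 successes of n = 50, Beta(2, 3) prior -> posterior Beta(20, 35)
  logtarget <- function(p) {
    dbinom(18, 50, p, log = TRUE) + dbeta(p, 2, 3, log = TRUE)
  }
  set.seed(123)
  draws <- mh_sample(
    logtarget, init = 0.5, lower = 0, upper = 1,
    n_iter = 30000L, burn_in = 5000L, thin = 25L
  )[, 1]
  a <- 20
  b <- 35
  post_mean <- a / (a + b)
  post_var <- a * b / ((a + b)^2 * (a + b + 1))
  mcse <- sd(draws) / sqrt(length(draws)) # draws thinned to near-independence
  expect_lt(abs(mean(draws) - post_mean), 3 * mcse)
  expect_lt(abs(var(draws) - post_var), 0.35 * post_var)
})

test_that("no-data fits recover the prior bounds and uniform vital-rate priors", {
  ds <- tiny_sim()$dataset
  mc <- mcmc_config(n_chains = 2L, n_iter = 20000L, burn_in = 4000L, thin = 10L)
  fit <- fit_model(model_spec("2", "constant"), ds, mc,
    seed = 4, prior_only = TRUE
  )
  phi <- posterior_draws(fit, "phi1")
  rho <- posterior_draws(fit, "rho")
  expect_true(all(phi > 0.8 & phi < 1))
  expect_true(all(rho > 0 & rho < 0.2))
  # loose moment checks only: under the prior the vital rates are tightly
  # coupled to the latent demographic path, so mixing is slow and the
  # effective sample size is small (the bounds checks above are exact)
  expect_lt(abs(mean(phi) - 0.9), 0.05)
  expect_lt(abs(mean(rho) - 0.1), 0.05)
  expect_gt(diff(range(phi)), 0.8 * 0.2)
  # exponential model: trend prior is uniform on the induced bounds
  fit1 <- fit_model(model_spec("1b", "constant"), ds, mc,
    seed = 4, prior_only = TRUE
  )
  ups <- posterior_draws(fit1, "upsilon1")
  expect_true(all(ups > log(0.8) & ups < log(1.2)))
  expect_lt(abs(mean(ups) - mean(c(log(0.8), log(1.2)))), 0.03)
})

test_that("identical seeds give bit-identical draws; doubling iterations extends the stream", {
  ds <- tiny_sim()$dataset
  spec <- model_spec("2", "constant")
  mc <- mcmc_config(n_chains = 2L, n_iter = 1200L, burn_in = 400L, thin = 10L)
  f1 <- fit_model(spec, ds, mc, seed = 99)
  f2 <- fit_model(spec, ds, mc, seed = 99)
  expect_identical(f1$draws, f2$draws)
  f3 <- fit_model(spec, ds, mcmc_config(
    n_chains = 2L, n_iter = 2000L, burn_in = 400L, thin = 10L
  ), seed = 99)
  n1 <- dim(f1$draws)[1]
  expect_identical(f1$draws[, , ], f3$draws[seq_len(n1), , ])
  f4 <- fit_model(spec, ds, mc, seed = 100)
  expect_false(identical(f1$draws, f4$draws))
})

test_that("every saved draw respects the parameter bounds", {
  ds <- tiny_sim()$dataset
  mc <- mcmc_config(n_chains = 2L, n_iter = 1000L, burn_in = 500L, thin = 10L)
  fit <- fit_model(model_spec("4", "change"), ds, mc, seed = 13)
  phi1 <- posterior_draws(fit, "phi1")
  phi2 <- posterior_draws(fit, "phi2")
  chi <- posterior_draws(fit, "chi")
  rho <- posterior_draws(fit, "rho")
  expect_true(all(phi1 > 0.8 & phi1 < 1 & phi2 > 0.8 & phi2 < 1))
  expect_true(all(rho > 0 & rho < 0.2))
  expect_true(all(chi > 0.6 & chi < pmin(phi1, phi2)))
  N16 <- posterior_draws(fit, "N_16")
  expect_true(all(N16 >= 0 & N16 <= fit$spec$N_max))
})

test_that("PSRF: identical chains give exactly 1, disjoint chains are flagged", {
  x <- rnorm(500)
  expect_identical(psrf(cbind(x, x)), 1)
  set.seed(8)
  iid <- cbind(rnorm(5000), rnorm(5000))
  r <- psrf(iid)
  expect_gte(r, 1)
  expect_lt(r, 1.01)
  expect_lt(abs(geweke_z(iid[, 1])), 3)
  expect_lt(abs(geweke_z(iid[, 2])), 3)
  disjoint <- cbind(rnorm(500), rnorm(500) + 50)
  expect_gt(psrf(disjoint), 1.06)
  expect_error(psrf(matrix(rnorm(100), ncol = 1)), "two chains")
})

test_that("convergence_diagnostics reports the monitored protocol quantities", {
  ds <- tiny_sim()$dataset
  mc <- mcmc_config(n_chains = 2L, n_iter = 2000L, burn_in = 1000L, thin = 5L)
  fit <- fit_model(model_spec("2", "constant"), ds, mc, seed = 6)
  diag <- convergence_diagnostics(fit)
  expect_setequal(
    diag$quantity, c("N_16", "upsilon1", "deviance", "phi1")
  )
  expect_true(all(is.finite(diag$psrf)))
  expect_true(is.logical(diag$flagged))
})
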