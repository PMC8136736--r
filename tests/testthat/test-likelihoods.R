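# Likelihood terms against closed forms, quadrature and pmf oracles.

test_that("distribution_probs: uniform limit, single cell, two-cell arithmetic", {
  expect_equal(distribution_probs(rnorm(7), 0), rep(1 / 7, 7))
  expect_equal(distribution_probs(3.2, 1.5), 1)
  expect_equal(distribution_probs(c(0, log(3)), 1), c(0.25, 0.75))
  expect_equal(sum(distribution_probs(rnorm(100) * 50, 2)), 1)
  expect_error(distribution_probs(c(-Inf, -Inf), 1), "non-finite")
})

test_that("esw_halfnormal matches closed forms and quadrature", {
  expect_equal(esw_halfnormal(1, 1e6), sqrt(pi / 2), tolerance = 1e-10)
  expect_lt(esw_halfnormal(1, 1e-9), 1e-8)
  quad <- integrate(function(x) exp(-x^2 / 2), 0, 1)$value
  expect_equal(esw_halfnormal(1, 1), quad, tolerance = 1e-8)
  expect_equal(esw_halfnormal(1, 1), 0.855624, tolerance = 1e-6)
  for (s in c(0.1, 0.5, 2)) {
    for (xm in c(0.2, 1, 5)) {
      quad <- integrate(function(x) exp(-x^2 / (2 * s^2)), 0, xm)$value
      expect_equal(esw_halfnormal(s, xm), quad, tolerance = 1e-8)
    }
  }
  expect_error(esw_halfnormal(-1, 1), "positive")
})

test_that("segment_detection_prob arithmetic and geometry guard", {
  expect_equal(segment_detection_prob(10, 2, 1, 400), 0.1)
  expect_equal(segment_detection_prob(10, 2, 0, 400), 0)
  expect_equal(segment_detection_prob(10, 20, 1, 400), 1)
  expect_error(segment_detection_prob(10, 30, 1, 400), "p.d > 1")
})

test_that("loglik_distances matches the quadrature-normalized density", {
  expect_equal(loglik_distances(0, 1, 1e7), log(sqrt(2 / pi)), tolerance = 1e-6)
  expect_equal(loglik_distances(numeric(0), 1, 3), 0)
  x <- c(0.5, 1.2)
  norm_const <- integrate(function(u) exp(-u^2 / 2), 0, 3)$value
  manual <- sum(log(exp(-x^2 / 2) / norm_const))
  expect_equal(loglik_distances(x, 1, 3), manual, tolerance = 1e-8)
  expect_error(loglik_distances(c(0.5, 3.2), 1, 3), "truncation")
})

test_that("loglik_counts matches dpois and the lambda arithmetic", {
  expect_equal(as.numeric(loglik_counts(0, 0, 0.5, 0.5)), 0)
  expect_equal(as.numeric(loglik_counts(1, 20, 0.1, 0.5)), -1)
  out <- loglik_counts(c(3, 0, 7), 1000, c(0.01, 0.02, 0.005), 0.1)
  expect_equal(attr(out, "lambda"), c(1, 2, 0.5))
  expect_equal(
    as.numeric(out), sum(dpois(c(3, 0, 7), c(1, 2, 0.5), log = TRUE))
  )
  expect_error(loglik_counts(-1, 10, 0.1, 0.1), "negative")
})

test_that("demographic step log-probability matches the binomial pmf product", {
  expect_equal(demographic_step_logprob(100, 0, 5, 1, 0.1, 0.8),
    dbinom(5, 100, 0.08, log = TRUE))
  expect_equal(demographic_step_logprob(100, 3, 5, 1, 0.1, 0.8), -Inf)
  expect_equal(
    demographic_step_logprob(100, 10, 8, 0.9, 0.1, 0.8),
    dbinom(10, 100, 0.1, log = TRUE) + dbinom(8, 100, 0.08, log = TRUE)
  )
  # binomial mean of deaths: mode at N (1 - phi)
  lp <- vapply(40:60, function(D) {
    demographic_step_logprob(1000, D, 0, 0.95, 0, 0.8)
  }, numeric(1))
  expect_equal((40:60)[which.max(lp)], 50)
})

test_that("initial abundance prior matches the binomial pmf", {
  expect_equal(initial_abundance_logprob(2000, 2000, 1), 0)
  expect_equal(initial_abundance_logprob(0, 2000, 0), 0)
  expect_equal(
    initial_abundance_logprob(1000, 2000, 0.5),
    dbinom(1000, 2000, 0.5, log = TRUE)
  )
  expect_error(initial_abundance_logprob(2001, 2000, 0.5), "N_max")
})

test_that("derived trend and change parameters", {
  expect_equal(derived_trend(0.08, 0.75, 0.94), 0)
  phi2 <- (2 / 3)^(1 / 8) - 0.06
  expect_equal(derived_trend(0.08, 0.75, phi2), log(2 / 3) / 8)
  expect_equal(derived_change(0.1, 0.1), 0)
  # monotone increasing in each vital rate
  base <- derived_trend(0.1, 0.7, 0.9)
  expect_gt(derived_trend(0.11, 0.7, 0.9), base)
  expect_gt(derived_trend(0.1, 0.71, 0.9), base)
  expect_gt(derived_trend(0.1, 0.7, 0.91), base)
})

test_that("exponential trajectory: constant and change variants", {
  expect_equal(exponential_trajectory(500, 0, 5), rep(500, 5))
  expect_equal(exponential_trajectory(100, log(2), 2)[2], 200)
  N <- exponential_trajectory(1000, 0, 16, upsilon2 = log(2 / 3) / 8, T_BP = 8)
  expect_equal(N[8], 1000)
  expect_equal(N[16], 1000 * 2 / 3, tolerance = 1e-10)
})

test_that("calf index likelihood matches the binomial pmf", {
  expect_equal(
    calf_index_logprob(5, 50, 0.08, 0.75, 0.94),
    dbinom(5, 50, 0.08, log = TRUE)
  )
  expect_equal(
    calf_index_logprob(0, 30, 0.08, 0.75, 0.94),
    30 * log(1 - 0.08)
  )
  expect_error(calf_index_logprob(10, 5, 0.08, 0.75, 0.94), "denominator")
})

test_that("availability probabilities partition the distribution", {
  region <- c(rep(TRUE, 5), rep(FALSE, 5))
  p <- rep(0.1, 10)
  expect_equal(
    availability_probs(p, region, integer(0)),
    c(pa1 = 0, pa2 = 0.5, pa3 = 0.5)
  )
  expect_equal(
    unname(sum(availability_probs(p, region, c(1L, 3L)))), 1
  )
  expect_equal(
    availability_probs(p, rep(TRUE, 10), integer(0)),
    c(pa1 = 0, pa2 = 1, pa3 = 0)
  )
  set.seed(1)
  for (i in 1:20) {
    p <- distribution_probs(rnorm(10), 1)
    pa <- availability_probs(p, region, sample(which(region), 2))
    expect_equal(unname(sum(pa)), 1, tolerance = 1e-12)
  }
  expect_error(availability_probs(p, region, 7L), "inside the survey region")
})
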