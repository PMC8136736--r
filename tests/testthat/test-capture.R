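# Capture-history marginal likelihood against trivial limits and an
# exhaustive latent-state enumeration oracle.

test_that("certain-detection and zero-detection limits", {
  Tn <- 4
  pa <- rbind(rep(0.3, Tn), rep(0.7, Tn), rep(0, Tn)) # always in region
  pr1 <- rep(1, Tn)
  # phi = 1, always available, certain recapture: all-ones history is sure
  Y1 <- matrix(c(0, 1, 1, 1), 1)
  expect_equal(
    capture_history_loglik(Y1, NULL, 1L, rep(1, Tn - 1), pa, pr1,
      sources = "survey_only"
    ), 0
  )
  # ... and any 0 after first capture is impossible
  Y0 <- matrix(c(0, 1, 0, 1), 1)
  expect_equal(
    capture_history_loglik(Y0, NULL, 1L, rep(1, Tn - 1), pa, pr1,
      sources = "survey_only"
    ), -Inf
  )
  # zero recapture probability: an all-zero history is certain
  expect_equal(
    capture_history_loglik(matrix(0L, 1, Tn), NULL, 1L, rep(0.9, Tn - 1),
      pa, rep(0, Tn),
      sources = "survey_only"
    ), 0
  )
})

test_that("marginal likelihood equals exhaustive enumeration (both sources)", {
  set.seed(31)
  for (rep in 1:120) {
    Tn <- 4L
    M <- 2L
    phi_t <- runif(Tn - 1, 0.5, 1)
    pa <- apply(matrix(rexp(3 * Tn), 3), 2, function(v) v / sum(v))
    pr_t <- runif(Tn, 0, 0.8) * rbinom(Tn, 1, 0.7)
    p_r_sb <- runif(1, 0.05, 0.9)
    first <- sample(1:3, 1)
    y <- integer(Tn)
    cc <- integer(Tn)
    for (t in (first + 1):Tn) {
      y[t] <- rbinom(1, 1, 0.4)
      cc[t] <- sample(0:M, 1)
    }
    y[pr_t == 0] <- 0L
    got <- capture_history_loglik(
      matrix(y, 1), matrix(cc, 1), first, phi_t, pa, pr_t, p_r_sb, M,
      sources = "both"
    )
    want <- enum_capture(y, cc, first, phi_t, pa, pr_t, p_r_sb, M)
    if (is.infinite(want)) {
      expect_equal(got, want)
    } else {
      expect_equal(got, want, tolerance = 1e-10)
    }
  }
})

test_that("survey-only marginal equals enumeration with the small-boat term off", {
  set.seed(77)
  for (rep in 1:60) {
    Tn <- 4L
    phi_t <- runif(Tn - 1, 0.5, 1)
    pa <- apply(matrix(rexp(3 * Tn), 3), 2, function(v) v / sum(v))
    pr_t <- runif(Tn, 0, 0.8)
    first <- sample(1:3, 1)
    y <- integer(Tn)
    for (t in (first + 1):Tn) y[t] <- rbinom(1, 1, 0.4)
    got <- capture_history_loglik(
      matrix(y, 1), NULL, first, phi_t, pa, pr_t,
      sources = "survey_only"
    )
    want <- enum_capture(y, integer(Tn), first, phi_t, pa, pr_t, 0, 0L)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("captures before the first-capture year are rejected", {
  Tn <- 4
  pa <- rbind(rep(0.3, Tn), rep(0.4, Tn), rep(0.3, Tn))
  Y <- matrix(c(1, 0, 0, 0), 1)
  expect_error(
    capture_history_loglik(Y, NULL, 2L, rep(0.9, Tn - 1), pa, rep(0.5, Tn),
      sources = "survey_only"
    ),
    "before first-capture"
  )
  expect_error(
    capture_history_loglik(Y, NULL, 1L, rep(0.9, Tn - 1), pa, rep(1.5, Tn),
      sources = "survey_only"
    ),
    "outside \\[0, 1\\]"
  )
})

test_that("pointwise capture increments sum to the marginal likelihood", {
  sim <- tiny_sim()
  ds <- sim$dataset
  spec <- model_spec("4", "change", T_BP = tiny_config()$T_BP)
  prep <- cetipm:::prepare_model_data(spec, ds)
  set.seed(5)
  for (i in 1:5) {
    p <- random_params(spec, prep)
    pw <- pointwise_loglik(spec, p, prep)
    jp <- joint_logposterior(spec, p, prep)
    cap_total <- sum(pw[startsWith(names(pw), "caps_")]) +
      sum(pw[startsWith(names(pw), "capb_")])
    expect_equal(cap_total, unname(jp$terms["capture"]), tolerance = 1e-8)
    data_total <- sum(pw)
    expect_equal(
      data_total,
      unname(sum(jp$terms[c("distances", "counts", "calf", "capture")])),
      tolerance = 1e-8
    )
  }
})
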