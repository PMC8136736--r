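# Joint log-posterior: additive structure across the model ladder, prior
# support, nesting, and agreement between the C++ sampler core and the pure
# R reference on saved draws.

test_that("Model 3 with an empty catalog reduces to Model 2 term-by-term", {
  ds <- tiny_sim()$dataset
  # drop every capture history
  ds$Y_survey <- ds$Y_survey[0, , drop = FALSE]
  ds$Y_sb <- ds$Y_sb[0, , , drop = FALSE]
  ds$first_survey <- ds$first_sb <- ds$first_any <- integer(0)
  ds$catalog_ids <- integer(0)
  spec2 <- model_spec("2", "constant", T_BP = 8)
  spec3 <- model_spec("3", "constant", T_BP = 8)
  p <- valid_params()
  j2 <- joint_logposterior(spec2, p, ds)
  j3 <- joint_logposterior(spec3, p, ds)
  expect_equal(j3$terms["capture"], c(capture = 0))
  expect_equal(j2$logpost, j3$logpost)
})

test_that("Model 2 equals Model 1b's data terms plus calf and process swap", {
  ds <- tiny_sim()$dataset
  p <- valid_params()
  spec1b <- model_spec("1b", "constant")
  spec2 <- model_spec("2", "constant")
  j1b <- joint_logposterior(spec1b, p, ds)
  j2 <- joint_logposterior(spec2, p, ds)
  # shared terms: distances identical; counts differ only through N_t
  expect_equal(j2$terms["distances"], j1b$terms["distances"])
  # with the exponential path forced equal to the latent path, counts agree
  p_flat <- p
  p_flat$D[] <- 0L
  p_flat$R[] <- 0L
  p_flat$N1c <- p$N1
  p_flat$upsilon1 <- 0
  j1b_flat <- joint_logposterior(spec1b, p_flat, ds)
  j2_flat <- joint_logposterior(spec2, p_flat, ds)
  expect_equal(j2_flat$N_t, j1b_flat$N_t)
  expect_equal(j2_flat$terms["counts"], j1b_flat$terms["counts"])
  # model 2 activates exactly the calf term on top of the shared data terms
  expect_false(is.na(j2$terms["calf"]))
  expect_equal(j1b$terms["calf"], c(calf = 0))
})

test_that("uniform-distribution nesting: b = 0 with a full-grid region matches Model 1a", {
  # construct a prepared-data fixture whose survey region is the whole grid
  ds <- tiny_sim()$dataset
  spec_a <- model_spec("1a", "constant")
  spec_b <- model_spec("1b", "constant")
  prep <- cetipm:::prepare_model_data(spec_b, ds)
  K <- prep$K
  prep$region_mask <- rep(TRUE, K)
  prep$region_cells <- seq_len(K)
  prep$H <- matrix(0, K, prep$Tn) # constant covariate: softmax is uniform
  p <- valid_params()
  p$b <- 0
  ja <- joint_logposterior(spec_a, p, prep)
  jb <- joint_logposterior(spec_b, p, prep)
  expect_equal(jb$terms["counts"], ja$terms["counts"] + c(counts = 0))
})

test_that("parameters outside the prior support give -Inf, not errors", {
  ds <- tiny_sim()$dataset
  spec <- model_spec("4", "change", T_BP = 8)
  base <- valid_params()
  for (tweak in list(
    c("phi1", 0.79), c("phi1", 1.01), c("rho", 0.21), c("chi", 0.59),
    c("chi", 0.95), c("p_r_sb", 1.2), c("s", -0.1), c("zeta", 1.5)
  )) {
    p <- base
    p[[tweak[1]]] <- as.numeric(tweak[2])
    expect_identical(
      joint_logposterior(spec, p, ds)$logpost, -Inf,
      label = paste("tweak", tweak[1])
    )
  }
  p <- base
  p$D[3] <- p$N1 + 1L
  expect_identical(joint_logposterior(spec, p, ds)$logpost, -Inf)
})

test_that("C++ sampler log-posterior equals the R reference on every saved draw", {
  ds <- tiny_sim()$dataset
  mc <- mcmc_config(n_chains = 1L, n_iter = 600L, burn_in = 200L, thin = 40L)
  for (mid in c("1a", "1b", "2", "3", "4")) {
    for (variant in c("constant", "change")) {
      spec <- model_spec(mid, variant, T_BP = 8)
      fit <- fit_model(spec, ds, mc, seed = 21)
      prep <- cetipm:::prepare_model_data(spec, ds)
      for (i in seq_len(dim(fit$draws)[1])) {
        v <- fit$draws[i, , 1]
        params <- list(
          s = v[["s"]], b = v[["b"]], zeta = v[["zeta"]],
          phi1 = v[["phi1"]], phi2 = v[["phi2"]], rho = v[["rho"]],
          chi = v[["chi"]], p_r_sb = v[["p_r_sb"]], N1c = v[["N1c"]],
          upsilon1 = v[["upsilon1"]], upsilon2 = v[["upsilon2"]],
          N1 = as.integer(v[["N_1"]]),
          D = as.integer(v[paste0("D_", seq_len(prep$Tn - 1L))]),
          R = as.integer(v[paste0("R_", seq_len(prep$Tn - 1L) + 1L)])
        )
        jp <- joint_logposterior(spec, params, prep)
        expect_equal(
          jp$logpost, v[["logpost"]],
          tolerance = 1e-8,
          label = paste("model", mid, variant, "draw", i)
        )
      }
    }
  }
})

test_that("pointwise row sums reproduce the data log-likelihood for every model", {
  ds <- tiny_sim()$dataset
  set.seed(17)
  for (mid in c("1a", "1b", "2", "3", "4")) {
    spec <- model_spec(mid, "constant", T_BP = 8)
    prep <- cetipm:::prepare_model_data(spec, ds)
    p <- random_params(spec, prep)
    jp <- joint_logposterior(spec, p, prep)
    pw <- pointwise_loglik(spec, p, prep)
    expect_equal(
      sum(pw),
      unname(sum(jp$terms[c("distances", "counts", "calf", "capture")])),
      tolerance = 1e-8, label = paste("model", mid)
    )
  }
})
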