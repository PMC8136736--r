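# Small-world fixtures shared across tests. Everything is generated in code;
# the default-scale world is only used where a test is explicitly about the
# calibrated defaults.

tiny_config <- function(...) {
  args <- modifyList(
    list(
      grid_cols = 8L, grid_rows = 4L, N0 = 60L,
      autocorr_range = 2, bump_col = 3, bump_row = 2.5, bump_sd = 2,
      ns_bump_col = 1.5, ns_bump_row = 2.5, ns_bump_sd = 1,
      survey_cols = 1:4, nearshore_cols = 1:2
    ),
    list(...)
  )
  do.call(sim_config, args)
}

tiny_design <- function(...) {
  survey_design(n_target = 4L, ...)
}

# one small scenario-B world, cached per session
tiny_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_scenario(tiny_config(), "B", tiny_design(), seed = 5)
    }
    cache
  }
})

# default-scale scenario world (expensive; used by a few tests), cached
default_sim <- local({
  cache <- NULL
  function(scenario = "B", seed = 3) {
    key <- paste(scenario, seed)
    if (is.null(cache) || !identical(attr(cache, "key"), key)) {
      cache <<- structure(
        simulate_scenario(sim_config(), scenario, survey_design(), seed = seed),
        key = key
      )
    }
    cache
  }
})

# named parameter set inside the support of every model
valid_params <- function(Tn = 16L, N1 = 1000L) {
  N <- numeric(Tn)
  N[1] <- N1
  D <- R <- integer(Tn - 1L)
  for (tau in seq_len(Tn - 1L)) {
    D[tau] <- round(N[tau] * 0.06)
    R[tau] <- round(N[tau] * 0.06)
    N[tau + 1] <- N[tau] - D[tau] + R[tau]
  }
  list(
    s = 0.1, b = 0.5, zeta = N1 / 3000, phi1 = 0.94, phi2 = 0.9,
    rho = 0.08, chi = 0.75, p_r_sb = 0.35, N1c = N1,
    upsilon1 = 0.0, upsilon2 = -0.05, N1 = as.integer(N1), D = D, R = R
  )
}

# draw a random parameter list from each model's support
random_params <- function(spec, prep) {
  p <- valid_params(prep$Tn)
  p$s <- runif(1, 0.05, 0.2)
  p$b <- runif(1, -1, 2)
  p$phi1 <- runif(1, 0.85, 0.99)
  p$phi2 <- runif(1, 0.85, 0.99)
  p$rho <- runif(1, 0.02, 0.18)
  p$chi <- runif(1, 0.6, min(p$phi1, p$phi2) - 0.01)
  p$p_r_sb <- runif(1, 0.1, 0.6)
  p$upsilon1 <- runif(1, -0.1, 0.1)
  p$upsilon2 <- runif(1, -0.1, 0.1)
  p
}
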