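# Model fitting by MCMC: R-side data marshalling, initialization, and the
# chain driver around the C++ Metropolis-within-Gibbs core.

#' MCMC configuration
#'
#' Defaults reproduce the published estimation protocol: two chains of
#' 100,000 iterations, burn-in 50,000, thinning 100, for 1,000 saved
#' parameter sets in total. `mcmc_config(preset = "desk")` is the reduced
#' preset used for desk-scale testing: 2 x 10,000 iterations, burn-in 5,000,
#' thinning 10 (the same 1,000 saved draws from shorter chains).
#'
#' @param n_chains number of chains.
#' @param n_iter iterations per chain.
#' @param burn_in burn-in iterations (discarded).
#' @param thin thinning interval.
#' @param preset `"full"` or `"desk"`; explicit arguments override.
#' @return an object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 2L, n_iter = NULL, burn_in = NULL,
                        thin = NULL, preset = c("full", "desk")) {
  preset <- match.arg(preset)
  def <- if (preset == "full") {
    list(n_iter = 100000L, burn_in = 50000L, thin = 100L)
  } else {
    list(n_iter = 10000L, burn_in = 5000L, thin = 10L)
  }
  cfg <- list(
    n_chains = as.integer(n_chains),
    n_iter = as.integer(if (is.null(n_iter)) def$n_iter else n_iter),
    burn_in = as.integer(if (is.null(burn_in)) def$burn_in else burn_in),
    thin = as.integer(if (is.null(thin)) def$thin else thin)
  )
  stopifnot(cfg$burn_in < cfg$n_iter, cfg$thin >= 1L, cfg$n_chains >= 1L)
  class(cfg) <- "mcmc_config"
  cfg
}

# marshal prepared data into the flat list the C++ core consumes
cpp_data_list <- function(spec, prep, prior_only = FALSE) {
  Tn <- prep$Tn
  sy <- prep$surveyed_years
  S_t <- vapply(
    sy, function(t) sum(prep$n_counts[prep$count_years == t]), numeric(1)
  )
  target <- matrix(0L, prep$K, Tn)
  for (t in seq_len(Tn)) target[prep$targets[[t]], t] <- 1L
  cap <- prep$cap
  dat <- list(
    T = Tn, K = prep$K,
    Sx2 = sum(prep$x^2), J = length(prep$x),
    x_max = prep$x_max, l = prep$l, A = prep$A, g0 = prep$g0,
    sy = as.integer(sy), S_t = as.numeric(S_t),
    n_counts = as.integer(prep$n_counts),
    count_cell = as.integer(prep$count_cells),
    count_sy = as.integer(match(prep$count_years, sy) - 1L),
    lgamma_const = sum(lgamma(prep$n_counts + 1)),
    region = prep$region_mask,
    target = target,
    H = prep$H,
    p_id_t = as.numeric(prep$p_id_t),
    calf_year = if (is.null(prep$calf)) integer(0) else as.integer(prep$calf$year),
    calf_nc = if (is.null(prep$calf)) integer(0) else as.integer(prep$calf$n_c),
    calf_N = if (is.null(prep$calf)) integer(0) else as.integer(prep$calf$N),
    n_ind = if (is.null(cap)) 0L else length(cap$first),
    M = as.integer(prep$M),
    first = if (is.null(cap)) integer(0) else as.integer(cap$first),
    Ys = if (is.null(cap)) {
      matrix(0L, 0, Tn)
    } else {
      matrix(as.integer(cap$Y_survey), nrow(cap$Y_survey), Tn)
    },
    Sbc = if (is.null(cap) || is.null(cap$Y_sb_count)) {
      matrix(0L, if (is.null(cap)) 0 else length(cap$first), Tn)
    } else {
      matrix(as.integer(cap$Y_sb_count), nrow(cap$Y_sb_count), Tn)
    }
  )
  if (prior_only) {
    dat$Sx2 <- 0
    dat$J <- 0L
    dat$sy <- integer(0)
    dat$S_t <- numeric(0)
    dat$n_counts <- integer(0)
    dat$count_cell <- integer(0)
    dat$count_sy <- integer(0)
    dat$lgamma_const <- 0
    dat$calf_year <- dat$calf_nc <- dat$calf_N <- integer(0)
    dat$n_ind <- 0L
    dat$first <- integer(0)
    dat$Ys <- matrix(0L, 0, Tn)
    dat$Sbc <- matrix(0L, 0, Tn)
  }
  dat
}

cpp_model_list <- function(spec, prep) {
  pr <- spec$priors
  list(
    model = match(spec$model, MODEL_IDS) - 1L,
    change = spec$variant == "change",
    T_BP = spec$T_BP,
    N_max = spec$N_max,
    phi_bounds = pr$phi_bounds,
    rho_bounds = pr$rho_bounds,
    chi_lower = pr$chi_lower,
    upsilon_bounds = pr$upsilon_bounds,
    b_sd = pr$b_sd,
    s_bounds = pr$s_bounds_mult * prep$x_max
  )
}

# initial values: detection scale from the raw distance spread, initial
# abundance from a design-based estimate of year-1 data, vital rates at
# bound midpoints, latent deaths/recruits at their expectations
init_state <- function(spec, prep, jitter = 0) {
  pr <- spec$priors
  s_bounds <- pr$s_bounds_mult * prep$x_max
  s0 <- if (length(prep$x) > 1) sqrt(mean(prep$x^2)) else prep$x_max / 2
  s0 <- min(max(s0, s_bounds[1] * 1.5), s_bounds[2] / 1.5)
  p_d0 <- segment_detection_prob(
    prep$l, esw_halfnormal(s0, prep$x_max), prep$g0, prep$A
  )
  S1 <- if (length(prep$surveyed_years)) {
    sum(prep$n_counts[prep$count_years == prep$surveyed_years[1]])
  } else {
    0
  }
  avail <- if (spec$model == "1a") 1 else 0.5
  N1_hat <- if (S1 > 0) S1 / (p_d0 * avail) else spec$N_max / 3
  N1_hat <- min(max(round(N1_hat), 10), spec$N_max - 10)
  if (jitter > 0) {
    N1_hat <- min(max(
      round(N1_hat * exp(runif(1, -jitter, jitter))), 10
    ), spec$N_max - 10)
    s0 <- min(max(s0 * exp(runif(1, -jitter, jitter)), s_bounds[1] * 1.2),
      s_bounds[2] / 1.2
    )
  }
  phi0 <- mean(pr$phi_bounds)
  rho0 <- mean(pr$rho_bounds)
  chi0 <- (pr$chi_lower + phi0) / 2
  Tn <- prep$Tn
  N <- numeric(Tn)
  N[1] <- N1_hat
  D <- R <- integer(Tn - 1L)
  for (tau in seq_len(Tn - 1L)) {
    D[tau] <- round(N[tau] * (1 - phi0))
    R[tau] <- round(N[tau] * rho0 * chi0)
    N[tau + 1L] <- N[tau] - D[tau] + R[tau]
  }
  list(
    s = s0, b = 0, zeta = N1_hat / spec$N_max,
    phi1 = phi0, phi2 = phi0, rho = rho0, chi = chi0,
    p_r_sb = 0.2, N1c = N1_hat,
    ups1 = 0, ups2 = 0,
    N1 = as.integer(N1_hat), D = D, R = R
  )
}

default_steps <- function() {
  c(
    s = 0.2, b = 0.2, phi1 = 0.5, phi2 = 0.5, rho = 0.5, chi = 0.5,
    p_r_sb = 0.3, N1c = 0.2, ups1 = 0.3, ups2 = 0.3, N1 = 25, latent = 8
  )
}

#' Fit an estimation model to a survey dataset by MCMC
#'
#' Runs the adaptive Metropolis-within-Gibbs sampler (C++ core) under the
#' published protocol. Identical seed and configuration give bit-identical
#' draws. Chains are initialized from a design-based abundance estimate with
#' mild deterministic jitter per chain.
#'
#' @param spec a [model_spec()].
#' @param data a `survey_dataset`.
#' @param mcmc an [mcmc_config()].
#' @param seed integer seed controlling all sampler randomness.
#' @param prior_only if TRUE, drop every data term and sample the prior
#'   (used for prior-recovery checks).
#' @return an object of class `cetipm_fit`: `draws` is an
#'   iterations x variables x chains array (variables include the model
#'   parameters, the abundance path `N_1 ... N_T`, `upsilon1`, `upsilon2`,
#'   `Delta`, `deviance` and `logpost`), plus acceptance rates and metadata.
#' @export
fit_model <- function(spec, data, mcmc = mcmc_config(), seed = 1L,
                      prior_only = FALSE) {
  stopifnot(inherits(spec, "model_spec"), inherits(mcmc, "mcmc_config"))
  prep <- if (inherits(data, "survey_dataset")) {
    prepare_model_data(spec, data)
  } else {
    data
  }
  dat <- cpp_data_list(spec, prep, prior_only = prior_only)
  mod <- cpp_model_list(spec, prep)
  steps <- default_steps()
  Tn <- prep$Tn
  vnames <- c(
    "s", "b", "zeta", "phi1", "phi2", "rho", "chi", "p_r_sb", "N1c",
    "upsilon1", "upsilon2", paste0("N_", seq_len(Tn)),
    paste0("D_", seq_len(Tn - 1L)), paste0("R_", seq_len(Tn - 1L) + 1L),
    "Delta", "deviance", "logpost", "lp_prior_proc"
  )
  n_save <- (mcmc$n_iter - mcmc$burn_in) %/% mcmc$thin
  draws <- array(
    NA_real_, c(n_save, length(vnames), mcmc$n_chains),
    dimnames = list(NULL, vnames, paste0("chain", seq_len(mcmc$n_chains)))
  )
  acc <- vector("list", mcmc$n_chains)
  for (ch in seq_len(mcmc$n_chains)) {
    res <- with_substream(seed, paste0("mcmc_chain", ch), {
      init <- init_state(spec, prep, jitter = if (ch == 1) 0 else 0.15)
      cpp_run_chain(
        mod, dat,
        list(
          n_iter = mcmc$n_iter, burn_in = mcmc$burn_in, thin = mcmc$thin
        ),
        init, steps
      )
    })
    draws[, , ch] <- res$draws
    acc[[ch]] <- res$acc
  }
  structure(
    list(
      spec = spec, draws = draws, acc = acc, mcmc = mcmc, seed = seed,
      prep = prep, prior_only = prior_only
    ),
    class = "cetipm_fit"
  )
}

#' @export
print.cetipm_fit <- function(x, ...) {
  d <- dim(x$draws)
  cat(
    "<cetipm_fit> Model", x$spec$model, paste0("(", x$spec$variant, ")"),
    "-", d[1], "draws x", d[3], "chains\n"
  )
  mon <- c("phi1", "rho", "chi", "upsilon1", paste0("N_", x$prep$Tn))
  mon <- mon[mon %in% dimnames(x$draws)[[2]]]
  sm <- t(vapply(mon, function(v) {
    vals <- as.vector(x$draws[, v, ])
    c(median = median(vals), q2.5 = quantile(vals, 0.025, names = FALSE),
      q97.5 = quantile(vals, 0.975, names = FALSE))
  }, numeric(3)))
  print(round(sm, 4))
  invisible(x)
}

#' Stack draws of one variable across chains
#'
#' @param fit a `cetipm_fit`.
#' @param var variable name.
#' @return numeric vector of pooled posterior draws.
#' @export
posterior_draws <- function(fit, var) {
  stopifnot(var %in% dimnames(fit$draws)[[2]])
  as.vector(fit$draws[, var, ])
}

#' Adaptive random-walk Metropolis sampler for a generic log-target
#'
#' The R mirror of the transformed-scale random-walk kernel used by the C++
#' core, exposed for contract testing (e.g. conjugate-toy posteriors with
#' known moments) and small ad-hoc targets. One Gaussian random walk per
#' coordinate on the transformed scale, Robbins-Monro adaptation of step
#' sizes toward 0.44 acceptance, frozen at the end of burn-in.
#'
#' @param logtarget function taking the parameter vector, returning the log
#'   density (may be `-Inf`).
#' @param init initial parameter vector.
#' @param lower,upper per-coordinate bounds (may be infinite); bounded
#'   coordinates are proposed on the logit scale, unbounded on the identity
#'   scale.
#' @param n_iter,burn_in,thin chain settings.
#' @param step initial step sizes.
#' @return matrix of saved draws.
#' @export
mh_sample <- function(logtarget, init, lower = -Inf, upper = Inf,
                      n_iter = 10000L, burn_in = 5000L, thin = 10L,
                      step = 0.5) {
  p <- length(init)
  lower <- rep_len(lower, p)
  upper <- rep_len(upper, p)
  step <- rep_len(step, p)
  to_z <- function(th, lo, hi) {
    if (is.finite(lo) && is.finite(hi)) {
      u <- (th - lo) / (hi - lo)
      log(u / (1 - u))
    } else {
      th
    }
  }
  from_z <- function(z, lo, hi) {
    if (is.finite(lo) && is.finite(hi)) lo + (hi - lo) * plogis(z) else z
  }
  ljac <- function(z, lo, hi) {
    if (is.finite(lo) && is.finite(hi)) {
      log(hi - lo) + plogis(z, log.p = TRUE) + plogis(-z, log.p = TRUE)
    } else {
      0
    }
  }
  th <- init
  lp <- logtarget(th)
  stopifnot(is.finite(lp))
  lstep <- log(step)
  n_save <- (n_iter - burn_in) %/% thin
  out <- matrix(NA_real_, n_save, p)
  row <- 0L
  for (iter in seq_len(n_iter)) {
    rate <- 1 / sqrt(iter / 50 + 1)
    for (j in seq_len(p)) {
      z <- to_z(th[j], lower[j], upper[j])
      znew <- z + exp(lstep[j]) * rnorm(1)
      thnew <- th
      thnew[j] <- from_z(znew, lower[j], upper[j])
      lpnew <- logtarget(thnew)
      la <- lpnew - lp + ljac(znew, lower[j], upper[j]) -
        ljac(z, lower[j], upper[j])
      accepted <- is.finite(lpnew) && log(runif(1)) < la
      if (accepted) {
        th <- thnew
        lp <- lpnew
      }
      if (iter <= burn_in) {
        lstep[j] <- lstep[j] + rate * (as.numeric(accepted) - 0.44)
      }
    }
    if (iter > burn_in && (iter - burn_in) %% thin == 0) {
      row <- row + 1L
      out[row, ] <- th
    }
  }
  out
}
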