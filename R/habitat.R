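# Habitat-field simulation.
#
# True suitability h[k, t] = exp(mu[k, t] + g[k, t]) where mu is a
# deterministic mean surface (a Gaussian bump whose centroid sits inside the
# survey region and, under the shifting scenario, mirrors across the region
# boundary after the change year) and g is a zero-mean Gaussian random field
# with separable squared-exponential correlation, redrawn independently each
# year. The measured covariate H mixes the standardized true suitability with
# independent noise at a fixed fidelity.

.cetipm_cache <- new.env(parent = emptyenv())

# Cholesky factor of the 1-D squared-exponential correlation matrix.
sqexp_chol_1d <- function(n, range) {
  key <- paste0("chol1d_", n, "_", format(range, digits = 12))
  if (!is.null(.cetipm_cache[[key]])) {
    return(.cetipm_cache[[key]])
  }
  d <- outer(seq_len(n), seq_len(n), "-")
  C <- exp(-d^2 / (2 * range^2))
  diag(C) <- diag(C) + 1e-9 # numerical nugget
  L <- t(chol(C))
  .cetipm_cache[[key]] <- L
  L
}

# One draw of the separable 2-D field, returned as a grid_rows x grid_cols
# matrix with unit marginal variance (up to the nugget).
draw_grf <- function(cfg) {
  Lr <- sqexp_chol_1d(cfg$grid_rows, cfg$autocorr_range)
  Lc <- sqexp_chol_1d(cfg$grid_cols, cfg$autocorr_range)
  z <- matrix(rnorm(cfg$grid_rows * cfg$grid_cols), cfg$grid_rows)
  Lr %*% z %*% t(Lc)
}

# Deterministic Gaussian bump (length-K vector) centred at (col0, row0).
bump_surface <- function(cfg, amplitude, col0, row0, bump_sd) {
  d2 <- (cfg$cell_col - col0)^2 + (cfg$cell_row - row0)^2
  amplitude * exp(-d2 / (2 * bump_sd^2))
}

# Mean log-suitability surface: persistent nearshore bump plus a mobile bump
# that sits at bump_col before the change year and mirrors across the
# survey-region boundary afterwards (shifting scenario only).
mean_surface <- function(cfg, amps, period = c("pre", "post")) {
  period <- match.arg(period)
  mobile_col <- if (period == "pre") cfg$bump_col else cfg$grid_cols + 1 - cfg$bump_col
  bump_surface(cfg, amps[["ns"]], cfg$ns_bump_col, cfg$ns_bump_row, cfg$ns_bump_sd) +
    bump_surface(cfg, amps[["mobile"]], mobile_col, cfg$bump_row, cfg$bump_sd)
}

mask_share_det <- function(cfg, amps, mask, period) {
  e <- exp(mean_surface(cfg, amps, period))
  sum(e[mask]) / sum(e)
}

#' Mean-surface amplitudes implied by the calibration targets
#'
#' Solves deterministically for the two mean-surface amplitudes: the
#' nearshore bump amplitude such that the nearshore area holds `ns_share` of
#' total mean suitability, and the mobile bump amplitude such that an
#' ordinary least-squares fit of log in-region suitability share on year
#' (a step change at `T_BP`) has slope `log(1 - decline_rate)`. The OLS
#' slope of a step series is `delta_log * Sxi / Sxx`, so the target slope
#' fixes the required pre/post log-share difference; nested root-finding on
#' the deterministic mean surface delivers both amplitudes. No stochastic
#' tuning is involved.
#'
#' @param cfg a [sim_config()].
#' @return named vector `c(ns = ..., mobile = ...)` of bump amplitudes
#'   (log-suitability units).
#' @export
solve_bump_amplitude <- function(cfg) {
  key <- paste0(
    "amp_", cfg$grid_cols, "_", cfg$grid_rows, "_",
    paste(format(c(cfg$bump_col, cfg$bump_row, cfg$bump_sd,
                   cfg$ns_bump_col, cfg$ns_bump_row, cfg$ns_bump_sd,
                   cfg$ns_share, cfg$decline_rate,
                   cfg$T_years, cfg$T_BP), digits = 12), collapse = "_")
  )
  if (!is.null(.cetipm_cache[[key]])) {
    return(.cetipm_cache[[key]])
  }
  t <- seq_len(cfg$T_years)
  xc <- t - mean(t)
  sxx <- sum(xc^2)
  sxi <- sum(xc[t > cfg$T_BP])
  delta_target <- log(1 - cfg$decline_rate) * sxx / sxi

  solve_ns <- function(a_mobile) {
    f <- function(a_ns) {
      mask_share_det(
        cfg, c(ns = a_ns, mobile = a_mobile), cfg$nearshore_mask, "pre"
      ) - cfg$ns_share
    }
    if (f(0) >= 0) 0 else uniroot(f, c(0, 50), tol = 1e-9)$root
  }
  g <- function(a_mobile) {
    amps <- c(ns = solve_ns(a_mobile), mobile = a_mobile)
    s_pre <- mask_share_det(cfg, amps, cfg$survey_region_mask, "pre")
    s_post <- mask_share_det(cfg, amps, cfg$survey_region_mask, "post")
    log(s_post) - log(s_pre) - delta_target
  }
  a_mobile <- if (g(0) <= 0) 0 else uniroot(g, c(0, 50), tol = 1e-9)$root
  amps <- c(ns = solve_ns(a_mobile), mobile = a_mobile)
  .cetipm_cache[[key]] <- amps
  amps
}

# Mixture weight delivering corr(H, h)^2 = fidelity when H = w z(h) + (1-w) e.
fidelity_weight <- function(fidelity) {
  sqrt(fidelity) / (sqrt(fidelity) + sqrt(1 - fidelity))
}

#' Generate the habitat field for one scenario realization
#'
#' Draws `T` yearly suitability surfaces over the grid. The latent field is
#' spatially autocorrelated (separable squared-exponential correlation with
#' the configured range) and is exponentiated to a positive suitability
#' index. Under `"random"` the mean surface is constant over years, so
#' year-to-year variation has no drift; under `"shifting"` the mean-surface
#' centroid mirrors to the opposite side of the survey-region boundary from
#' year `T_BP + 1` onward, relocating suitability mass out of the survey
#' region. The measured covariate `H` is generated alongside with the
#' configured fidelity (default: it explains one third of the within-year
#' variance of true suitability).
#'
#' The yearly Gaussian-field draws depend only on the seed, not on the
#' scenario, so matched seeds share habitat noise across scenarios (and the
#' first `T_BP` years of a shifting field equal the random field's).
#'
#' @param cfg a [sim_config()].
#' @param scenario_habitat `"random"` or `"shifting"`.
#' @param seed master seed; the habitat substream is derived from it.
#' @return an object of class `habitat_field` with elements `h` and `H`
#'   (cells x years matrices), `cell_area`, `cell_col`, `cell_row`,
#'   `scenario_habitat`, and `amplitude`.
#' @export
generate_habitat_field <- function(cfg, scenario_habitat = c("random", "shifting"),
                                   seed = cfg$seed) {
  validate_sim_config(cfg)
  scenario_habitat <- match.arg(scenario_habitat)
  if (cfg$autocorr_range <= 0) {
    stop("autocorrelation range must be positive", call. = FALSE)
  }
  amps <- solve_bump_amplitude(cfg)
  mu_pre <- mean_surface(cfg, amps, "pre")
  mu_post <- if (scenario_habitat == "shifting") {
    mean_surface(cfg, amps, "post")
  } else {
    mu_pre
  }
  K <- cfg$n_cells
  h <- matrix(NA_real_, K, cfg$T_years)
  H <- matrix(NA_real_, K, cfg$T_years)
  w <- fidelity_weight(cfg$fidelity)
  with_substream(seed, "habitat", {
    for (t in seq_len(cfg$T_years)) {
      g <- cfg$grf_sd * as.vector(draw_grf(cfg))
      mu <- if (t <= cfg$T_BP) mu_pre else mu_post
      h[, t] <- exp(mu + g)
      z <- (h[, t] - mean(h[, t])) / sd(h[, t])
      Hm <- w * z + (1 - w) * rnorm(K)
      H[, t] <- (Hm - mean(Hm)) / sd(Hm)
    }
  })
  structure(
    list(
      h = h, H = H, cell_area = 1,
      cell_col = cfg$cell_col, cell_row = cfg$cell_row,
      scenario_habitat = scenario_habitat, amplitude = amps
    ),
    class = "habitat_field"
  )
}

#' @export
print.habitat_field <- function(x, ...) {
  cat(
    "<habitat_field>", nrow(x$h), "cells x", ncol(x$h), "years,",
    x$scenario_habitat, "scenario, bump amplitudes",
    paste(signif(x$amplitude, 4), collapse = "/"), "\n"
  )
  invisible(x)
}
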