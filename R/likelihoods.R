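# Likelihood terms and process-model densities shared by all estimation
# models. These are the reference implementations: the C++ sampler core is
# tested against them, and they are themselves tested against closed-form,
# quadrature, pmf and exhaustive-enumeration oracles.

#' Habitat-based distribution probabilities
#'
#' Expected proportion of the population in each cell: a softmax of the
#' linear predictor `b . H_k` over cells (an ideal free distribution over
#' measured suitability). Overflow-guarded by max-subtraction.
#'
#' @param H_t covariate values for the K cells in one year (vector, or a
#'   K x p matrix for p covariates).
#' @param b coefficient (scalar, or length-p vector).
#' @return probability vector over the K cells, summing to 1.
#' @export
distribution_probs <- function(H_t, b) {
  eta <- if (is.matrix(H_t)) drop(H_t %*% b) else H_t * b
  if (!any(is.finite(eta))) {
    stop("all linear predictors are non-finite", call. = FALSE)
  }
  e <- exp(eta - max(eta))
  e / sum(e)
}

#' Effective strip half-width of a truncated half-normal detection function
#'
#' `ESW = integral_0^x_max exp(-x^2 / (2 s^2)) dx`, which equals `1/f(0)` for
#' the truncated half-normal distance density.
#'
#' @param s detection scale (standard deviation of the half-normal).
#' @param x_max truncation distance.
#' @return the effective strip half-width, in the units of `s`.
#' @export
esw_halfnormal <- function(s, x_max) {
  if (any(s <= 0) || any(x_max <= 0)) {
    stop("s and x_max must be positive", call. = FALSE)
  }
  s * sqrt(2 * pi) * (pnorm(x_max / s) - 0.5)
}

#' Per-cell detection probability of a transect segment
#'
#' `p.d = 2 l ESW g0 / A`: the probability that an individual present in a
#' cell of area `A` is detected from a segment of length `l`.
#'
#' @param l segment length.
#' @param esw effective strip half-width.
#' @param g0 detection probability on the line.
#' @param A cell area.
#' @return detection probability.
#' @export
segment_detection_prob <- function(l, esw, g0 = 1, A = 1) {
  if (any(l <= 0) || any(esw < 0) || any(A <= 0)) {
    stop("l and A must be positive, esw non-negative", call. = FALSE)
  }
  p <- 2 * l * esw * g0 / A
  if (any(p > 1 + 1e-12)) {
    stop("p.d > 1: survey geometry inconsistent (strip exceeds cell)",
      call. = FALSE
    )
  }
  pmin(p, 1)
}

#' Log-likelihood of perpendicular detection distances
#'
#' Half-normal detection: distances follow a normal(0, s^2) truncated to
#' `[0, x_max]`, with density `exp(-x^2/(2 s^2)) / ESW`.
#'
#' @param x distances.
#' @param s2 half-normal variance.
#' @param x_max truncation distance.
#' @param pointwise if TRUE also return per-distance contributions.
#' @return log-likelihood (with `pointwise` attribute if requested).
#' @export
loglik_distances <- function(x, s2, x_max, pointwise = FALSE) {
  if (length(x) == 0L) {
    return(if (pointwise) structure(0, pointwise = numeric(0)) else 0)
  }
  if (any(x < 0) || any(x > x_max)) {
    stop("distance outside the truncation window", call. = FALSE)
  }
  s <- sqrt(s2)
  pw <- -x^2 / (2 * s2) - log(esw_halfnormal(s, x_max))
  if (pointwise) structure(sum(pw), pointwise = pw) else sum(pw)
}

#' Log-likelihood of per-cell detection counts
#'
#' Counts are Poisson with mean `lambda_{k,t} = N_t * p.k_{k,t} * p.d_{k,t}`.
#'
#' @param n observed counts (vector over surveyed cell-years).
#' @param N_t total abundance matching each count.
#' @param p_k distribution probability of each counted cell.
#' @param p_d detection probability of each counted cell.
#' @param pointwise if TRUE attach per-count contributions.
#' @return log-likelihood with attribute `lambda` (and optionally
#'   `pointwise`).
#' @export
loglik_counts <- function(n, N_t, p_k, p_d, pointwise = FALSE) {
  if (any(n < 0)) stop("negative counts", call. = FALSE)
  lambda <- N_t * p_k * p_d
  if (any(lambda < 0)) stop("negative Poisson mean", call. = FALSE)
  pw <- dpois(n, lambda, log = TRUE)
  out <- structure(sum(pw), lambda = lambda)
  if (pointwise) attr(out, "pointwise") <- pw
  out
}

#' Log-probability of one demographic transition
#'
#' Binomial demographic model: deaths `D ~ Binomial(N_prev, 1 - phi)` and
#' recruits `R ~ Binomial(N_prev, rho * chi)`; the implied next abundance is
#' `N_prev - D + R`.
#'
#' @param N_prev abundance in the previous year.
#' @param D deaths out of `N_prev`.
#' @param R recruits (age-1 juveniles) produced by `N_prev`.
#' @param phi non-calf survival for this transition.
#' @param rho per-capita fecundity.
#' @param chi calf survival.
#' @return log-probability (`-Inf` for out-of-range latent values).
#' @export
demographic_step_logprob <- function(N_prev, D, R, phi, rho, chi) {
  if (D < 0 || D > N_prev || R < 0 || R > N_prev) {
    return(-Inf)
  }
  dbinom(D, N_prev, 1 - phi, log = TRUE) +
    dbinom(R, N_prev, rho * chi, log = TRUE)
}

#' Log-probability of the initial abundance
#'
#' `N1 ~ Binomial(N_max, zeta)` with inclusion parameter `zeta`.
#'
#' @param N1 initial abundance.
#' @param N_max maximum plausible population size.
#' @param zeta inclusion probability.
#' @return log-probability.
#' @export
initial_abundance_logprob <- function(N1, N_max, zeta) {
  if (N1 < 0 || N1 > N_max) {
    stop("N1 must lie in [0, N_max]", call. = FALSE)
  }
  dbinom(N1, N_max, zeta, log = TRUE)
}

#' Derived long-term trend and change parameters
#'
#' `upsilon = log(rho * chi + phi)` is the log of the annual multiplier of
#' the binomial demographic model; `Delta = upsilon_2 - upsilon_1` quantifies
#' a change in trend between the two halves of the study.
#'
#' @param rho,chi,phi vital rates.
#' @return log trend.
#' @export
derived_trend <- function(rho, chi, phi) {
  g <- rho * chi + phi
  if (any(g <= 0)) stop("rho * chi + phi must be positive", call. = FALSE)
  log(g)
}

#' @rdname derived_trend
#' @param upsilon1,upsilon2 pre- and post-change trends.
#' @export
derived_change <- function(upsilon1, upsilon2) {
  upsilon2 - upsilon1
}

#' Deterministic exponential population trajectory
#'
#' Constant variant: `N_t = N1 exp(upsilon (t - 1))`. Change variant: the
#' growth rate switches from `upsilon1` to `upsilon2` after `T_BP`, with the
#' trajectory continuous at the change point.
#'
#' @param N1 initial abundance.
#' @param upsilon growth rate (constant variant), or pre-change rate.
#' @param T_years horizon.
#' @param upsilon2 post-change rate (enables the change variant).
#' @param T_BP change year (required with `upsilon2`).
#' @return abundance vector of length `T_years`.
#' @export
exponential_trajectory <- function(N1, upsilon, T_years,
                                   upsilon2 = NULL, T_BP = NULL) {
  if (N1 <= 0) stop("N1 must be positive", call. = FALSE)
  t <- seq_len(T_years)
  if (is.null(upsilon2)) {
    return(N1 * exp(upsilon * (t - 1)))
  }
  stopifnot(!is.null(T_BP), T_BP >= 1L, T_BP < T_years)
  # transition from year tau to tau+1 uses upsilon2 once tau >= T_BP, so the
  # post-change rate acts on years T_BP+1 ... T (continuous at T_BP),
  # matching the change-point convention of the demographic variant
  trans_rate <- ifelse(seq_len(T_years - 1L) < T_BP, upsilon, upsilon2)
  N1 * exp(cumsum(c(0, trans_rate)))
}

#' Log-likelihood of a calf index
#'
#' `n.c ~ Binomial(N, rho / (rho chi + phi))`: the expected proportion of
#' cows with calves among detected (or identified) animals, given that calves
#' present in year t were produced by the previous year's population.
#'
#' @param n_c cows with calves (vector over years).
#' @param N index denominator (detected or identified animals).
#' @param rho,chi,phi vital rates.
#' @param pointwise if TRUE attach per-year contributions.
#' @return log-likelihood.
#' @export
calf_index_logprob <- function(n_c, N, rho, chi, phi, pointwise = FALSE) {
  p <- rho / (rho * chi + phi)
  if (p < 0 || p > 1) {
    stop("calf-index proportion outside [0, 1]", call. = FALSE)
  }
  if (any(n_c < 0) || any(n_c > N)) {
    stop("calf count exceeds denominator", call. = FALSE)
  }
  pw <- dbinom(n_c, N, p, log = TRUE)
  if (pointwise) structure(sum(pw), pointwise = pw) else sum(pw)
}

#' Availability probabilities over the three sampling strata
#'
#' Partitions the distribution probabilities into: targeted small-boat cells
#' (`p.a1`), the rest of the survey region (`p.a2`), and outside the survey
#' region (`p.a3`). `p.a1 + p.a2` is the probability of being available to
#' the line-transect survey.
#'
#' @param p_k distribution probabilities over all cells (sums to 1).
#' @param region_mask logical mask of survey-region cells.
#' @param targets integer indices of targeted cells (must lie in the region;
#'   may be empty).
#' @return named vector `c(pa1, pa2, pa3)`.
#' @export
availability_probs <- function(p_k, region_mask, targets = integer(0)) {
  if (abs(sum(p_k) - 1) > 1e-8) {
    stop("p_k must sum to 1", call. = FALSE)
  }
  if (length(targets) && !all(region_mask[targets])) {
    stop("target cells must lie inside the survey region", call. = FALSE)
  }
  pa1 <- sum(p_k[targets])
  pa2 <- sum(p_k[region_mask]) - pa1
  pa3 <- 1 - pa1 - pa2
  c(pa1 = pa1, pa2 = pa2, pa3 = max(pa3, 0))
}

#' Marginal log-likelihood of capture histories
#'
#' Exact marginal probability of the observed post-first-capture history of
#' each cataloged individual, jointly over the line-transect survey captures
#' and (optionally) the small-boat robust-design captures. The latent alive
#' state (absorbing death, survival `phi_t`) and the yearly three-state
#' availability draw (targeted cells / rest of survey region / outside) are
#' marginalized analytically by a forward recursion; within a year, survey
#' and small-boat captures are conditionally independent given the shared
#' availability state.
#'
#' @param Y_survey n x T 0/1 matrix of survey captures (ignored outside
#'   survey years), or NULL if the survey platform is not modeled.
#' @param Y_sb_count n x T matrix of small-boat capture counts (0..M), or
#'   NULL when `sources = "survey_only"`.
#' @param first integer vector: first-capture year of each individual (the
#'   history is conditioned on it).
#' @param phi_t survival probabilities for transitions 1->2, ..., (T-1)->T.
#' @param pa 3 x T matrix of availability probabilities (rows: targeted,
#'   region non-targeted, outside region).
#' @param pr_survey_t length-T vector: per-year survey recapture probability
#'   given availability in the region (0 in years without a survey).
#' @param p_r_sb per-occasion small-boat capture probability given presence
#'   in a targeted cell.
#' @param M number of secondary occasions.
#' @param sources `"survey_only"` (Model 3) or `"both"` (Model 4).
#' @param pointwise if TRUE, attach the per-individual log-likelihoods.
#' @return total log-likelihood.
#' @export
capture_history_loglik <- function(Y_survey, Y_sb_count, first, phi_t, pa,
                                   pr_survey_t, p_r_sb = 0, M = 0L,
                                   sources = c("both", "survey_only"),
                                   pointwise = FALSE) {
  sources <- match.arg(sources)
  n <- length(first)
  Tn <- ncol(pa)
  stopifnot(length(phi_t) == Tn - 1L, length(pr_survey_t) == Tn)
  if (any(pr_survey_t < 0 | pr_survey_t > 1, na.rm = TRUE) ||
    p_r_sb < 0 || p_r_sb > 1 || any(phi_t < 0 | phi_t > 1)) {
    stop("probability parameters outside [0, 1]", call. = FALSE)
  }
  use_sb <- sources == "both"
  ll <- numeric(n)
  for (i in seq_len(n)) {
    t0 <- first[i]
    if (!is.na(t0) && t0 < Tn) {
      if (any(Y_survey[i, seq_len(t0 - 1)] > 0) ||
        (use_sb && any(Y_sb_count[i, seq_len(t0 - 1)] > 0))) {
        stop("capture before first-capture year for individual ", i,
          call. = FALSE
        )
      }
    }
    wa <- 1
    wd <- 0
    if (is.na(t0) || t0 >= Tn) {
      ll[i] <- 0
      next
    }
    for (t in (t0 + 1L):Tn) {
      ph <- phi_t[t - 1L]
      wd <- wd + wa * (1 - ph)
      wa <- wa * ph
      y <- if (!is.null(Y_survey)) Y_survey[i, t] else 0L
      # pr_survey_t is zero in years without a survey, so a y = 1 there gets
      # emission 0 and the year is otherwise uninformative, as required
      pr <- pr_survey_t[t]
      c_sb <- if (use_sb) Y_sb_count[i, t] else 0L
      e_states <- numeric(3)
      for (s_av in 1:3) {
        e <- pa[s_av, t]
        p_det <- if (s_av <= 2) pr else 0
        e <- e * if (y == 1L) p_det else 1 - p_det
        if (use_sb) {
          p_occ <- if (s_av == 1L) p_r_sb else 0
          e <- e * if (c_sb > 0L && s_av != 1L) {
            0
          } else {
            p_occ^c_sb * (1 - p_occ)^(M - c_sb)
          }
        }
        e_states[s_av] <- e
      }
      e_alive <- sum(e_states)
      all_zero <- y == 0L && c_sb == 0L
      wa <- wa * e_alive
      wd <- wd * as.numeric(all_zero)
    }
    ll[i] <- log(wa + wd)
  }
  total <- sum(ll)
  if (pointwise) structure(total, by_individual = ll) else total
}
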