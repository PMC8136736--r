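# Model specification and the reference joint log-posterior.
#
# The model ladder follows the published likelihood matrix:
#   1a: exponential population model, uniform distribution over the survey
#       region (N_t is survey-region abundance), distances + counts.
#   1b: exponential population model, habitat-based distribution over the
#       full grid, distances + counts.
#   2:  binomial demographic model + habitat + survey calf index.
#   3:  Model 2 + CJS mark-recapture from the line-transect survey.
#   4:  Model 3 + robust-design small-boat mark-recapture, with the calf
#       index switched to identified individuals.
# Each model has a constant-trend variant and a change-in-trend variant in
# which only survival (Models 2-4) or the exponential rate (Model 1) differs
# between the two halves of the study.

MODEL_IDS <- c("1a", "1b", "2", "3", "4")

#' Specify an estimation model
#'
#' @param model one of `"1a"`, `"1b"`, `"2"`, `"3"`, `"4"`.
#' @param variant `"constant"` or `"change"` (change-in-trend).
#' @param T_BP hypothesized change year (used by the change variant).
#' @param N_max maximum plausible population size (binomial initial-abundance
#'   prior; also the upper bound of the exponential model's N1 prior).
#' @param priors optional overrides: a list with any of `phi_bounds`,
#'   `rho_bounds`, `chi_lower`, `upsilon_bounds`, `b_sd`, `s_bounds_mult`
#'   (bounds on the detection scale as multiples of `x_max`).
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(model = MODEL_IDS, variant = c("constant", "change"),
                       T_BP = 8L, N_max = 3000L, priors = list()) {
  model <- match.arg(model)
  variant <- match.arg(variant)
  pr <- modifyList(
    list(
      phi_bounds = c(0.8, 1),
      rho_bounds = c(0, 0.2),
      chi_lower = 0.6,
      upsilon_bounds = c(log(0.8), log(1.2)),
      b_sd = 10,
      s_bounds_mult = c(0.01, 4)
    ),
    priors
  )
  structure(
    list(
      model = model,
      variant = variant,
      T_BP = as.integer(T_BP),
      N_max = as.integer(N_max),
      pop_process = if (model %in% c("1a", "1b")) "exponential" else "binomial",
      habitat = model != "1a",
      calf = switch(model, "1a" = , "1b" = "none", "2" = , "3" = "survey", "4" = "id"),
      capture = switch(model, "1a" = , "1b" = , "2" = "none", "3" = "survey", "4" = "both"),
      priors = pr
    ),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat(
    "<model_spec> Model", x$model, paste0("(", x$variant, " trend)"),
    "-", x$pop_process, "population process;",
    if (x$habitat) "habitat-based" else "uniform", "distribution;",
    "calf index:", x$calf, "; mark-recapture:", x$capture, "\n"
  )
  invisible(x)
}

# Precompute everything the likelihood needs from a survey_dataset.
# Shared by the R reference implementation and the C++ sampler.
prepare_model_data <- function(spec, data) {
  stopifnot(inherits(spec, "model_spec"), inherits(data, "survey_dataset"))
  Tn <- data$T_years
  des <- data$design
  if (spec$capture == "both" && nrow(data$Y_survey) == 0L) {
    stop("Model 4 requires capture histories; the dataset has none",
      call. = FALSE
    )
  }
  # equal-effort design: l, A, x_max constant over surveyed cell-years
  if (length(unique(data$counts$l)) != 1L ||
    length(unique(data$counts$A)) != 1L ||
    length(unique(data$counts$x_max)) != 1L) {
    stop("count effort columns are not constant; equal-effort design required",
      call. = FALSE
    )
  }
  region_cells <- which(data$survey_region_mask)
  surveyed_years <- sort(unique(data$counts$year))
  # counts ordered year-major, cell within year
  ord <- order(data$counts$year, data$counts$cell)
  counts <- data$counts[ord, ]
  p_id_t <- rep(0, Tn)
  p_id_t[data$p_id_data$year] <- ifelse(
    is.na(data$p_id_data$p_id), 0, data$p_id_data$p_id
  )

  # capture-history catalog for the active sources
  cap <- NULL
  if (spec$capture == "survey") {
    keep <- which(!is.na(data$first_survey))
    cap <- list(
      Y_survey = data$Y_survey[keep, , drop = FALSE],
      Y_sb_count = NULL,
      first = data$first_survey[keep],
      sources = "survey_only"
    )
  } else if (spec$capture == "both") {
    sbc <- apply(data$Y_sb, c(1L, 3L), sum)
    cap <- list(
      Y_survey = data$Y_survey,
      Y_sb_count = sbc,
      Y_sb_occ = data$Y_sb,
      first = data$first_any,
      sources = "both"
    )
  }
  calf <- switch(spec$calf,
    none = NULL,
    survey = data$calf_survey,
    id = data$calf_id[data$calf_id$N > 0, , drop = FALSE]
  )
  list(
    Tn = Tn,
    K = data$n_cells,
    x = data$distances$x,
    x_max = counts$x_max[1L],
    l = counts$l[1L],
    A = counts$A[1L],
    g0 = des$g0,
    n_counts = counts$n,
    count_cells = counts$cell,
    count_years = counts$year,
    surveyed_years = surveyed_years,
    region_cells = region_cells,
    region_mask = data$survey_region_mask,
    H = data$H,
    targets = data$targets,
    p_id_t = p_id_t,
    calf = calf,
    cap = cap,
    M = des$M
  )
}

# Availability matrix (3 x T): targeted cells / region minus targets /
# outside region, from the distribution probabilities.
availability_matrix <- function(p_k_mat, prep) {
  Tn <- prep$Tn
  pa <- matrix(0, 3, Tn)
  for (t in seq_len(Tn)) {
    pa[, t] <- availability_probs(
      p_k_mat[, t], prep$region_mask, prep$targets[[t]]
    )
  }
  pa
}

#' Joint log-posterior of a model given a dataset
#'
#' Reference (pure R) implementation of the full joint density: the sum of
#' the active data likelihood terms for the model (distances and counts for
#' all models; calf index for Models 2-4; survey capture histories for
#' Models 3-4; small-boat histories for Model 4), the population process
#' (binomial demographic prior for Models 2-4, deterministic exponential
#' trajectory for Models 1a/1b), and the parameter priors. Used as the
#' oracle for the C++ sampler core and for term-level tests; returns `-Inf`
#' (never an error) for parameters outside the prior support.
#'
#' @param spec a [model_spec()].
#' @param params named list of parameters; see Details.
#' @param data a `survey_dataset` (or the result of an internal
#'   `prepare_model_data()` call).
#' @details Parameters by model: all models use `s` (detection scale) and,
#'   except 1a, `b` (habitat coefficient). Models 1a/1b: `N1c` (initial
#'   abundance, continuous) and `upsilon1` (plus `upsilon2` for the change
#'   variant). Models 2-4: `zeta`, `N1` (integer), `D` and `R` (latent
#'   deaths/recruits, length `T - 1`), `phi1` (plus `phi2` for change),
#'   `rho`, `chi`; Model 4 adds `p_r_sb`.
#' @return list with `logpost`, named `terms`, the implied `N_t`, trend(s)
#'   `upsilon`, and `Delta` (change variant).
#' @export
joint_logposterior <- function(spec, params, data) {
  prep <- if (inherits(data, "survey_dataset")) {
    prepare_model_data(spec, data)
  } else {
    data
  }
  pr <- spec$priors
  Tn <- prep$Tn
  out <- list(
    logpost = -Inf,
    terms = c(
      distances = NA_real_, counts = NA_real_, calf = NA_real_,
      capture = NA_real_, process = NA_real_, priors = NA_real_
    ),
    N_t = rep(NA_real_, Tn), upsilon = NA_real_, Delta = NA_real_
  )
  s_bounds <- pr$s_bounds_mult * prep$x_max
  s <- params$s
  if (s <= s_bounds[1] || s >= s_bounds[2]) {
    return(out)
  }
  lp_prior <- -log(diff(s_bounds)) # flat prior on the detection scale

  # distribution probabilities and detection
  if (spec$habitat) {
    b <- params$b
    lp_prior <- lp_prior + dnorm(b, 0, pr$b_sd, log = TRUE)
    p_k_mat <- apply(prep$H, 2L, distribution_probs, b = b)
  }
  esw <- esw_halfnormal(s, prep$x_max)
  p_d <- segment_detection_prob(prep$l, esw, prep$g0, prep$A)

  # population process and trend
  change <- spec$variant == "change"
  if (spec$pop_process == "exponential") {
    if (params$N1c <= 0 || params$N1c > spec$N_max) {
      return(out)
    }
    ub <- pr$upsilon_bounds
    ups1 <- params$upsilon1
    ups2 <- if (change) params$upsilon2 else NULL
    if (ups1 <= ub[1] || ups1 >= ub[2]) {
      return(out)
    }
    if (change && (ups2 <= ub[1] || ups2 >= ub[2])) {
      return(out)
    }
    lp_prior <- lp_prior - log(spec$N_max) - log(diff(ub)) * (1 + change)
    N_t <- exponential_trajectory(
      params$N1c, ups1, Tn,
      upsilon2 = ups2, T_BP = if (change) spec$T_BP else NULL
    )
    lp_process <- 0
    upsilon <- c(ups1, ups2)
  } else {
    phi1 <- params$phi1
    phi2 <- if (change) params$phi2 else phi1
    rho <- params$rho
    chi <- params$chi
    zeta <- params$zeta
    if (phi1 <= pr$phi_bounds[1] || phi1 >= pr$phi_bounds[2] ||
      phi2 <= pr$phi_bounds[1] || phi2 >= pr$phi_bounds[2] ||
      rho <= pr$rho_bounds[1] || rho >= pr$rho_bounds[2] ||
      chi <= pr$chi_lower || chi >= min(phi1, phi2) ||
      zeta <= 0 || zeta >= 1) {
      return(out)
    }
    lp_prior <- lp_prior - log(diff(pr$phi_bounds)) * (1 + change) -
      log(diff(pr$rho_bounds)) - log(min(phi1, phi2) - pr$chi_lower)
    D <- params$D
    R <- params$R
    N1 <- params$N1
    if (N1 < 0 || N1 > spec$N_max) {
      return(out)
    }
    N_t <- numeric(Tn)
    N_t[1] <- N1
    lp_process <- initial_abundance_logprob(N1, spec$N_max, zeta)
    for (tau in seq_len(Tn - 1L)) {
      ph <- if (tau >= spec$T_BP) phi2 else phi1
      lp_process <- lp_process +
        demographic_step_logprob(N_t[tau], D[tau], R[tau], ph, rho, chi)
      N_t[tau + 1L] <- N_t[tau] - D[tau] + R[tau]
      if (N_t[tau + 1L] < 0 || N_t[tau + 1L] > spec$N_max) {
        return(out)
      }
    }
    if (!is.finite(lp_process)) {
      out$N_t <- N_t
      return(out)
    }
    upsilon <- c(
      derived_trend(rho, chi, phi1),
      if (change) derived_trend(rho, chi, phi2)
    )
  }

  # distances
  ll_dist <- loglik_distances(prep$x, s^2, prep$x_max)

  # counts
  yr_idx <- prep$count_years
  if (spec$habitat) {
    p_k_counts <- p_k_mat[cbind(prep$count_cells, yr_idx)]
  } else {
    p_k_counts <- rep(1 / length(prep$region_cells), length(prep$n_counts))
  }
  ll_counts <- as.numeric(
    loglik_counts(prep$n_counts, N_t[yr_idx], p_k_counts, p_d)
  )

  # calf index: the proportion uses the survival rate in force in each year
  ll_calf <- 0
  if (spec$calf != "none") {
    pre <- prep$calf$year <= spec$T_BP
    ll_calf <- if (change) {
      calf_index_logprob(
        prep$calf$n_c[pre], prep$calf$N[pre], rho, chi, phi1
      ) + calf_index_logprob(
        prep$calf$n_c[!pre], prep$calf$N[!pre], rho, chi, phi2
      )
    } else {
      calf_index_logprob(prep$calf$n_c, prep$calf$N, rho, chi, phi1)
    }
  }

  # capture histories
  ll_cap <- 0
  if (spec$capture != "none") {
    if (spec$capture == "both" &&
      (params$p_r_sb <= 0 || params$p_r_sb >= 1)) {
      return(out)
    }
    phi_t <- vapply(seq_len(Tn - 1L), function(tau) {
      if (change && tau >= spec$T_BP) phi2 else phi1
    }, numeric(1))
    pa <- availability_matrix(p_k_mat, prep)
    pr_survey_t <- rep(0, Tn)
    pr_survey_t[prep$surveyed_years] <-
      p_d * prep$p_id_t[prep$surveyed_years]
    ll_cap <- capture_history_loglik(
      prep$cap$Y_survey, prep$cap$Y_sb_count, prep$cap$first,
      phi_t, pa, pr_survey_t,
      p_r_sb = if (spec$capture == "both") params$p_r_sb else 0,
      M = prep$M, sources = prep$cap$sources
    )
  }

  terms <- c(
    distances = ll_dist, counts = ll_counts, calf = ll_calf,
    capture = ll_cap, process = lp_process, priors = lp_prior
  )
  list(
    logpost = sum(terms),
    terms = terms,
    N_t = N_t,
    upsilon = upsilon,
    Delta = if (change) derived_change(upsilon[1], upsilon[2]) else NA_real_
  )
}
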