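# Pointwise log-likelihood contributions for WAIC.
#
# Datum granularity: one datum per detected distance, per surveyed
# cell-year count, per calf-index year, per individual-year (survey capture
# histories) and per individual-occasion-year (small-boat histories). The
# capture-history likelihood is marginal over latent alive and availability
# states, so its pointwise units are sequential predictive increments
# (within a year: the survey observation first, then occasions 1..M); the
# increments sum exactly to the marginal log-likelihood.

capture_pointwise <- function(Y_survey, Y_sb_occ, first, phi_t, pa,
                              pr_survey_t, p_r_sb, M, sources,
                              survey_years) {
  n <- length(first)
  Tn <- ncol(pa)
  use_sb <- sources == "both"
  pw_survey <- matrix(NA_real_, n, Tn)
  pw_sb <- if (use_sb) array(NA_real_, c(n, M, Tn)) else NULL
  wa <- rep(1, n)
  wd <- rep(0, n)
  for (t in 2:Tn) {
    active <- !is.na(first) & first < t
    if (!any(active)) next
    ph <- phi_t[t - 1L]
    wd[active] <- wd[active] + wa[active] * (1 - ph)
    wa[active] <- wa[active] * ph
    wa3 <- cbind(wa * pa[1, t], wa * pa[2, t], wa * pa[3, t])
    if (t %in% survey_years) {
      y <- Y_survey[, t]
      tot0 <- rowSums(wa3) + wd
      pr <- pr_survey_t[t]
      fac12 <- ifelse(y == 1L, pr, 1 - pr)
      wa3[, 1] <- wa3[, 1] * fac12
      wa3[, 2] <- wa3[, 2] * fac12
      wa3[, 3] <- wa3[, 3] * ifelse(y == 1L, 0, 1)
      wd <- wd * ifelse(y == 1L, 0, 1)
      tot1 <- rowSums(wa3) + wd
      pw_survey[active, t] <- log(tot1[active]) - log(tot0[active])
    }
    if (use_sb) {
      for (m in seq_len(M)) {
        y <- Y_sb_occ[, m, t]
        tot0 <- rowSums(wa3) + wd
        wa3[, 1] <- wa3[, 1] * ifelse(y == 1L, p_r_sb, 1 - p_r_sb)
        zero <- ifelse(y == 1L, 0, 1)
        wa3[, 2] <- wa3[, 2] * zero
        wa3[, 3] <- wa3[, 3] * zero
        wd <- wd * zero
        tot1 <- rowSums(wa3) + wd
        pw_sb[active, m, t] <- log(tot1[active]) - log(tot0[active])
      }
    }
    wa <- rowSums(wa3)
    # individuals not yet cataloged in year t are untouched by construction:
    # restore their initial conditioning weights
    wa[!active] <- 1
    wd[!active] <- 0
  }
  list(survey = pw_survey, sb = pw_sb)
}

#' Pointwise log-likelihood of one parameter set
#'
#' Evaluates the per-datum log-likelihood contributions of the active data
#' terms of a model at one parameter set. The concatenated contributions sum
#' to the total data log-likelihood (the joint log-posterior minus process
#' and prior terms) to numerical precision.
#'
#' @param spec a [model_spec()].
#' @param params named parameter list (see [joint_logposterior()]).
#' @param data a `survey_dataset`.
#' @return named numeric vector of pointwise contributions; names encode the
#'   datum (`dist_j`, `count_cell.year`, `calf_year`, `caps_i.year`,
#'   `capb_i.m.year`).
#' @export
pointwise_loglik <- function(spec, params, data) {
  prep <- if (inherits(data, "survey_dataset")) {
    prepare_model_data(spec, data)
  } else {
    data
  }
  change <- spec$variant == "change"
  s <- params$s
  esw <- esw_halfnormal(s, prep$x_max)
  p_d <- segment_detection_prob(prep$l, esw, prep$g0, prep$A)

  out <- list()
  pw_d <- attr(
    loglik_distances(prep$x, s^2, prep$x_max, pointwise = TRUE), "pointwise"
  )
  names(pw_d) <- paste0("dist_", seq_along(pw_d))
  out$distances <- pw_d

  N_t <- if (!is.null(prep$N_path_override)) {
    prep$N_path_override
  } else {
    joint_logposterior(spec, params, prep)$N_t
  }
  if (spec$habitat) {
    p_k_mat <- apply(prep$H, 2L, distribution_probs, b = params$b)
    p_k_counts <- p_k_mat[cbind(prep$count_cells, prep$count_years)]
  } else {
    p_k_counts <- rep(1 / length(prep$region_cells), length(prep$n_counts))
  }
  pw_c <- attr(
    loglik_counts(prep$n_counts, N_t[prep$count_years], p_k_counts, p_d,
      pointwise = TRUE
    ),
    "pointwise"
  )
  names(pw_c) <- paste0("count_", prep$count_cells, ".", prep$count_years)
  out$counts <- pw_c

  if (spec$calf != "none") {
    phi1 <- params$phi1
    phi2 <- if (change) params$phi2 else phi1
    ph_year <- ifelse(prep$calf$year <= spec$T_BP, phi1, phi2)
    pw_cf <- vapply(seq_len(nrow(prep$calf)), function(i) {
      calf_index_logprob(
        prep$calf$n_c[i], prep$calf$N[i], params$rho, params$chi, ph_year[i]
      )
    }, numeric(1))
    names(pw_cf) <- paste0("calf_", prep$calf$year)
    out$calf <- pw_cf
  }

  if (spec$capture != "none") {
    Tn <- prep$Tn
    phi1 <- params$phi1
    phi2 <- if (change) params$phi2 else phi1
    phi_t <- ifelse(seq_len(Tn - 1L) >= spec$T_BP, phi2, phi1)
    pa <- availability_matrix(
      apply(prep$H, 2L, distribution_probs, b = params$b), prep
    )
    pr_survey_t <- rep(0, Tn)
    pr_survey_t[prep$surveyed_years] <- p_d * prep$p_id_t[prep$surveyed_years]
    cp <- capture_pointwise(
      prep$cap$Y_survey, prep$cap$Y_sb_occ, prep$cap$first, phi_t, pa,
      pr_survey_t,
      p_r_sb = if (spec$capture == "both") params$p_r_sb else 0,
      M = prep$M, sources = prep$cap$sources,
      survey_years = prep$surveyed_years
    )
    ps <- cp$survey
    keep <- which(!is.na(ps), arr.ind = TRUE)
    v <- ps[keep]
    names(v) <- paste0("caps_", keep[, 1], ".", keep[, 2])
    out$cap_survey <- v
    if (!is.null(cp$sb)) {
      keep <- which(!is.na(cp$sb), arr.ind = TRUE)
      v <- cp$sb[keep]
      names(v) <- paste0(
        "capb_", keep[, 1], ".", keep[, 2], ".", keep[, 3]
      )
      out$cap_sb <- v
    }
  }
  unlist(unname(out))
}
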