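# WAIC model comparison and change-in-trend posterior summaries.

#' Watanabe's information criterion from pointwise log-likelihoods
#'
#' `lppd = sum_datum log mean_draw exp(ll)` (computed with log-sum-exp
#' stabilization), `p_waic = sum_datum var_draw(ll)`, and
#' `waic = -2 (lppd - p_waic)`.
#'
#' @param pointwise draws x datum matrix of pointwise log-likelihoods.
#' @return named vector `c(waic, p_waic, lppd)`.
#' @export
waic <- function(pointwise) {
  stopifnot(is.matrix(pointwise), nrow(pointwise) >= 2L,
    ncol(pointwise) >= 1L)
  if (any(!is.finite(pointwise))) {
    stop("non-finite pointwise log-likelihood entries", call. = FALSE)
  }
  S <- nrow(pointwise)
  mx <- apply(pointwise, 2L, max)
  lppd <- sum(mx + log(colMeans(exp(sweep(pointwise, 2L, mx)))))
  p_waic <- sum(apply(pointwise, 2L, var))
  c(waic = -2 * (lppd - p_waic), p_waic = p_waic, lppd = lppd)
}

#' Pointwise log-likelihood matrix of a fitted model
#'
#' Evaluates [pointwise_loglik()] at every saved draw.
#'
#' @param fit a [fit_model()] result.
#' @param data the `survey_dataset` the model was fit to.
#' @return draws x datum matrix with datum labels as column names.
#' @export
pointwise_matrix <- function(fit, data) {
  stopifnot(inherits(fit, "cetipm_fit"))
  prep <- if (inherits(data, "survey_dataset")) {
    prepare_model_data(fit$spec, data)
  } else {
    data
  }
  if (fit$spec$capture == "both" && is.null(prep$cap$Y_sb_occ)) {
    stop("occasion-level small-boat data required for the pointwise matrix",
      call. = FALSE
    )
  }
  vars <- dimnames(fit$draws)[[2]]
  n_save <- dim(fit$draws)[1]
  chains <- dim(fit$draws)[3]
  rows <- n_save * chains
  first <- TRUE
  out <- NULL
  r <- 0L
  for (ch in seq_len(chains)) {
    for (i in seq_len(n_save)) {
      v <- fit$draws[i, , ch]
      params <- list(
        s = v[["s"]], b = v[["b"]], zeta = v[["zeta"]],
        phi1 = v[["phi1"]], phi2 = v[["phi2"]], rho = v[["rho"]],
        chi = v[["chi"]], p_r_sb = v[["p_r_sb"]], N1c = v[["N1c"]],
        upsilon1 = v[["upsilon1"]], upsilon2 = v[["upsilon2"]],
        N1 = v[[paste0("N_", 1L)]],
        D = NA, R = NA
      )
      # rebuild latent D/R from the saved abundance path
      N_path <- v[paste0("N_", seq_len(prep$Tn))]
      params$N1 <- as.integer(round(N_path[1]))
      pw <- pointwise_loglik_path(fit$spec, params, prep, N_path)
      if (first) {
        out <- matrix(NA_real_, rows, length(pw),
          dimnames = list(NULL, names(pw))
        )
        first <- FALSE
      }
      r <- r + 1L
      out[r, ] <- pw
    }
  }
  out
}

# pointwise likelihood given the saved abundance path (the data likelihood
# depends on latent D/R only through N_t)
pointwise_loglik_path <- function(spec, params, prep, N_path) {
  prep$N_path_override <- N_path
  pointwise_loglik(spec, params, prep)
}

#' Compare constant-trend and change-in-trend fits by WAIC
#'
#' @param fits named list with elements `constant` and `change`, each a
#'   [fit_model()] result for the same model and dataset.
#' @param data the shared `survey_dataset`.
#' @return data.frame in the published comparison layout: WAIC, `p_waic`,
#'   `lppd`, and the within-pair `delta_waic` (best model 0), with a
#'   substantial-support flag at 2.00.
#' @export
compare_models <- function(fits, data) {
  stopifnot(all(c("constant", "change") %in% names(fits)))
  pw <- lapply(fits[c("constant", "change")], pointwise_matrix, data = data)
  if (!identical(colnames(pw$constant), colnames(pw$change))) {
    stop("variant fits have mismatched datum labels", call. = FALSE)
  }
  w <- t(vapply(pw, waic, numeric(3)))
  delta <- w[, "waic"] - min(w[, "waic"])
  out <- data.frame(
    variant = rownames(w),
    waic = w[, "waic"], p_waic = w[, "p_waic"], lppd = w[, "lppd"],
    delta_waic = delta,
    substantial_support = delta < 2
  )
  rownames(out) <- NULL
  out
}

#' Posterior summary of the change-in-trend parameter
#'
#' Empirical posterior probability that the derived change parameter
#' `Delta = upsilon2 - upsilon1` is negative, the corresponding odds, and
#' the probability of a negative change exceeding a threshold.
#'
#' @param fit a change-variant [fit_model()] result.
#' @param threshold biologically significant change threshold (default
#'   0.02).
#' @return object of class `change_summary`: `p_negative`, `odds`
#'   (formatted), `p_below_threshold`, threshold odds, and draw counts.
#' @export
change_summary <- function(fit, threshold = 0.02) {
  stopifnot(inherits(fit, "cetipm_fit"))
  if (fit$spec$variant != "change") {
    stop("change_summary requires a change-variant fit", call. = FALSE)
  }
  delta <- posterior_draws(fit, "Delta")
  p_neg <- mean(delta < 0)
  p_thr <- mean(delta < -threshold)
  structure(
    list(
      p_negative = p_neg,
      odds = format_odds(p_neg),
      threshold = threshold,
      p_below_threshold = p_thr,
      odds_below_threshold = format_odds(p_thr),
      n_draws = length(delta)
    ),
    class = "change_summary"
  )
}

#' Format a probability as approximate integer odds
#'
#' Rounds toward the published narrative style: the larger side of the odds
#' is truncated to a whole number (0.849 -> "5:1", 0.469 -> "1:1",
#' 0.2 -> "1:4"); probabilities at 0 or 1 are reported as ">999".
#'
#' @param p probability.
#' @return character odds string.
#' @export
format_odds <- function(p) {
  stopifnot(p >= 0, p <= 1)
  if (p >= 1) {
    return(">999:1")
  }
  if (p <= 0) {
    return("1:>999")
  }
  odds <- p / (1 - p)
  if (odds >= 1) {
    paste0(max(1, floor(odds)), ":1")
  } else {
    paste0("1:", max(1, floor(1 / odds)))
  }
}

#' @export
print.change_summary <- function(x, ...) {
  cat(
    "<change_summary> P(Delta < 0) =", sprintf("%.3f", x$p_negative),
    paste0("(approx. ", x$odds, " odds)"), "\n  P(Delta < -",
    format(x$threshold), ") =", sprintf("%.3f", x$p_below_threshold),
    paste0("(approx. ", x$odds_below_threshold, " odds)"), "\n"
  )
  invisible(x)
}
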