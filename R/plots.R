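# Basic trajectory and posterior plots (base graphics).

#' Plot an estimated population trajectory against the truth
#'
#' Posterior median (dashed) and 95% credible interval (dotted) of the
#' yearly abundance, with the true trajectory overlaid as points when
#' supplied.
#'
#' @param fit a [fit_model()] result.
#' @param truth_N optional true abundance vector.
#' @param in_region optional in-survey-region counts to overlay.
#' @param ... passed to [plot()].
#' @export
plot_trajectory <- function(fit, truth_N = NULL, in_region = NULL, ...) {
  tr <- trajectory_summary(fit)
  ylim <- range(tr[, c("q2.5", "q97.5")], truth_N, in_region, 0, na.rm = TRUE)
  plot(tr[, "year"], tr[, "median"],
    type = "l", lty = 2, col = "blue", ylim = ylim,
    xlab = "Year", ylab = "Abundance",
    main = paste("Model", fit$spec$model, paste0("(", fit$spec$variant, ")")),
    ...
  )
  lines(tr[, "year"], tr[, "q2.5"], lty = 3, col = "blue")
  lines(tr[, "year"], tr[, "q97.5"], lty = 3, col = "blue")
  if (!is.null(truth_N)) points(seq_along(truth_N), truth_N, pch = 16, col = "blue")
  if (!is.null(in_region)) points(seq_along(in_region), in_region, pch = 1)
  invisible(tr)
}

#' Histogram of the posterior of one quantity
#'
#' @param fit a [fit_model()] result.
#' @param var variable name (e.g. `"Delta"`, `"phi1"`).
#' @param true_value optional reference line.
#' @param ... passed to [hist()].
#' @export
plot_posterior <- function(fit, var, true_value = NULL, ...) {
  x <- posterior_draws(fit, var)
  graphics::hist(x, breaks = 40, main = var, xlab = var, ...)
  if (!is.null(true_value)) graphics::abline(v = true_value, col = "blue", lty = 2)
  invisible(x)
}
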