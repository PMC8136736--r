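# Convergence diagnostics: Gelman-Rubin potential scale reduction factor
# and the Geweke window-comparison z-score.

#' Gelman-Rubin potential scale reduction factor
#'
#' Plain (non-rank-normalized) PSRF computed on the saved draws:
#' `sqrt(var_plus / W)` with `var_plus = (n-1)/n W + B/n`, truncated below
#' at 1 (values below 1 are finite-sample artifacts of the variance
#' decomposition; identical chains give exactly 1).
#'
#' @param x draws matrix (iterations x chains), or a vector list per chain.
#' @return the PSRF point estimate.
#' @export
psrf <- function(x) {
  if (is.list(x)) x <- do.call(cbind, x)
  stopifnot(is.matrix(x))
  m <- ncol(x)
  if (m < 2L) stop("PSRF needs at least two chains", call. = FALSE)
  n <- nrow(x)
  means <- colMeans(x)
  W <- mean(apply(x, 2L, var))
  B <- n * var(means)
  if (W == 0) {
    return(if (B == 0) 1 else Inf)
  }
  var_plus <- (n - 1) / n * W + B / n
  max(1, sqrt(var_plus / W))
}

#' Geweke convergence z-score
#'
#' Compares the mean of the first `frac1` fraction of a chain with the mean
#' of the last `frac2` fraction, standardized by spectral-density estimates
#' of the respective standard errors (AR-fit spectrum at frequency zero).
#'
#' @param x numeric vector (one chain of one quantity).
#' @param frac1,frac2 window fractions (defaults 0.1 and 0.5).
#' @return the z-score.
#' @export
geweke_z <- function(x, frac1 = 0.1, frac2 = 0.5) {
  n <- length(x)
  n1 <- max(2L, floor(frac1 * n))
  n2 <- max(2L, floor(frac2 * n))
  x1 <- x[seq_len(n1)]
  x2 <- x[seq.int(n - n2 + 1L, n)]
  s1 <- spectrum0_ar(x1)
  s2 <- spectrum0_ar(x2)
  (mean(x1) - mean(x2)) / sqrt(s1 / n1 + s2 / n2)
}

# spectral density at frequency zero via an AIC-selected AR fit
spectrum0_ar <- function(x) {
  if (var(x) == 0) {
    return(0)
  }
  fit <- tryCatch(
    ar(x, aic = TRUE, order.max = min(20L, floor(length(x) / 3))),
    error = function(e) NULL
  )
  if (is.null(fit) || length(fit$ar) == 0L) {
    return(var(x))
  }
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' Convergence diagnostics for a fitted model
#'
#' PSRF per monitored quantity (requires >= 2 chains) and the Geweke z-score
#' per chain, for the quantities the estimation protocol monitors: final
#' population size, long-term trend, survival (where estimated), and
#' deviance. Quantities with PSRF above the threshold are flagged.
#'
#' @param fit a [fit_model()] result.
#' @param monitored variable names; the default picks the protocol set.
#' @param threshold PSRF flag threshold (default 1.06, the published
#'   convergence ceiling).
#' @return data.frame with one row per quantity: `psrf`, `flagged`, and
#'   Geweke z per chain.
#' @export
convergence_diagnostics <- function(fit, monitored = NULL, threshold = 1.06) {
  stopifnot(inherits(fit, "cetipm_fit"))
  vars <- dimnames(fit$draws)[[2]]
  if (is.null(monitored)) {
    monitored <- c(
      paste0("N_", fit$prep$Tn), "upsilon1", "deviance",
      if (fit$spec$pop_process == "binomial") "phi1"
    )
  }
  stopifnot(all(monitored %in% vars))
  n_chains <- dim(fit$draws)[3]
  if (n_chains < 2L) stop("PSRF needs at least two chains", call. = FALSE)
  out <- do.call(rbind, lapply(monitored, function(v) {
    x <- fit$draws[, v, ]
    r <- psrf(x)
    gz <- vapply(seq_len(n_chains), function(ch) geweke_z(x[, ch]), numeric(1))
    d <- data.frame(quantity = v, psrf = r, flagged = r > threshold)
    d[paste0("geweke_z_chain", seq_len(n_chains))] <- as.list(gz)
    d
  }))
  rownames(out) <- NULL
  out
}
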