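# Additional plain-text serialization: simulator truth, habitat fields,
# configurations, model specifications, and pointwise log-likelihoods.

#' Write and read a simulation configuration as a key-value text file
#'
#' YAML-style `key: value` lines; vectors are comma-separated.
#'
#' @param cfg a [sim_config()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(cfg, path) {
  keys <- c(
    "grid_cols", "grid_rows", "T_years", "T_BP", "N0",
    "vitals_stable", "vitals_declining", "autocorr_range", "grf_sd",
    "fidelity", "bump_col", "bump_row", "bump_sd",
    "ns_bump_col", "ns_bump_row", "ns_bump_sd", "ns_share",
    "decline_rate", "survey_cols", "nearshore_cols", "seed"
  )
  lines <- vapply(keys, function(k) {
    paste0(k, ": ", paste(sprintf("%.12g", as.numeric(cfg[[k]])), collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, ": ", fixed = TRUE)
  vals <- lapply(kv, function(x) as.numeric(strsplit(x[2], ",")[[1]]))
  names(vals) <- vapply(kv, `[[`, character(1), 1L)
  for (nm in c("vitals_stable", "vitals_declining")) {
    names(vals[[nm]]) <- c("phi", "rho", "chi")
  }
  do.call(sim_config, vals)
}

#' Write the latent population truth as a long-format CSV
#'
#' One row per individual-year while alive: id, year, alive flag, assigned
#' cell (NA if [distribute_individuals()] has not run), and the
#' cow-with-calf flag.
#'
#' @param truth a `population_truth`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_population_truth <- function(truth, path) {
  stopifnot(inherits(truth, "population_truth"))
  idx <- which(truth$alive, arr.ind = TRUE)
  df <- data.frame(
    id = idx[, 1],
    year = idx[, 2],
    alive = 1L,
    cell = if (is.null(truth$cell)) NA_integer_ else truth$cell[idx],
    calf_flag = as.integer(truth$calf[idx])
  )
  df <- df[order(df$id, df$year), ]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a habitat field (true and measured suitability) as CSV
#'
#' @param field a `habitat_field`.
#' @param path output file; columns cell, year, h, H.
#' @return `path`, invisibly.
#' @export
write_habitat_field <- function(field, path) {
  stopifnot(inherits(field, "habitat_field"))
  K <- nrow(field$h)
  Tn <- ncol(field$h)
  df <- data.frame(
    cell = rep(seq_len(K), Tn),
    year = rep(seq_len(Tn), each = K),
    h = sprintf("%.12g", as.vector(field$h)),
    H = sprintf("%.12g", as.vector(field$H))
  )
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write and read a model specification as a key-value text file
#'
#' @param spec a [model_spec()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_model_spec <- function(spec, path) {
  pr <- spec$priors
  lines <- c(
    paste0("model: ", spec$model),
    paste0("variant: ", spec$variant),
    paste0("T_BP: ", spec$T_BP),
    paste0("N_max: ", spec$N_max),
    paste0("phi_bounds: ", paste(pr$phi_bounds, collapse = ",")),
    paste0("rho_bounds: ", paste(pr$rho_bounds, collapse = ",")),
    paste0("chi_lower: ", pr$chi_lower),
    paste0("upsilon_bounds: ", paste(
      sprintf("%.12g", pr$upsilon_bounds),
      collapse = ","
    )),
    paste0("b_sd: ", pr$b_sd),
    paste0("s_bounds_mult: ", paste(pr$s_bounds_mult, collapse = ","))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, ": ", fixed = TRUE)
  vals <- lapply(kv, function(x) strsplit(x[2], ",")[[1]])
  names(vals) <- vapply(kv, `[[`, character(1), 1L)
  num <- function(k) as.numeric(vals[[k]])
  model_spec(
    model = vals$model, variant = vals$variant,
    T_BP = as.integer(num("T_BP")), N_max = as.integer(num("N_max")),
    priors = list(
      phi_bounds = num("phi_bounds"), rho_bounds = num("rho_bounds"),
      chi_lower = num("chi_lower"), upsilon_bounds = num("upsilon_bounds"),
      b_sd = num("b_sd"), s_bounds_mult = num("s_bounds_mult")
    )
  )
}

#' Write a pointwise log-likelihood matrix as CSV
#'
#' Draws as rows, datum labels as columns (the layout consumed by
#' [waic()]).
#'
#' @param pw a draws x datum matrix from [pointwise_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pointwise_loglik <- function(pw, path) {
  stopifnot(is.matrix(pw))
  df <- as.data.frame(pw)
  df <- cbind(draw = seq_len(nrow(pw)), df)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
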