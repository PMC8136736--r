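# Plain-text serialization of survey datasets. Reals are written with 12
# significant digits (%.12g), which round-trips stably: writing, reading and
# re-writing a dataset produces byte-identical files.

fmt_real_cols <- function(df) {
  for (nm in names(df)) {
    if (is.double(df[[nm]])) df[[nm]] <- sprintf("%.12g", df[[nm]])
  }
  df
}

write_table <- function(df, path) {
  write.csv(fmt_real_cols(df), path, row.names = FALSE, quote = FALSE)
}

#' Write a survey dataset to a directory of CSV/JSON files
#'
#' Files written: `distances.csv`, `counts.csv`, `calf_index.csv` (both
#' indices, distinguished by an `index` column), `pid.csv`, `ch_survey.csv`
#' and `ch_smallboat.csv` (wide capture-history matrices with catalog id and
#' first-capture years), `habitat_covariate.csv` (the measured covariate),
#' `targets.csv`, and `meta.json` (geometry, survey years, design).
#'
#' @param ds a `survey_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_survey_dataset <- function(ds, dir) {
  validate_survey_dataset(ds)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_table(ds$distances, file.path(dir, "distances.csv"))
  write_table(ds$counts, file.path(dir, "counts.csv"))
  calf <- rbind(
    cbind(index = "survey", ds$calf_survey),
    cbind(index = "id", ds$calf_id)
  )
  write_table(calf, file.path(dir, "calf_index.csv"))
  write_table(ds$p_id_data, file.path(dir, "pid.csv"))

  chs <- data.frame(
    id = ds$catalog_ids,
    first_survey = ds$first_survey,
    first_any = ds$first_any
  )
  chs <- cbind(chs, as.data.frame(ds$Y_survey))
  names(chs)[-(1:3)] <- paste0("y", seq_len(ds$T_years))
  write_table(chs, file.path(dir, "ch_survey.csv"))

  M <- ds$design$M
  sb_flat <- matrix(
    as.integer(ds$Y_sb), nrow = dim(ds$Y_sb)[1],
    dimnames = list(NULL, paste0(
      "y", rep(seq_len(ds$T_years), each = M), "_", rep(seq_len(M), ds$T_years)
    ))
  )
  chb <- cbind(
    data.frame(id = ds$catalog_ids, first_any = ds$first_any),
    as.data.frame(sb_flat)
  )
  write_table(chb, file.path(dir, "ch_smallboat.csv"))

  K <- nrow(ds$H)
  write_table(
    data.frame(
      cell = rep(seq_len(K), ncol(ds$H)),
      year = rep(seq_len(ncol(ds$H)), each = K),
      H = as.vector(ds$H)
    ),
    file.path(dir, "habitat_covariate.csv")
  )
  write_table(
    data.frame(
      year = rep(seq_along(ds$targets), lengths(ds$targets)),
      cell = unlist(ds$targets)
    ),
    file.path(dir, "targets.csv")
  )
  meta <- list(
    T_years = ds$T_years,
    n_cells = ds$n_cells,
    survey_years = ds$survey_years,
    survey_region_cells = which(ds$survey_region_mask),
    nearshore_cells = which(ds$nearshore_mask),
    design = unclass(ds$design)
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}

#' Read a survey dataset written by [write_survey_dataset()]
#'
#' @param dir directory containing the files.
#' @return a validated `survey_dataset`.
#' @export
read_survey_dataset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  design <- do.call(survey_design, meta$design[c(
    "survey_years", "l", "cell_area", "x_max", "s_true", "g0", "p_id",
    "n_target", "M", "p_r_sb"
  )])
  Tn <- meta$T_years
  distances <- read.csv(file.path(dir, "distances.csv"))
  counts <- read.csv(file.path(dir, "counts.csv"))
  calf <- read.csv(file.path(dir, "calf_index.csv"))
  pid <- read.csv(file.path(dir, "pid.csv"))
  chs <- read.csv(file.path(dir, "ch_survey.csv"))
  chb <- read.csv(file.path(dir, "ch_smallboat.csv"))
  hab <- read.csv(file.path(dir, "habitat_covariate.csv"))
  tg <- read.csv(file.path(dir, "targets.csv"))

  Y_survey <- as.matrix(chs[, paste0("y", seq_len(Tn)), drop = FALSE])
  dimnames(Y_survey) <- list(chs$id, NULL)
  storage.mode(Y_survey) <- "integer"
  M <- design$M
  sb_cols <- paste0(
    "y", rep(seq_len(Tn), each = M), "_", rep(seq_len(M), Tn)
  )
  Y_sb <- array(
    as.integer(as.matrix(chb[, sb_cols, drop = FALSE])),
    c(nrow(chb), M, Tn), dimnames = list(chb$id, NULL, NULL)
  )
  H <- matrix(hab$H[order(hab$year, hab$cell)], meta$n_cells, Tn)
  mask_region <- seq_len(meta$n_cells) %in% meta$survey_region_cells
  mask_ns <- seq_len(meta$n_cells) %in% meta$nearshore_cells

  first_survey <- chs$first_survey
  sb_any <- apply(Y_sb, c(1L, 3L), max)
  first_sb <- apply(sb_any, 1L, function(y) {
    w <- which(y == 1L)
    if (length(w)) w[1L] else NA_integer_
  })
  ds <- structure(
    list(
      distances = distances,
      counts = counts,
      H = H,
      calf_survey = calf[calf$index == "survey", c("year", "n_c", "N")],
      calf_id = calf[calf$index == "id", c("year", "n_c", "N")],
      Y_survey = Y_survey,
      Y_sb = Y_sb,
      first_survey = as.integer(first_survey),
      first_sb = as.integer(first_sb),
      first_any = as.integer(chs$first_any),
      catalog_ids = chs$id,
      targets = lapply(seq_len(Tn), function(t) tg$cell[tg$year == t]),
      p_id_data = pid,
      survey_region_mask = mask_region,
      nearshore_mask = mask_ns,
      survey_years = design$survey_years,
      T_years = Tn,
      n_cells = meta$n_cells,
      design = design
    ),
    class = "survey_dataset"
  )
  rownames(ds$calf_survey) <- rownames(ds$calf_id) <- NULL
  validate_survey_dataset(ds)
  ds
}
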