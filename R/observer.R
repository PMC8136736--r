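# Observation-process simulators: line-transect distance sampling with
# photo-identification from the survey vessel, and annual robust-design
# small-boat studies in targeted nearshore cells. All platforms feed one
# shared identification catalog.

#' Simulate line-transect distance sampling
#'
#' One transect bisects every survey-region cell in each survey year (equal
#' effort everywhere). Each non-calf individual present in a surveyed cell
#' gets a perpendicular offset drawn uniformly on `[0, A/(2l)]` and is
#' detected with probability `g0 * exp(-x^2 / (2 s_true^2))` if the offset is
#' within the truncation distance `x_max`.
#'
#' @param truth a [distribute_individuals()] result.
#' @param field the matching [generate_habitat_field()] result.
#' @param cfg the [sim_config()].
#' @param design a [survey_design()].
#' @param seed master seed; the observation substream is derived from it.
#' @return list with `detections` (data.frame: year, ind, cell, x),
#'   `counts` (data.frame: year, cell, n, l, A, x_max covering every surveyed
#'   cell-year), and `effort` (the per-cell-year effort columns of `counts`).
#' @export
simulate_line_transect <- function(truth, field, cfg, design, seed) {
  stopifnot(inherits(truth, "population_truth"), inherits(design, "survey_design"))
  validate_survey_design(design)
  if (is.null(truth$cell)) {
    stop("cell assignments missing: run distribute_individuals() first",
      call. = FALSE
    )
  }
  if (any(design$survey_years < 1L | design$survey_years > truth$T_years)) {
    stop("survey years outside the study period", call. = FALSE)
  }
  region_cells <- which(cfg$survey_region_mask)
  half_width <- design$cell_area / (2 * design$l)
  det <- vector("list", length(design$survey_years))
  with_substream(seed, "observation_lt", {
    for (j in seq_along(design$survey_years)) {
      t <- design$survey_years[j]
      present <- which(truth$alive[, t] & truth$cell[, t] %in% region_cells)
      n <- length(present)
      x <- runif(n, 0, half_width)
      p_det <- ifelse(
        x <= design$x_max,
        design$g0 * exp(-x^2 / (2 * design$s_true^2)), 0
      )
      hit <- runif(n) <= p_det
      det[[j]] <- data.frame(
        year = rep.int(t, sum(hit)),
        ind = present[hit],
        cell = truth$cell[present[hit], t],
        x = x[hit]
      )
    }
  })
  detections <- do.call(rbind, det)
  grid_cells <- expand.grid(cell = region_cells, year = design$survey_years)
  tab <- table(
    factor(detections$cell, levels = region_cells),
    factor(detections$year, levels = design$survey_years)
  )
  counts <- data.frame(
    year = grid_cells$year,
    cell = grid_cells$cell,
    n = as.vector(tab),
    l = design$l, A = design$cell_area, x_max = design$x_max
  )
  list(
    detections = detections,
    counts = counts,
    effort = counts[, c("year", "cell", "l", "A", "x_max")]
  )
}

#' Simulate photo-identification from the line-transect survey
#'
#' Every detected non-calf is identified to individual with the same
#' probability `p_id` (identifiability driven by sighting conditions rather
#' than individual distinctiveness). The realized per-year identification
#' rate is reported as data, as the estimation models consume it.
#'
#' @param detections the `detections` element of [simulate_line_transect()].
#' @param design a [survey_design()].
#' @param seed master seed (photo-id substream).
#' @return list with `id_events` (data.frame: year, ind) and `p_id_data`
#'   (data.frame: year, n_detected, n_identified, p_id).
#' @export
simulate_survey_photo_id <- function(detections, design, seed) {
  with_substream(seed, "observation_id", {
    identified <- runif(nrow(detections)) <= design$p_id
  })
  id_events <- detections[identified, c("year", "ind")]
  years <- sort(unique(detections$year))
  n_det <- vapply(years, function(t) sum(detections$year == t), integer(1))
  n_id <- vapply(years, function(t) sum(id_events$year == t), integer(1))
  list(
    id_events = id_events,
    p_id_data = data.frame(
      year = years, n_detected = n_det, n_identified = n_id,
      p_id = ifelse(n_det > 0, n_id / n_det, NA_real_)
    )
  )
}

#' Select small-boat target cells for one year
#'
#' The `n_target` nearshore cells with the highest true suitability in the
#' given year; deterministic given the field, with ties broken by lowest cell
#' index.
#'
#' @param field a [generate_habitat_field()] result.
#' @param cfg the [sim_config()] (provides the nearshore mask).
#' @param year year index.
#' @param n_target number of cells to select.
#' @return integer vector of cell indices, sorted by decreasing suitability.
#' @export
select_target_cells <- function(field, cfg, year, n_target) {
  ns <- which(cfg$nearshore_mask)
  if (length(ns) == 0L) stop("nearshore mask is empty", call. = FALSE)
  if (n_target > length(ns)) {
    stop("n_target exceeds the number of nearshore cells", call. = FALSE)
  }
  h <- field$h[ns, year]
  ns[order(-h, ns)][seq_len(n_target)]
}

#' Simulate annual robust-design small-boat studies
#'
#' In each year, individuals whose assigned cell is targeted are detected and
#' identified independently on each of `M` secondary occasions with
#' probability `p_r_sb`.
#'
#' @param truth a [distribute_individuals()] result.
#' @param targets list (length `T`) of target-cell index vectors.
#' @param design a [survey_design()].
#' @param seed master seed (small-boat substream).
#' @return data.frame of capture events: year, occasion, ind.
#' @export
simulate_small_boat <- function(truth, targets, design, seed) {
  stopifnot(length(targets) == truth$T_years)
  ev <- list()
  with_substream(seed, "observation_sb", {
    for (t in seq_len(truth$T_years)) {
      present <- which(truth$alive[, t] & truth$cell[, t] %in% targets[[t]])
      if (!length(present)) next
      for (m in seq_len(design$M)) {
        hit <- present[runif(length(present)) <= design$p_r_sb]
        if (length(hit)) {
          ev[[length(ev) + 1L]] <- data.frame(
            year = t, occasion = m, ind = hit
          )
        }
      }
    }
  })
  if (length(ev)) do.call(rbind, ev) else {
    data.frame(year = integer(), occasion = integer(), ind = integer())
  }
}

#' Compile the two calf indices
#'
#' The survey index counts cows with calves among all animals detected in the
#' line-transect survey each survey year. The identification index counts
#' cows with calves among the distinct individuals identified in small-boat
#' studies each year (identified individuals only, to avoid double-counting).
#'
#' @param detections detections from [simulate_line_transect()].
#' @param sb_events capture events from [simulate_small_boat()].
#' @param truth the [simulate_population_truth()] truth (calf flags).
#' @return list with `calf_survey` (year, n_c, N over survey years) and
#'   `calf_id` (year, n_c, N over all years).
#' @export
compile_calf_indices <- function(detections, sb_events, truth) {
  survey_years <- sort(unique(detections$year))
  calf_survey <- do.call(rbind, lapply(survey_years, function(t) {
    d <- detections[detections$year == t, ]
    data.frame(
      year = t,
      n_c = sum(truth$calf[cbind(d$ind, d$year)]),
      N = nrow(d)
    )
  }))
  calf_id <- do.call(rbind, lapply(seq_len(truth$T_years), function(t) {
    ids <- unique(sb_events$ind[sb_events$year == t])
    data.frame(
      year = t,
      n_c = if (length(ids)) sum(truth$calf[ids, t]) else 0L,
      N = length(ids)
    )
  }))
  list(calf_survey = calf_survey, calf_id = calf_id)
}

#' Realized capture-rate summary
#'
#' Measures, against the latent truth, the two capture probabilities the
#' observation design is calibrated to: the per-survey-year probability that
#' an alive, previously cataloged individual is recaptured in the
#' line-transect survey, and the annual probability that an alive,
#' previously cataloged individual is captured on at least one small-boat
#' occasion. "Previously cataloged" means first identified (on either
#' platform) in an earlier year, so these are recapture rates in the CJS
#' sense.
#'
#' @param truth the [distribute_individuals()] truth used to generate `ds`.
#' @param ds the matching `survey_dataset`.
#' @return named vector `c(survey = ..., smallboat = ...)` of pooled
#'   individual-year rates.
#' @export
capture_rate_summary <- function(truth, ds) {
  idx <- match(ds$catalog_ids, seq_len(nrow(truth$alive)))
  sb_any <- apply(ds$Y_sb, c(1L, 3L), max)
  num_s <- den_s <- num_b <- den_b <- 0L
  for (t in seq_len(ds$T_years)) {
    at_risk <- which(!is.na(ds$first_any) & ds$first_any < t &
      truth$alive[idx, t])
    if (!length(at_risk)) next
    if (t %in% ds$survey_years) {
      den_s <- den_s + length(at_risk)
      num_s <- num_s + sum(ds$Y_survey[at_risk, t])
    }
    den_b <- den_b + length(at_risk)
    num_b <- num_b + sum(sb_any[at_risk, t])
  }
  c(
    survey = if (den_s) num_s / den_s else NA_real_,
    smallboat = if (den_b) num_b / den_b else NA_real_
  )
}
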