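# Assembly, validation and serialization of the survey dataset: everything
# an estimation model is allowed to see (the latent truth stays outside).

#' Assemble and validate a survey dataset
#'
#' Collects the outputs of the observation simulators into one validated
#' object. Individuals identified on either platform form a single shared
#' catalog; capture histories are matrices over that catalog.
#'
#' @param lt result of [simulate_line_transect()].
#' @param photo result of [simulate_survey_photo_id()].
#' @param targets list of per-year target-cell vectors.
#' @param sb_events result of [simulate_small_boat()].
#' @param calf result of [compile_calf_indices()].
#' @param field the [generate_habitat_field()] (only the measured covariate
#'   `H` enters the dataset).
#' @param cfg the [sim_config()].
#' @param design the [survey_design()].
#' @return an object of class `survey_dataset`.
#' @export
build_survey_dataset <- function(lt, photo, targets, sb_events, calf,
                                 field, cfg, design) {
  Tn <- cfg$T_years
  ids <- sort(unique(c(photo$id_events$ind, sb_events$ind)))
  n_cat <- length(ids)
  Y_survey <- matrix(0L, n_cat, Tn, dimnames = list(ids, NULL))
  if (nrow(photo$id_events)) {
    Y_survey[cbind(
      match(photo$id_events$ind, ids), photo$id_events$year
    )] <- 1L
  }
  Y_sb <- array(0L, c(n_cat, design$M, Tn), dimnames = list(ids, NULL, NULL))
  if (nrow(sb_events)) {
    Y_sb[cbind(
      match(sb_events$ind, ids), sb_events$occasion, sb_events$year
    )] <- 1L
  }
  first_survey <- apply(Y_survey, 1L, function(y) {
    w <- which(y == 1L)
    if (length(w)) w[1L] else NA_integer_
  })
  sb_any <- apply(Y_sb, c(1L, 3L), max)
  first_sb <- apply(sb_any, 1L, function(y) {
    w <- which(y == 1L)
    if (length(w)) w[1L] else NA_integer_
  })
  first_any <- pmin(first_survey, first_sb, na.rm = TRUE)

  ds <- structure(
    list(
      distances = lt$detections[, c("year", "cell", "x")],
      counts = lt$counts,
      H = field$H,
      calf_survey = calf$calf_survey,
      calf_id = calf$calf_id,
      Y_survey = Y_survey,
      Y_sb = Y_sb,
      first_survey = first_survey,
      first_sb = first_sb,
      first_any = first_any,
      catalog_ids = ids,
      targets = targets,
      p_id_data = photo$p_id_data,
      survey_region_mask = cfg$survey_region_mask,
      nearshore_mask = cfg$nearshore_mask,
      survey_years = design$survey_years,
      T_years = Tn,
      n_cells = cfg$n_cells,
      design = design
    ),
    class = "survey_dataset"
  )
  validate_survey_dataset(ds)
  ds
}

#' Validate the internal consistency of a survey dataset
#'
#' Checks the dataset invariants: per-cell counts equal the number of
#' distance records for that cell and year, distances respect the truncation
#' window, survey capture histories only mark survey years, small-boat
#' captures only occur in targeted years with a non-empty target set, calf
#' counts are bounded by their denominators, and first-capture years match
#' the capture histories.
#'
#' @param ds a `survey_dataset`.
#' @return the dataset, invisibly; aborts with a named validation error
#'   otherwise.
#' @export
validate_survey_dataset <- function(ds) {
  stopifnot(inherits(ds, "survey_dataset"))
  for (i in seq_len(nrow(ds$counts))) {
    k <- ds$counts$cell[i]
    t <- ds$counts$year[i]
    n_dist <- sum(ds$distances$cell == k & ds$distances$year == t)
    if (n_dist != ds$counts$n[i]) {
      stop(
        "count/distance mismatch in cell ", k, ", year ", t,
        ": count ", ds$counts$n[i], " vs ", n_dist, " distance records",
        call. = FALSE
      )
    }
  }
  if (nrow(ds$distances) &&
    (any(ds$distances$x < 0) || any(ds$distances$x > ds$design$x_max))) {
    stop("distance outside the truncation window [0, x_max]", call. = FALSE)
  }
  off_years <- setdiff(which(colSums(ds$Y_survey) > 0), ds$survey_years)
  if (length(off_years)) {
    stop(
      "survey capture history has captures outside survey years: ",
      paste(off_years, collapse = ", "),
      call. = FALSE
    )
  }
  if (nrow(ds$Y_survey)) {
    for (i in seq_len(nrow(ds$Y_survey))) {
      w <- c(
        which(ds$Y_survey[i, ] == 1L),
        which(apply(ds$Y_sb[i, , , drop = FALSE], 3L, max) == 1L)
      )
      if (length(w) == 0L || min(w) != ds$first_any[i]) {
        stop("first-capture year inconsistent for catalog row ", i,
          call. = FALSE
        )
      }
    }
  }
  for (nm in c("calf_survey", "calf_id")) {
    ci <- ds[[nm]]
    if (any(ci$n_c < 0 | ci$n_c > ci$N)) {
      stop(nm, ": calf count exceeds its denominator", call. = FALSE)
    }
  }
  invisible(ds)
}

#' @export
print.survey_dataset <- function(x, ...) {
  cat(
    "<survey_dataset>", nrow(x$distances), "distances,",
    nrow(x$counts), "cell-year counts,",
    nrow(x$Y_survey), "cataloged individuals over", x$T_years, "years\n"
  )
  invisible(x)
}

#' Simulate one full scenario dataset
#'
#' End-to-end convenience wrapper: habitat field, population truth, cell
#' assignments, line-transect survey with photo-ID, small-boat studies, calf
#' indices, and the assembled [build_survey_dataset()]. Scenarios follow the
#' factorial design: A = stable population, random habitat; B = stable,
#' shifting; C = stable-then-declining, random; D = stable-then-declining,
#' shifting. All stochastic components draw from named substreams of the
#' master seed, so matched seeds share population realizations across (A, B)
#' and (C, D) and habitat realizations across (A, C) and (B, D).
#'
#' @param cfg a [sim_config()].
#' @param scenario one of `"A"`, `"B"`, `"C"`, `"D"`.
#' @param design a [survey_design()].
#' @param seed master seed.
#' @return list with `truth`, `field`, `dataset`, and `scenario`.
#' @export
simulate_scenario <- function(cfg, scenario = c("B", "A", "C", "D"),
                              design = survey_design(), seed = cfg$seed) {
  scenario <- match.arg(scenario)
  scen_pop <- if (scenario %in% c("A", "B")) "stable" else "stable_then_declining"
  scen_hab <- if (scenario %in% c("A", "C")) "random" else "shifting"
  field <- generate_habitat_field(cfg, scen_hab, seed)
  truth <- simulate_population_truth(cfg, scen_pop, seed)
  truth <- distribute_individuals(truth, field, seed)
  lt <- simulate_line_transect(truth, field, cfg, design, seed)
  photo <- simulate_survey_photo_id(lt$detections, design, seed)
  targets <- lapply(
    seq_len(cfg$T_years),
    function(t) select_target_cells(field, cfg, t, design$n_target)
  )
  sb_events <- simulate_small_boat(truth, targets, design, seed)
  calf <- compile_calf_indices(lt$detections, sb_events, truth)
  ds <- build_survey_dataset(
    lt, photo, targets, sb_events, calf, field, cfg, design
  )
  list(truth = truth, field = field, dataset = ds, scenario = scenario)
}
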