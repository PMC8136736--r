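# Individual-based, age-structured population simulation.
#
# A single non-calf class (juveniles + adults) plus dependent calves. Each
# year every alive non-calf produces a calf with probability rho; the calf is
# with its mother for that year and recruits to the non-calf class the next
# year with probability chi. Each non-calf survives to the next year with
# probability phi. Under the stable-then-declining scenario phi switches to
# the declining value for all transitions into years T_BP+1 ... T, so the
# annual multiplier becomes phi2 + rho * chi from year T_BP onwards.

#' Simulate the latent population truth
#'
#' @param cfg a [sim_config()].
#' @param scenario_pop `"stable"` or `"stable_then_declining"`.
#' @param seed master seed; the population substream is derived from it, so
#'   the first `T_BP` years of the two population scenarios are identical for
#'   matched seeds (the declining regime only alters survival draws after the
#'   change year, and draws are consumed in a scenario-independent order up
#'   to that point).
#' @return an object of class `population_truth` with per-year non-calf
#'   abundance `N_t`, per-individual `alive` and `calf` flags (individuals x
#'   years matrices), `birth_year` (NA for founders), `death_year` (NA if
#'   alive at the end), and an empty `cell` slot to be filled by
#'   [distribute_individuals()].
#' @export
simulate_population_truth <- function(cfg,
                                      scenario_pop = c(
                                        "stable", "stable_then_declining"
                                      ),
                                      seed = cfg$seed) {
  validate_sim_config(cfg)
  scenario_pop <- match.arg(scenario_pop)
  Tn <- cfg$T_years
  vs <- cfg$vitals_stable
  vd <- cfg$vitals_declining
  rho <- vs[["rho"]]
  chi <- vs[["chi"]]

  cap <- cfg$N0 + ceiling(cfg$N0 * 0.2 * Tn) + 64L
  alive <- matrix(FALSE, cap, Tn)
  calf <- matrix(FALSE, cap, Tn)
  birth_year <- rep(NA_integer_, cap)
  death_year <- rep(NA_integer_, cap)
  n_ind <- cfg$N0
  alive[seq_len(cfg$N0), 1L] <- TRUE

  grow <- function(mat, n) {
    rbind(mat, matrix(FALSE, n, ncol(mat)))
  }

  with_substream(seed, "population", {
    for (t in seq_len(Tn)) {
      ids <- which(alive[, t])
      n_t <- length(ids)
      if (n_t == 0L) next
      # calf production in year t (cow-with-calf flag for the calf index)
      has_calf <- runif(n_t) <= rho
      calf[ids[has_calf], t] <- TRUE
      if (t < Tn) {
        # calves recruit to the non-calf class next year w.p. chi
        recruits <- sum(runif(sum(has_calf)) <= chi)
        if (recruits > 0L) {
          if (n_ind + recruits > nrow(alive)) {
            extra <- max(recruits, 256L)
            alive <- grow(alive, extra)
            calf <- grow(calf, extra)
            birth_year <- c(birth_year, rep(NA_integer_, extra))
            death_year <- c(death_year, rep(NA_integer_, extra))
          }
          new_ids <- n_ind + seq_len(recruits)
          alive[new_ids, t + 1L] <- TRUE
          birth_year[new_ids] <- t + 1L
          n_ind <- n_ind + recruits
        }
        # non-calf survival into year t + 1
        phi_t <- if (scenario_pop == "stable_then_declining" && t >= cfg$T_BP) {
          vd[["phi"]]
        } else {
          vs[["phi"]]
        }
        survives <- runif(n_t) <= phi_t
        alive[ids[survives], t + 1L] <- TRUE
        death_year[ids[!survives]] <- t # last year alive is t
      }
    }
  })

  alive <- alive[seq_len(n_ind), , drop = FALSE]
  calf <- calf[seq_len(n_ind), , drop = FALSE]
  structure(
    list(
      N_t = colSums(alive),
      alive = alive, calf = calf,
      birth_year = birth_year[seq_len(n_ind)],
      death_year = death_year[seq_len(n_ind)],
      cell = NULL,
      scenario_pop = scenario_pop,
      T_years = Tn
    ),
    class = "population_truth"
  )
}

#' Assign individuals to habitat cells
#'
#' Each alive individual's cell in each year is drawn independently with
#' probability proportional to true suitability `h[, t]` (an ideal free
#' distribution). Dependent calves are co-located with their mothers and are
#' not assigned separately. Draws use one uniform per individual-year through
#' an inverse-CDF lookup, so matched seeds give identical assignments across
#' scenarios wherever the suitability surfaces coincide.
#'
#' @param truth a [simulate_population_truth()] result.
#' @param field a [generate_habitat_field()] result.
#' @param seed master seed; the distribution substream is derived from it.
#' @return `truth` with the `cell` matrix (individuals x years; NA when not
#'   alive) filled, plus the habitat scenario label.
#' @export
distribute_individuals <- function(truth, field, seed) {
  stopifnot(inherits(truth, "population_truth"), inherits(field, "habitat_field"))
  Tn <- truth$T_years
  if (ncol(field$h) != Tn) {
    stop("habitat field and population truth cover different numbers of years",
      call. = FALSE
    )
  }
  K <- nrow(field$h)
  cell <- matrix(NA_integer_, nrow(truth$alive), Tn)
  with_substream(seed, "distribution", {
    for (t in seq_len(Tn)) {
      h_t <- field$h[, t]
      tot <- sum(h_t)
      if (!is.finite(tot) || tot <= 0) {
        stop("suitability surface is all zero in year ", t, call. = FALSE)
      }
      cum <- cumsum(h_t) / tot
      ids <- which(truth$alive[, t])
      if (length(ids)) {
        u <- runif(length(ids))
        cell[ids, t] <- pmin(findInterval(u, cum) + 1L, K)
      }
    }
  })
  truth$cell <- cell
  truth$scenario_habitat <- field$scenario_habitat
  truth
}

#' Yearly number of individuals inside the survey region
#'
#' @param truth a [distribute_individuals()] result (cell assignments must be
#'   present).
#' @param cfg the [sim_config()] providing the survey-region mask.
#' @return integer vector of length `T`.
#' @export
survey_region_trajectory <- function(truth, cfg) {
  stopifnot(inherits(truth, "population_truth"))
  if (is.null(truth$cell)) {
    stop("cell assignments missing: run distribute_individuals() first",
      call. = FALSE
    )
  }
  in_region <- which(cfg$survey_region_mask)
  vapply(seq_len(truth$T_years), function(t) {
    sum(truth$alive[, t] & truth$cell[, t] %in% in_region)
  }, integer(1))
}

#' @export
print.population_truth <- function(x, ...) {
  cat(
    "<population_truth>", nrow(x$alive), "individuals over", x$T_years,
    "years (", x$scenario_pop, ")\n  N_t:", paste(x$N_t, collapse = " "), "\n"
  )
  invisible(x)
}
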