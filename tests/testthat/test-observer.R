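# Observation simulators: detection limits, distance distribution,
# photo-id, target selection, small-boat studies and calf indices.

# minimal truth: n individuals alive in year 1 of a 1-year study, all in
# given cells
point_truth <- function(cells, Tn = 1L) {
  n <- length(cells)
  structure(
    list(
      N_t = rep(n, Tn),
      alive = matrix(TRUE, n, Tn),
      calf = matrix(FALSE, n, Tn),
      birth_year = rep(NA_integer_, n),
      death_year = rep(NA_integer_, n),
      cell = matrix(rep(cells, Tn), n, Tn),
      scenario_pop = "stable", T_years = Tn
    ),
    class = "population_truth"
  )
}

test_that("perfect-detection limit finds every individual in surveyed cells", {
  cfg <- tiny_config()
  region <- which(cfg$survey_region_mask)
  outside <- which(!cfg$survey_region_mask)
  truth <- point_truth(c(rep(region[1], 30), rep(outside[1], 10)))
  # strip covers the whole cell (x_max = A/(2l)), huge scale: p(det) = 1
  des <- tiny_design(survey_years = 1L, x_max = 0.5, s_true = 50)
  lt <- simulate_line_transect(truth, NULL, cfg, des, seed = 1)
  expect_equal(nrow(lt$detections), 30L)
  expect_equal(sum(lt$counts$n), 30L)
  expect_equal(lt$counts$n[lt$counts$cell == region[1]], 30L)
})

test_that("detection distances follow the truncated half-normal (KS test)", {
  cfg <- tiny_config()
  cell <- which(cfg$survey_region_mask)[1]
  truth <- point_truth(rep(cell, 4000))
  des <- tiny_design(survey_years = 1L)
  x <- unlist(lapply(1:5, function(seed) {
    simulate_line_transect(truth, NULL, cfg, des, seed = seed)$detections$x
  }))
  expect_gt(length(x), 4000)
  s <- des$s_true
  cdf <- function(q) {
    (pnorm(q / s) - 0.5) / (pnorm(des$x_max / s) - 0.5)
  }
  expect_gt(suppressWarnings(ks.test(x, cdf)$p.value), 0.01)
})

test_that("expected detections match N p.d over replicates", {
  cfg <- tiny_config()
  cell <- which(cfg$survey_region_mask)[2]
  n_ind <- 50L
  truth <- point_truth(rep(cell, n_ind))
  des <- tiny_design(survey_years = 1L)
  p_d <- segment_detection_prob(
    des$l, esw_halfnormal(des$s_true, des$x_max), des$g0, des$cell_area
  )
  counts <- vapply(1:600, function(seed) {
    nrow(simulate_line_transect(truth, NULL, cfg, des, seed = seed)$detections)
  }, numeric(1))
  mcse <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - n_ind * p_d), 3 * mcse)
})

test_that("strip wider than the cell is rejected", {
  expect_error(survey_design(x_max = 0.6), "wider than the cell")
})

test_that("photo-id limits: p_id 1 identifies everyone, p_id 0 nobody", {
  sim <- tiny_sim()
  lt <- simulate_line_transect(
    sim$truth, sim$field, tiny_config(), tiny_design(), seed = 2
  )
  ph1 <- simulate_survey_photo_id(lt$detections, tiny_design(p_id = 1), seed = 2)
  expect_equal(nrow(ph1$id_events), nrow(lt$detections))
  expect_true(all(ph1$p_id_data$p_id == 1))
  ph0 <- simulate_survey_photo_id(lt$detections, tiny_design(p_id = 0), seed = 2)
  expect_equal(nrow(ph0$id_events), 0L)
})

test_that("target selection is the deterministic top-n by suitability", {
  cfg <- tiny_config()
  f <- generate_habitat_field(cfg, "random", seed = 3)
  ns <- which(cfg$nearshore_mask)
  tg <- select_target_cells(f, cfg, 2, 3)
  expect_equal(tg, ns[order(-f$h[ns, 2], ns)][1:3])
  expect_identical(tg, select_target_cells(f, cfg, 2, 3))
  # all nearshore cells
  expect_setequal(select_target_cells(f, cfg, 1, length(ns)), ns)
  # ties resolved toward the lowest cell index
  f$h[ns, 4] <- 1
  expect_equal(select_target_cells(f, cfg, 4, 3), sort(ns)[1:3])
  expect_error(select_target_cells(f, cfg, 1, length(ns) + 1L), "n_target")
})

test_that("small-boat capture limits", {
  cfg <- tiny_config()
  region <- which(cfg$nearshore_mask)
  truth <- point_truth(c(rep(region[1], 10), rep(max(which(cfg$survey_region_mask)), 5)))
  targets <- list(region[1])
  des1 <- tiny_design(p_r_sb = 1)
  ev <- simulate_small_boat(truth, targets, des1, seed = 1)
  # all individuals in the target cell captured on all M occasions
  expect_equal(nrow(ev), 10L * des1$M)
  expect_true(all(ev$ind <= 10))
  des0 <- tiny_design(p_r_sb = 0)
  expect_equal(nrow(simulate_small_boat(truth, targets, des0, seed = 1)), 0L)
})

test_that("calf indices: trivial cases and the fecundity expectation", {
  sim <- tiny_sim()
  # no calves
  truth0 <- sim$truth
  truth0$calf[] <- FALSE
  lt <- simulate_line_transect(truth0, sim$field, tiny_config(), tiny_design(), seed = 4)
  targets <- lapply(seq_len(truth0$T_years), function(t) {
    select_target_cells(sim$field, tiny_config(), t, 4)
  })
  sb <- simulate_small_boat(truth0, targets, tiny_design(), seed = 4)
  ci <- compile_calf_indices(lt$detections, sb, truth0)
  expect_true(all(ci$calf_survey$n_c == 0))
  expect_true(all(ci$calf_id$n_c == 0))
  # everyone a cow with calf
  truth1 <- sim$truth
  truth1$calf[] <- TRUE
  ci1 <- compile_calf_indices(lt$detections, sb, truth1)
  expect_equal(ci1$calf_survey$n_c, ci1$calf_survey$N)
  expect_equal(ci1$calf_id$n_c, ci1$calf_id$N)
  # bounded by denominators always
  ci2 <- compile_calf_indices(lt$detections, sb, sim$truth)
  expect_true(all(ci2$calf_survey$n_c <= ci2$calf_survey$N))
})

test_that("survey calf proportion matches rho/(rho chi + phi) under stable vitals", {
  cfg <- sim_config(N0 = 400L)
  v <- cfg$vitals_stable
  expected <- v[["rho"]] / (v[["rho"]] * v[["chi"]] + v[["phi"]])
  props <- unlist(lapply(1:30, function(seed) {
    sim <- simulate_scenario(cfg, "B", survey_design(), seed = seed)
    with(sim$dataset$calf_survey, n_c / N)
  }))
  mcse <- sd(props) / sqrt(length(props))
  expect_lt(abs(mean(props) - expected), 3 * mcse)
})

test_that("no capture history extends past the true death year", {
  sim <- tiny_sim()
  ds <- sim$dataset
  idx <- match(ds$catalog_ids, seq_len(nrow(sim$truth$alive)))
  sb_any <- apply(ds$Y_sb, c(1L, 3L), max)
  for (i in seq_along(idx)) {
    dy <- sim$truth$death_year[idx[i]]
    if (!is.na(dy) && dy < ds$T_years) {
      late <- (dy + 1L):ds$T_years
      expect_true(all(ds$Y_survey[i, late] == 0L))
      expect_true(all(sb_any[i, late] == 0L))
    }
  }
})
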