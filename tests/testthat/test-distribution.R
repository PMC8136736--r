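# Individual-to-cell assignment and the survey-region trajectory.

make_field <- function(cfg, h_vec) {
  structure(
    list(
      h = matrix(h_vec, cfg$n_cells, cfg$T_years),
      H = matrix(0, cfg$n_cells, cfg$T_years),
      cell_area = 1, cell_col = cfg$cell_col, cell_row = cfg$cell_row,
      scenario_habitat = "random", amplitude = c(ns = 0, mobile = 0)
    ),
    class = "habitat_field"
  )
}

test_that("uniform suitability spreads individuals evenly; point mass concentrates them", {
  cfg <- tiny_config()
  pop <- simulate_population_truth(cfg, "stable", seed = 1)
  K <- cfg$n_cells
  tr <- distribute_individuals(pop, make_field(cfg, rep(1, K)), seed = 1)
  occ <- table(factor(tr$cell[tr$alive], levels = seq_len(K)))
  n_tot <- sum(occ)
  expect_gt(
    suppressWarnings(chisq.test(occ, p = rep(1 / K, K))$p.value), 0.01
  )
  h <- rep(0, K)
  h[13] <- 5
  tr2 <- distribute_individuals(pop, make_field(cfg, h), seed = 1)
  expect_true(all(tr2$cell[tr2$alive] == 13L))
})

test_that("cell occupancy matches multinomial probabilities (chi-square GOF)", {
  cfg <- tiny_config()
  pop <- simulate_population_truth(cfg, "stable", seed = 3)
  set.seed(99)
  h <- rexp(cfg$n_cells) + 0.1
  tr <- distribute_individuals(pop, make_field(cfg, h), seed = 3)
  cells <- tr$cell[tr$alive]
  expect_gte(length(cells), 800) # at least ~800 individual-years of draws
  occ <- table(factor(cells, levels = seq_len(cfg$n_cells)))
  p <- h / sum(h)
  expect_gt(suppressWarnings(chisq.test(occ, p = p)$p.value), 0.01)
})

test_that("all-zero suitability aborts", {
  cfg <- tiny_config()
  pop <- simulate_population_truth(cfg, "stable", seed = 1)
  expect_error(
    distribute_individuals(pop, make_field(cfg, rep(0, cfg$n_cells)), seed = 1),
    "all zero"
  )
})

test_that("survey-region trajectory respects trivial masks and requires assignments", {
  cfg <- tiny_config()
  pop <- simulate_population_truth(cfg, "stable", seed = 2)
  expect_error(survey_region_trajectory(pop, cfg), "assignments missing")
  f <- generate_habitat_field(cfg, "random", seed = 2)
  tr <- distribute_individuals(pop, f, seed = 2)
  cfg_all <- cfg
  cfg_all$survey_region_mask <- rep(TRUE, cfg$n_cells)
  expect_equal(survey_region_trajectory(tr, cfg_all), unname(pop$N_t))
  cfg_none <- cfg
  cfg_none$survey_region_mask <- rep(FALSE, cfg$n_cells)
  expect_true(all(survey_region_trajectory(tr, cfg_none) == 0L))
})

test_that("scenario D declines faster in-region than B or C", {
  cfg <- tiny_config(N0 = 200L)
  slope <- function(sc, seed) {
    sim <- simulate_scenario(cfg, sc, tiny_design(), seed = seed)
    traj <- survey_region_trajectory(sim$truth, cfg)
    unname(coef(lm(log(pmax(traj, 1)) ~ seq_along(traj)))[2])
  }
  seeds <- 1:8
  sB <- vapply(seeds, function(s) slope("B", s), numeric(1))
  sC <- vapply(seeds, function(s) slope("C", s), numeric(1))
  sD <- vapply(seeds, function(s) slope("D", s), numeric(1))
  expect_lt(mean(sD), mean(sB))
  expect_lt(mean(sD), mean(sC))
})
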