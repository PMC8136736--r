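# Dataset assembly, validation and serialization round-trips.

test_that("write -> read -> write is byte-identical and stable across runs", {
  ds <- tiny_sim()$dataset
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  d3 <- withr::local_tempdir()
  write_survey_dataset(ds, d1)
  ds2 <- read_survey_dataset(d1)
  write_survey_dataset(ds2, d2)
  for (f in list.files(d1)) {
    expect_identical(
      readLines(file.path(d1, f)), readLines(file.path(d2, f)),
      label = paste("file", f)
    )
  }
  # regenerating the same scenario from the same seed gives identical files
  sim2 <- simulate_scenario(tiny_config(), "B", tiny_design(), seed = 5)
  write_survey_dataset(sim2$dataset, d3)
  for (f in list.files(d1)) {
    expect_identical(
      readLines(file.path(d1, f)), readLines(file.path(d3, f)),
      label = paste("regenerated file", f)
    )
  }
})

test_that("deleting a distance record trips validation naming cell and year", {
  ds <- tiny_sim()$dataset
  ds$distances <- ds$distances[-1L, ]
  bad_cell <- tiny_sim()$dataset$distances$cell[1L]
  bad_year <- tiny_sim()$dataset$distances$year[1L]
  expect_error(
    validate_survey_dataset(ds),
    paste0("cell ", bad_cell, ", year ", bad_year)
  )
})

test_that("capture histories violating first-capture or survey-year rules are caught", {
  ds <- tiny_sim()$dataset
  off <- setdiff(seq_len(ds$T_years), ds$survey_years)[1]
  ds$Y_survey[1, off] <- 1L
  expect_error(validate_survey_dataset(ds), "outside survey years")

  ds <- tiny_sim()$dataset
  ds$first_any[1] <- ds$first_any[1] + 1L
  expect_error(validate_survey_dataset(ds), "first-capture")

  ds <- tiny_sim()$dataset
  ds$calf_survey$n_c[1] <- ds$calf_survey$N[1] + 1L
  expect_error(validate_survey_dataset(ds), "denominator")
})

test_that("capture-rate summary is computed over previously cataloged alive individuals", {
  sim <- tiny_sim()
  r <- capture_rate_summary(sim$truth, sim$dataset)
  expect_true(all(r >= 0 & r <= 1))
})

test_that("config, model-spec, truth and habitat serialization round-trips", {
  dir <- withr::local_tempdir()
  cfg <- tiny_config()
  p1 <- file.path(dir, "config.txt")
  write_sim_config(cfg, p1)
  cfg2 <- read_sim_config(p1)
  for (k in c("grid_cols", "T_years", "N0", "fidelity", "ns_share")) {
    expect_equal(cfg2[[k]], cfg[[k]], label = k)
  }
  expect_equal(cfg2$vitals_declining, cfg$vitals_declining)

  spec <- model_spec("4", "change", T_BP = 8L, N_max = 2500L)
  p2 <- file.path(dir, "spec.txt")
  write_model_spec(spec, p2)
  spec2 <- read_model_spec(p2)
  expect_equal(spec2[c("model", "variant", "T_BP", "N_max")],
    spec[c("model", "variant", "T_BP", "N_max")])
  expect_equal(spec2$priors, spec$priors)

  sim <- tiny_sim()
  p3 <- file.path(dir, "truth.csv")
  write_population_truth(sim$truth, p3)
  truth_df <- read.csv(p3)
  expect_equal(nrow(truth_df), sum(sim$truth$alive))
  expect_equal(
    unname(table(truth_df$year)[1]), sim$truth$N_t[1]
  )
  p4 <- file.path(dir, "habitat.csv")
  write_habitat_field(sim$field, p4)
  hab <- read.csv(p4)
  expect_equal(nrow(hab), nrow(sim$field$h) * ncol(sim$field$h))
  expect_equal(
    matrix(hab$h, nrow(sim$field$h)), sim$field$h,
    tolerance = 1e-10, ignore_attr = TRUE
  )
})
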