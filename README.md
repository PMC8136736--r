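# cetipm

Integrated population models (IPMs) for estimating cetacean population
trends — and detecting changes in trend — when surveys cover only part of a
shifting range.

Cetacean stock assessments usually rest on line-transect distance-sampling
surveys of a fixed region. If the habitat shifts (regime shift, climate
change), animals leave the survey region and the apparent abundance
declines even though the population is stable; a conventional trend model
cannot tell distribution change from population change. `cetipm` is a
simulation-estimation framework for quantifying that confounding and for
measuring how much habitat covariates, calf indices, and individual
photo-identification mark-recapture data (from the survey vessel and from
annual small-boat studies) improve trend estimation.

It provides:

* a **scenario simulator**: an individual-based, age-structured whale
  population (~1000 non-calves, 16 years, stable or stable-then-declining
  with a one-third decline over the final 8 years) distributed over a
  spatially autocorrelated habitat grid that either varies randomly or
  shifts out of the survey region after year 8 (scenarios A-D, factorial,
  with shared realizations across scenarios for matched seeds);
* an **observation simulator**: six triennial line-transect surveys with
  half-normal detection and perpendicular distances, photo-ID of detected
  animals, annual three-occasion robust-design small-boat studies in the
  ten best nearshore cells, and two calf indices — calibrated so that the
  realized capture products match the published summaries (0.08 per survey
  year; 0.15 per year for the small boat);
* a **ladder of Bayesian IPMs** (Models 1a, 1b, 2, 3, 4 — from distance
  sampling alone to the full joint model with both mark-recapture sources),
  each in constant-trend and change-in-trend variants, fit by an adaptive
  Metropolis-within-Gibbs sampler (C++ core) under the published MCMC
  protocol, with latent alive/availability states marginalized analytically;
* **evaluation tools**: WAIC model comparison with pointwise
  log-likelihoods, posterior summaries of the derived change parameter
  `Delta = upsilon_2 - upsilon_1` where `upsilon = log(rho chi + phi)`,
  Gelman-Rubin and Geweke diagnostics, trajectory plots, and an end-to-end
  scenario-experiment driver with a machine-readable report.

## Worked example

```r
library(cetipm)

cfg <- sim_config()                                   # the default world
sim <- simulate_scenario(cfg, "B", survey_design(), seed = 42)
sim$dataset
#> <survey_dataset> 796 distances, 2400 cell-year counts, 1285 cataloged individuals over 16 years

sim$truth$N_t                                         # true population: stable
#>  [1] 1000  995 1019 1020 1005 1017  997  977  970  968  966  980  990  989 1004  995
survey_region_trajectory(sim$truth, cfg)              # in-region: apparent decline
#>  [1] 775 778 686 682 744 788 593 693 327 399 479 519 457 472 515 433

fit <- fit_model(model_spec("4", "constant"), sim$dataset,
                 mcmc_config(preset = "desk"), seed = 1)
fit
#> <cetipm_fit> Model 4 (constant) - 500 draws x 2 chains
#>            median     q2.5    q97.5
#> phi1       0.9439   0.9362   0.9516
#> rho        0.0695   0.0606   0.0790
#> chi        0.6275   0.6010   0.7357
#> upsilon1  -0.0120  -0.0209  -0.0012
#> N_16     847.0000 746.0000 962.0250
```

The population is stable (true trend 0, true survival 0.94): the full IPM
recovers survival accurately and estimates a long-term trend near zero
despite the in-region counts falling by ~4% per year — the habitat
covariate and the mark-recapture data absorb most (not all) of the
distribution shift. The change-in-trend variant summarizes the evidence for
a change after year 8:

```r
fitc <- fit_model(model_spec("4", "change"), sim$dataset,
                  mcmc_config(preset = "desk"), seed = 1)
change_summary(fitc)
#> <change_summary> P(Delta < 0) = 0.156 (approx. 1:5 odds)
#>   P(Delta < - 0.02 ) = 0.005 (approx. 1:199 odds)

convergence_diagnostics(fit)[, 1:3]
#>   quantity     psrf flagged
#> 1     N_16 1.003356   FALSE
#> 2 upsilon1 1.000403   FALSE
#> 3 deviance 1.002169   FALSE
#> 4     phi1 1.000000   FALSE
```

The full grid of scenarios and models, with WAIC comparison tables and
change summaries written to `report.json`:

```r
run_scenario_experiment(cfg, scenarios = c("B", "C"),
                        models = c("1a", "1b", "2", "3", "4"),
                        mcmc = mcmc_config(preset = "desk"),
                        seed = 1, out_dir = "exp/")
```

A command-line interface mirrors the main entry points:

```sh
Rscript -e 'cetipm::cetipm_cli()' simulate --scenario B --seed 17 --out data/
Rscript -e 'cetipm::cetipm_cli()' fit --model 4 --variant change --data data/ --preset desk --out fit/
Rscript -e 'cetipm::cetipm_cli()' report --scenarios B,C --models 1a,4 --out report/
```

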