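# depsim

Dynamic microsimulation of dependency and care needs in ageing
populations.

## The problem

Planning health and social care for an ageing population requires
projections not just of how many people will be old, but of how many
will need care, at what intensity, and with which co-occurring
conditions. `depsim` implements a discrete-time dynamic microsimulation
for this problem: individual records — each carrying sociodemographic
factors, health behaviours, eight chronic diseases, sensory
impairments, cognition (MMSE) and physical dependency — are advanced
month by month through stochastic state transitions and lifetable
mortality, and the replicate runs are summarised as dependency counts
and prevalence by age band, multimorbidity cross-tabulations,
birth-cohort independence traces, and Sullivan-method health
expectancies.

Dependency is measured on the **interval-of-need** scale, which
classifies people by the frequency with which they need care:

* **high** — needs 24-hour care,
* **medium** — needs help at regular times daily,
* **low** — needs help less than daily,
* **independent** — free from care,

derived from activities-of-daily-living items, continence and
cognition. Severe cognitive impairment (MMSE 0–9) alone implies high
dependency.

## The model

* **Base cohort.** Pooled multi-study extracts with study-specific
  sampling weights are raked (iterative proportional fitting) to
  age-band × sex population margins, cloned to unit weights, and
  subsampled; the inverse sampling fraction scales counts back to
  population units.
* **Transition models.** For every stochastic characteristic (all
  except age, sex, education, occupation) a weighted logistic
  regression of the 2-year state change on baseline covariates is
  fitted from two-wave panel data; age and sex enter every model, and
  recovery to the next less severe category is modelled for physical
  dependency, mild/moderate cognitive impairment, depression and the
  sensory impairments. Biennial probabilities *p* are converted to the
  monthly scale as *m* = 1 − (1 − *p*)^(1/24).
* **Engine.** Each month, each alive individual transitions a
  characteristic when its monthly probability exceeds a fresh uniform
  draw; monthly mortality is the annual lifetable survival taken to the
  1/12 power; dementia is allocated probabilistically outside the
  monthly loop, conditional on age group, MMSE category and residence.
* **Outputs.** Sullivan's method partitions period life expectancy at
  65 into state expectancies, e_state = Σ π_state(x)·L_x / l_65.
  Uncertainty is reported as the range over ten repeated seeded runs,
  with the first run as the headline.

Because the real survey microdata are not distributable, the package
includes a first-class synthetic-cohort generator with a known,
serialisable ground truth (`truth_params()`), which enables exact
parameter-recovery and oracle tests.

## Worked example

```r
library(depsim)

categorise_mmse(c(9, 21, 27))
#> [1] "severe" "mild"   "normal"
classify_interval_of_need(list(help_toilet = TRUE), dialect = "study_b")
#> [1] "high"
biennial_to_monthly(0.5)
#> [1] 0.02846806

set.seed(42)
params <- truth_params()
panel <- list(generate_study_extract(8000, "studyA", params, seed = 1),
              generate_study_extract(4000, "studyB", params, seed = 2))
models <- fit_transition_models(panel, min_at_risk = 30)
models[["stroke:FALSE>TRUE"]]
#> <transition_model stroke:FALSE>TRUE (incidence), n=9653, events=184>
#> (Intercept)       age_c      age_c2    sex_male
#>     -4.3525      0.0634      0.0047      0.1138

base <- build_base_population(panel, default_margins(4e5), 0.01, seed = 3)
lt <- generate_lifetable(params)
dt <- generate_dementia_table(params)
cfg <- simulation_config(end = "2025-06", output_years = c(2015, 2025),
                         n_runs = 3, master_seed = 7)
res <- run_simulation(base, models, lt, dt, cfg)

cube <- tabulate_runs(res)
subset(cube_margin(cube, c("run", "year", "interval_of_need")), run == 1)
#>    run year interval_of_need count
#> 1    1 2015             high   163
#> 4    1 2025             high   260
#> 7    1 2015      independent   856
#> 10   1 2025      independent   679
#> 13   1 2015              low   395
#> 16   1 2025              low   242
#> 19   1 2015           medium   143
#> 22   1 2025           medium   108

pv <- dependency_prevalence(res$runs[[1]]$snapshots[["2025"]], ages = 65:105)
sullivan(pv, lt, year = 2025)
#>      sex year       level     years proportion_pct total_le
#> 1 female 2025 independent 10.971756      50.935085 21.54066
#> 2 female 2025         low  4.635065      21.517743 21.54066
#> 3 female 2025      medium  1.660615       7.709211 21.54066
#> 4 female 2025        high  4.273229      19.837962 21.54066
#> 5   male 2025 independent 10.736047      57.672088 18.61567
#> 6   male 2025         low  2.977690      15.995610 18.61567
#> 7   male 2025      medium  1.784383       9.585378 18.61567
#> 8   male 2025        high  3.117552      16.746924 18.61567

range_over_runs(res, function(rr) {
  s <- rr$snapshots[["2025"]]
  c(high_dep_65plus = sum(s$alive & s$age_months >= 780 &
                            s$interval_of_need == "high", na.rm = TRUE))
})
#>         statistic headline min max
#> 1 high_dep_65plus      260 260 276

relative_change(3655, 5602)
#> [1] 53.3
```

The counts are sample counts of the simulated base cohort (multiply by
`attr(base, "scaling_factor")`, here 100, for population units). The
Sullivan rows partition total life expectancy at 65 — for women here,
21.5 remaining years of which 11.0 are expected independent (50.9%) at
2025 prevalence. `relative_change` / `proportion_of_le` implement the
percent arithmetic used in the projection report tables.

A command-line front end with `generate | fit | simulate | report`
subcommands is installed at `inst/cli/depsim`; each stage writes a JSON
manifest, and `report` refuses to run on inputs that fail their
manifest checksums.

## Package layout

* `R/interval_of_need.R` — MMSE categorisation and the interval-of-need
  classifier (two item dialects).
* `R/synthetic_cohort.R`, `R/truth_params.R` — the ground-truth
  parameterisation, study-extract generator, raking/cloning/sampling.
* `R/transition_models.R` — weighted logistic transition fits,
  probability-scale conversions, JSON serialisation.
* `R/engine.R` — the monthly simulation loop and replicate runner.
* `R/dementia.R`, `R/lifetable.R` — post-simulation dementia
  allocation; Gompertz–Makeham lifetable with l_x / L_x columns.
* `R/outputs.R` — tabulation cube, Sullivan expectancies, cohort
  traces, run ranges, report arithmetic.
* `R/stages.R`, `R/io.R`, `inst/cli/depsim` — pipeline stages,
  validated CSV I/O, manifests, CLI.

See the vignette in `vignettes/` for the modelling assumptions, the
synthetic-data design and known limitations.
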