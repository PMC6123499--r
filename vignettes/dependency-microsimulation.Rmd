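---
title: "Methods: dynamic microsimulation of dependency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dynamic microsimulation of dependency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depsim)
```

# The model

`depsim` is a discrete-time dynamic microsimulation. Each simulated
individual is a record of sociodemographic factors (sex, age in
months, education, occupation), health behaviours (smoking status,
body-mass class, physical activity), eight chronic diseases (coronary
heart disease, stroke, hypertension, diabetes, arthritis, cancer,
respiratory disease, depression), vision and hearing impairment,
cognition (an MMSE score, 0–30), physical dependency on the
interval-of-need scale, residence (community or care home), and an
alive flag. The simulation has two parts: construction of a weighted
base cohort, and monthly stochastic ageing of that cohort to a
projection horizon.

## Interval of need

Dependency is the four-level interval-of-need scale — `independent <
low < medium < high` — defined by the frequency of care required:
24-hour care (high), help at regular times daily (medium), help less
than daily (low), free from care (independent). The classifier
(`classify_interval_of_need()`) evaluates the level rules top-down
(high, then medium, then low) and the first rule that fires wins; this
makes the categories exclusive and ties deterministic. Two item
dialects are supported, reflecting the two item sets under which the
scale is operationalised: `study_a` (richer: proxy-interview items, an
MMSE 0–9 rule in the high row, instrumental items such as cutting
toenails and heavy housework) and `study_b` (leaner: pushing/pulling
and house/garden-work difficulty items). Three deliberate reading
choices:

* **Incontinence never classifies alone**: it enters only in the
  conjunctions "incontinent and needs help putting on shoes and socks"
  (both dialects) and, in `study_a`, "incontinent and needs help to
  dress (proxy)".
* **Missing items**: a person is classifiable at a level whenever the
  items triggering that level are present-and-true, whatever else is
  missing; `independent` additionally requires that *no* rule item is
  missing. If no rule fires and anything is missing, the person is
  unclassifiable and the classifier errors rather than guessing.
* **Cognition floors**: only severe impairment (MMSE 0–9) forces a
  dependency floor (high). Mild and moderate impairment influence
  dependency through the transition models, not through the
  classifier.

Physical dependency is simulated free of cognitive impairment and the
final interval of need is `max(physical, cognition floor)`
(`combine_physical_and_cognition()`), applied at snapshot time. This
avoids double-counting cognition, which is both a component of the
scale and a risk factor for transitions.

## Transition models

Every stochastic characteristic (all except age, sex, education and
occupation) moves by adjacent severity steps, each step governed by a
logistic model of the 2-year state change fitted to two-wave panel
data (`fit_transition_model()`). Conventions:

* Age enters in years centred at 65 (`age_c`), with a square scaled by
  100 (`age_c2`) so coefficients stay O(1); sex enters everywhere.
  Physical-dependency worsening models additionally take the chronic
  disease count, cognitive-impairment indicators, physical inactivity,
  obesity and sensory impairment — the major modifiable risk factors
  for dependency. Covariate lists are configuration-driven
  (`default_covariate_config()`).
* Fits are weighted by the study-specific sampling weights, normalised
  to mean one inside the fit so that estimates (and standard errors)
  are invariant to uniform weight rescaling. Estimation uses
  `stats::glm` with a quasibinomial family (prior weights are
  non-integer).
* Individuals lost to follow-up, including deaths, are censored: the
  fit conditions on being observed at both waves. Attrition in the
  synthetic panel is missing-at-random given age, which this treatment
  handles correctly.
* Recovery models — to the next less severe category only — exist for
  low/medium/high physical dependency, mild and moderate cognitive
  impairment, depression, and the vision and hearing impairments.
  Diseases other than depression are absorbing.
* Dementia is never a covariate: it is allocated after the simulation
  (below), so it cannot be an explanatory variable.
* Degenerate inputs error loudly, naming the transition: fewer at-risk
  individuals than `min_at_risk` (default 50), zero (or all) events, a
  covariate constant over the at-risk panel, or apparent separation
  (non-convergence or |coefficient| > 15).

**Monthly conversion.** The biennial probability *p* is rescaled to a
monthly probability *m* by complement compounding, *m* = 1 − (1 −
*p*)^(1/24), the constant-hazard-within-window form; 24 monthly
applications recompose *p* exactly (to 10⁻¹², tested on a 1000-point
grid). An embedded multi-state (matrix-logarithm) rescaling would
interact across competing transitions; the root form is the standard,
transparent choice and is applied per transition. Annual survival is
likewise taken to the 1/12 power, so twelve monthly survivals compound
exactly to the annual probability.

## The monthly engine

Within a month each characteristic is updated in a configurable order
(default: behaviours → diseases → sensory impairments → cognition →
physical dependency), with later characteristics seeing the
within-month updated values of earlier ones — dependency is downstream
of its risk factors. An individual transitions when the model's
monthly probability strictly exceeds a uniform draw. Mortality is
applied after the characteristic updates (the within-month order of
mortality is a free choice at monthly resolution; applying it last
means a person's final month of life is simulated in full), and
survivors then age one month. Dead individuals are frozen: no field,
including age, changes after death.

Random numbers: each replicate run derives its own seed
deterministically from the master seed, and within a run one uniform
vector is drawn for the *whole* population per characteristic-model
per month (and per mortality pass), regardless of who is at risk.
Results are therefore independent of the iteration order over
individuals, and paired runs under perturbed parameters share their
random numbers (common random numbers), which makes stochastic
monotonicity checks sharp. The cost — a few unused draws — is
negligible.

Because updates are sequential within a month, a person can pass
through two adjacent severity steps in one month (normal → mild →
moderate), and for reversible characteristics the within-month chain
is the product of the step matrices, not a single-draw competing-risks
scheme. At monthly resolution the step probabilities are small and
this effect is second-order; the engine's two-state occupancy is
tested against the matrix power of exactly this sequential-update
chain, and the absorbing case against the textbook chain.

**Dementia** is allocated outside the monthly loop, at each output-year
snapshot, as a Bernoulli draw per individual with probability from an
age-group × MMSE-category × residence table. It alters no other field.

**Snapshots** are taken after the June update of each output year — a
mid-year period-prevalence convention (the choice of month is not
substantive; it is configurable via `snapshot_month`).

No new entrants are injected: the base cohort starts at ages 35+, so
everyone who is 65+ by the last output year is already in the base;
immigration is out of scope. Care-home residence is held fixed (no
residence transition model). Ages beyond the lifetable's terminal row
reuse the terminal survival probability. Transition models are held
constant over the projection — a strong assumption shared by this
class of models.

## Base-cohort construction

`build_base_population()` pools the study extracts with their
study-specific weights, rakes the pooled weights to age-band × sex
population margins, clones each row `round(weight)` times
(round-half-to-even, so totals are stable and deterministic), and
draws a simple random subsample. Raking is iterative proportional
fitting with relative tolerance 10⁻¹⁰ and a 100-sweep cap; with a full
age-band × sex cross-classification this reduces to direct
post-stratification and converges in one sweep, but the general loop
is kept so coarser margin specifications also work. The inverse
sampling fraction is recorded as the `scaling_factor` attribute and
carried through to the output cube — counts are sample counts, and the
factor converts them to population units.

## Outputs

`tabulate_runs()` produces exact integer counts by run × year × sex ×
age band (65–74, 75–84, 85+) × interval of need × disease-count
stratum (0–1, 2, 3+) × dementia flag; margins over any index are
additive by construction. Sullivan's method
(`sullivan()`) partitions period life expectancy at 65:

$$e_{state} = \frac{\sum_{x \ge 65} \pi_{state}(x) \, L_x}{l_{65}},$$

with π taken from the same year's snapshot (period, not cohort,
expectancies). State years sum to total LE identically; this is
property-tested to 10⁻⁹ over random prevalence schedules and
lifetables. Prevalence is computed per single year of age and sex;
ages with fewer than 30 observations are smoothed by a 5-year centred
moving window on the counts, and ages beyond the observed range carry
the nearest observed age — small-sample noise in the oldest ages
otherwise dominates the tail of the lifetable weighting.
Report-table arithmetic (`relative_change()`, `proportion_of_le()`)
rounds half away from zero to one decimal, matching the conventional
printed style. Uncertainty is reported as the min–max range over the
replicate runs with the first run as the headline
(`range_over_runs()`); these are Monte-Carlo ranges, not confidence
intervals.

# The synthetic-cohort generator

The real inputs to such a model — pooled national longitudinal studies
and an official projection lifetable — cannot be redistributed, so the
package generates synthetic stand-ins with known ground truth
(`truth_params()`), and the truth is serialised beside every generated
dataset. The generator's defaults define the package's study
conditions and were fixed once, on demographic plausibility, not tuned
to any test outcome:

* **Scale**: three study extracts of 13 000, 4 400 and 2 600
  individuals (echoing the relative sizes of a large household panel,
  a mid-sized ageing cohort and a smaller cognitive-ageing study),
  pooled to a 20 000-person panel; a 1% subsample after cloning forms
  the base population. The bundled default margins total 3 million
  (base ≈ 30 000); the acceptance script uses margins of 800 000 (base
  ≈ 8 000) so a ten-run projection completes in minutes on one CPU.
* **Age structure**: exponential density declining at 1.8%/year from
  age 35, with a female share rising with age. This is a smooth
  stand-in; it deliberately does not reproduce cohort bulges (e.g. a
  baby boom), so projected *totals* evolve differently from a real
  population — the machinery, not the demography, is the point.
* **Baseline prevalence**: every characteristic follows a logistic
  age-sex gradient with round-number coefficients (e.g. hypertension
  rising from ~5% at 35 to ~50% at 85; severe cognitive impairment
  rare below 80; care-home residence ~5% at 85). Lognormal sampling
  weights (σ = 0.5) emulate design weights.
* **Transitions**: biennial logits with plausible signs and sizes —
  disease incidence rising with age, recovery falling with age,
  dependency worsening increasing with the disease count.
* **Mortality**: Gompertz–Makeham hazard μ(x) = a·e^(0.095(x−35)) +
  0.0002 with a = 7.5×10⁻⁴ (men) and 5.25×10⁻⁴ (women), giving life
  expectancies at 65 of about 18.6 and 21.5 years — period-realistic
  for a high-income country in the mid-2010s. l_x uses radix 100 000;
  L_x is the midpoint (l_x + l_{x+1})/2 with terminal open interval
  L_ω = l_ω/μ_ω, standard demographic practice.
* **Attrition**: 15% over two years, missing-at-random given age
  (logit slope 0.01/year), matching the censoring treatment in the
  fitting module.
* **Panel generation**: the 2-year follow-up applies one biennial
  Bernoulli draw per transition model with *all* probabilities
  evaluated on the frozen baseline state — exactly the structure the
  two-wave GLM estimates, which is what makes parameter recovery a
  clean test. Where a worsening and a recovery model share a baseline
  state, the later registry write wins; the resulting joint bias is a
  product of two step probabilities and is avoided in the
  recovery tests by using absorbing and single-recovery
  characteristics.

What passing tests on this synthetic world do **not** show: that the
generator's gradients match any real survey; that real panel
attrition is ignorable; that real transition models are stable over
20 years; or that the projected totals resemble a real population's
(no cohort bulges, no migration). They do show that the estimation
machinery recovers known truth, that the engine obeys its analytic
oracles (matrix powers, lifetable survivorship, Sullivan
conservation), and that the full pipeline is deterministic under its
seeds.

# Numerical and testing choices

* Seeds: every stochastic stage takes an explicit integer seed;
  replicate-run seeds are drawn from the master seed via a temporary
  RNG state that is restored afterwards.
* Problem sizes: unit tests use populations of 10³–10⁴ and short
  horizons; the oracle tests use 10 000 individuals (Monte-Carlo
  standard errors small enough for 3σ bounds to be meaningful); the
  parameter-recovery experiment uses 50 replicates of a 20 000-person
  panel; the acceptance pipeline uses an 8 000-person base over
  2014–2035 with ten runs. These sizes are the package's own
  desk-scale choices.
* CSV writers format doubles with `%.17g`, so all tables round-trip
  exactly; readers validate cell types and name the offending
  row/column. Pipeline stages write JSON manifests (config hash,
  seeds, file checksums); downstream stages refuse inputs that fail
  their checksums, and re-running a stage from the same configuration
  reproduces its data files byte-identically.

# Known limitations

* The interval-of-need item dialects are idealised indicator sets; no
  mapping from any real questionnaire's wording is attempted, and the
  MMSE instrument itself is not scored.
* Weighted-GLM standard errors use the quasibinomial dispersion, not a
  full design-based (linearised) variance; for the synthetic
  equal-design panels these agree, but for strongly clustered real
  surveys they would not.
* One period lifetable drives mortality throughout, so total life
  expectancy at 65 is constant across output years; projecting
  *changes* in total LE would require year-specific (projected)
  lifetables, which the Sullivan function accepts but the bundled
  generator does not produce.
* No scenario engine (counterfactual risk-factor paths), no care-cost
  layer, no migration, no residence transitions.
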