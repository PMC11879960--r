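---
title: "Optimizing weekly PE schedules for cohort health outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimizing weekly PE schedules for cohort health outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peopt)
```

## The problem

School physical-education (PE) programs are usually scheduled by convention
rather than by expected health impact. `peopt` treats the weekly PE schedule
as a decision vector — how many sessions per week, how long each session is,
how time is split across five activity types (aerobic, strength, team,
flexibility, recreational) and three intensity levels (low, moderate,
vigorous) — and searches for the schedule that maximizes a weighted,
multi-metric health fitness score over a cohort of students aged 6–18.

Four outcome metrics enter the score: predicted BMI reduction, fitness-score
improvement, per-session caloric expenditure, and resting-heart-rate (RHR)
reduction. Six metaheuristics — a genetic algorithm (GA), particle swarm
optimization (PSO), ant colony optimization (ACO), simulated annealing (SA),
differential evolution (DE) and an artificial bee colony (ABC) — search the
same decision space under the same evaluation budget, so their results are
directly comparable.

## The health model

### Closed-form energetics

Per-session energy expenditure uses a MET (metabolic equivalent of task)
formulation augmented by a basal-metabolic-rate factor:

$$\mathrm{Calories} = \mathrm{MET}\cdot W\cdot t\cdot\Bigl(1 + \frac{\mathrm{BMR}}{1000}\Bigr),
\qquad \mathrm{BMR} = 10W + 6.25H - 5A + S,$$

with weight $W$ in kg, height $H$ in cm, age $A$ in years, and the sex
constant $S = +5$ (male) / $-161$ (female). The schedule's single MET value
is the activity-mix- and intensity-mix-weighted average of a 5×3 MET table
(`effective_met()`), i.e. a convex combination of the table entries.

### The dose–response layer

Candidate schedules must be scored *before* they are implemented, so the
before/after outcome differences have to be predicted. The package uses a
transparent, monotone, bounded closed-form layer (`predict_outcomes()`):

* **BMI reduction** — energy balance: weekly kcal accumulated over
  `horizon_weeks` (default 12, one school term), divided by 7,700 kcal per
  kg of body fat and by height squared, capped at `bmi_cap` (default
  5 kg/m²).
* **Fitness gain** — saturating exponential
  $\Delta F = F_{\max}(1 - e^{-k_f \cdot \mathrm{MVPA\ h/wk}})$ driven by
  weekly moderate-to-vigorous hours (defaults $F_{\max}=20$ points,
  $k_f = 0.15$).
* **RHR reduction** — saturating exponential in weekly *aerobic* hours
  (defaults $\mathrm{HR}_{\max} = 10$ bpm, $k_h = 0.2$), since endurance
  training is the primary driver of resting-heart-rate adaptation.

Saturation encodes diminishing returns; caps keep single-term predictions
physiologically bounded. All coefficients sit in one `response_params()`
object and are configurable.

### Scalarization

Raw metrics live on incommensurate scales (kcal ≈ 10², bpm ≈ 10⁰), so each
metric is min–max scaled to [0, 1] by fixed decision-space bounds
(`metric_norms()`, values outside clipped) before the weighted sum

$$f = w_1\,\Delta\mathrm{BMI}' + w_2\,\Delta F' + w_3\,\mathrm{Cal}' + w_4\,\Delta\mathrm{HR}',$$

with default weights 0.4/0.3/0.2/0.1 — BMI reduction first (childhood
obesity), then fitness, energy expenditure, and cardiovascular response.
Without normalization the calorie term would dominate every other priority.
The cohort objective is the *mean of per-student scores*, not the score of
the mean student; the distinction matters because the response model is
nonlinear in anthropometrics.

### Calibration of the default MET table

The BMR factor $(1 + \mathrm{BMR}/1000)$ multiplies the raw MET-hour
product by roughly 2.2–2.5 for school-age students. With textbook MET
magnitudes this would predict per-session expenditures of well over
1,000 kcal for a vigorous hour — far outside the 300–400 kcal/session range
typical of school PE interventions. The default table therefore stores
*effective* MET values (aerobic 1.3/1.7/2.2 for low/moderate/vigorous, other
activities proportionally lower, all within [1, 15]) calibrated so that:

* a 1-hour fully vigorous aerobic session for a student with the median
  14-year-old anthropometrics burns ≈ 257 kcal, and
* the optimized schedule (2 h × 5 sessions of vigorous aerobic work at the
  10 h/week cap) averages ≈ 390 kcal/session over the default cohort,

both inside the plausible 250–450 kcal/session band. The calibration was
fixed once from the generator's anthropometric distributions; users modeling
measured (rather than effective) METs can supply their own table through
`response_params()`.

## The decision space and its repair rules

All six optimizers share one 10-coordinate real-vector encoding:
session duration ∈ [0.5, 2] h, session count ∈ {1..7} (relaxed to continuous
and rounded), five activity shares and three intensity shares. Constraints
are handled by repair rather than penalties, so every evaluated candidate is
feasible and fitness values are comparable across algorithms:

1. clip every coordinate to its box bounds;
2. snap to the discretization grid when one is attached
   (`discretize_space()`; ACO and the exhaustive oracle require it, the
   continuous algorithms then explore the identical grid);
3. round the session count to an integer;
4. renormalize both proportion blocks onto their simplexes (an all-zero
   block becomes uniform);
5. shrink the session duration to `t_max_weekly / n_sessions` when the
   weekly-hours cap (default 10 h/week) would be exceeded.

The bounds are a reconstruction, not an empirical fact: the cap of
10 h/week was chosen so that plausible optima press against roughly the
weekly volume a school timetable could accommodate. The default
discretization (7 duration levels, 7 counts, 3 levels per proportion
coordinate) gives ACO a grid whose decoded schedules include the continuous
optimum corner.

## The optimizers

All algorithms maximize, share the budget *population × iterations*
evaluations (+ population for initialization, default 30 × 200), count every
objective evaluation exactly, and return a non-decreasing best-so-far
trajectory. Defaults, all overridable in `optimizer_config()`:

* **GA** — tournament selection (size 3), per-gene blend crossover
  (`pc = 0.9`), Gaussian mutation (`pm = 0.1`, scale 0.1 of each coordinate
  range), elitism of 1.
* **PSO** — inertia `w = 0.7`, cognitive/social `c1 = c2 = 1.5`, velocity
  clamped at half the coordinate range, zero initial velocities (so
  `w = c1 = c2 = 0` provably freezes the swarm).
* **ACO** — per-coordinate pheromone vectors, selection ∝
  $\tau^\alpha\eta^\beta$ with `alpha = beta = 1`, uninformative default
  heuristic η (a hook accepts user-supplied η), evaporation `rho = 0.1`,
  deposit `Q × fitness` by the iteration-best ant, pheromone floored at
  `1e-9` so no level's probability ever reaches zero.
* **SA** — `population` independent chains (honouring the shared budget),
  Gaussian proposals (scale 0.15 of range), Metropolis acceptance
  $\exp(-\Delta E/T)$ for worsening moves, geometric cooling
  `T(t+1) = 0.95 T(t)` from `t0 = 1`.
* **DE** — rand/1/bin: donor $x_{r1} + F(x_{r2} - x_{r3})$ with `f = 0.5`,
  binomial crossover `cr = 0.9` with one guaranteed donor component, greedy
  selection.
* **ABC** — `population/2` food sources; employed and onlooker phases each
  cost one evaluation per source (so a colony consumes exactly `population`
  evaluations per cycle); fitness-proportional onlooker selection on
  shifted fitness; sources failing to improve for `limit = 20` trials are
  re-initialized by scouts folded into the employed phase, preserving the
  budget.

Hyperparameters beyond the shared budget are reconstructions chosen from
common practice for each algorithm family; none were fitted to outcomes.

`exhaustive_oracle()` enumerates every grid point of a discretized space
(≤ 10⁶ points) and returns the exact argmax with deterministic
lexicographic tie-breaking. The test suite uses it as ground truth: on a
400-point toy grid each algorithm must reach the enumerated optimum in
nearly all seeded runs. For such grid studies `optimizer_config(cache =
TRUE)` memoizes objective values per grid point; cache hits still count as
evaluations, so budgets are unaffected.

## The synthetic cohort

No real student records ship with the package; `generate_cohort()` emulates
the study's feature set with seeded, self-consistent draws:

* age uniform on 6–18; sex Bernoulli with configurable ratio;
* height from a sex- and age-conditional piecewise-linear growth reference
  (growth-chart medians at integer ages) plus Gaussian noise (SD 6 cm);
* BMI right-skewed — an age-increasing mean (15.3 kg/m² at 6 to
  19.9 kg/m² at 18) times a log-normal factor, truncated to [12, 38];
* weight derived as `bmi × (height/100)²`, so the three anthropometrics are
  mutually consistent by construction (weight and height are not part of
  the study's tabulated feature set but are required inputs of the BMR and
  calorie formulas, so they are generated and stored explicitly);
* fitness score ~ N(62, 13) clipped to [0, 100]; RHR declining with age
  (≈ 92 bpm at 6 to ≈ 71 at 18, SD 7, clipped to [50, 120]);
* baseline weekly PE time, session frequency, a Dirichlet-style activity
  mix, an intensity level, and a per-session caloric expenditure computed
  from the record's own mix, weight and BMR — so the baseline feature obeys
  the same energetics as the optimizer's predictions;
* instructor-to-student ratio and facility utilization are generated for
  completeness but are not decision variables.

Missingness is injected completely at random (exact per-feature counts, so
realized rates match requested ones up to rounding), never into the record
id, BMI, or the compositional activity block. Outlier injection displaces
continuous cells at least 3 IQRs from the feature median — strictly beyond
the 1.5-IQR Tukey fences — and logs every displacement so tests can verify
that the filter recovers exactly the injected records.

**What passing tests do and do not show.** The generator produces plausible
marginals and self-consistent anthropometrics, but no real covariance
structure (fitness, BMI and RHR are drawn independently given age), no
longitudinal trajectories, and missingness that is MCAR by construction.
Tests passing on these cohorts validate the pipeline's mechanics and the
model's stated properties — not the clinical accuracy of predicted outcome
magnitudes on real students.

## Preprocessing

`preprocess_cohort()` runs a fixed stage order: mean/mode imputation →
record-wise IQR outlier removal → min–max scaling → one-hot encoding.
Choices the study description left open, fixed and documented here:

* quartiles by linear interpolation of order statistics (R's type-7
  default), so the brute-force oracle in the tests matches exactly;
* imputation *before* filtering, so fences are computed on complete data;
* a record is removed when *any* screened continuous feature falls outside
  its fences (cell-wise removal would leave ragged records that the
  optimizer cannot consume); bounded compositional shares and one-hot
  indicators are not screened — Tukey fences on an indicator with a
  minority class would flag the minority wholesale;
* scaling parameters are estimated on the post-filter cohort and stored in
  the report; the returned object keeps both the natural-unit `clean`
  cohort (what the optimizer consumes) and the scaled, encoded `scaled`
  view. Re-running the pipeline on its own `clean` output with the stored
  fences and scaling parameters is the identity — without stored fences,
  iterated Tukey filtering could keep shaving the tails;
* `min_max_scale()` maps a degenerate feature (max = min) to 0 with a
  warning rather than erroring, so constant columns cannot kill a run.

## Experiments

* `convergence_experiment()` — aligned best-so-far trajectories for any
  subset of algorithms under a guard that rejects unequal
  population × iterations budgets.
* `summary_experiment()` — seeded replicates per algorithm (default 10)
  with mean ± z·SD/√n confidence half-widths for weekly PE time, the four
  outcome metrics, and best fitness. The normal-approximation CI is the
  simplest defensible choice for replicate means; with ≤ 10 replicates the
  half-widths are indicative, not inferential.
* `sensitivity_experiment()` — perturbs the BMI weight by ±5% (relative),
  rescales the remaining weights proportionally so the simplex constraint
  holds, and re-runs the same algorithm (ACO by default) with the same
  seed. BMI-priority and fitness-score indices are ratios of optimized
  cohort-mean ΔBMI and ΔF to baseline, × 100; the 0% row is the baseline
  itself, so its indices are exactly 100 by construction. Under the default
  co-monotone response model all four metrics share one optimum, so ±5%
  perturbations typically leave the optimized schedule unchanged and the
  indices at exactly 100 — consistent with (and the degenerate case of) the
  expected directions: larger BMI weight never lowers the BMI priority
  index and never raises the fitness index. Reproducing numerically large
  trade-offs would require a response model in which the metrics genuinely
  compete, which the stated closed forms do not induce.
* `rank_algorithms()` — per-metric ranks (larger mean = better), ties
  broken alphabetically.

`run_pipeline()` wires synth → preprocess → compare → sensitivity together,
derives every stage seed from one global seed via a documented hash
(`derive_seed()`), echoes the effective configuration, and writes a
MANIFEST recording files, timings and completion — a failed stage still
leaves a manifest marked incomplete.

## Problem sizes and numerical choices

The default study configuration is a 500-student cohort, population 30,
200 iterations, 10 replicates; the test suite exercises oracle equivalence
at 100 seeds × 6 algorithms on a 400-point grid and the full property set in
a few minutes on one core. Simplex sums are enforced to 1e-9; the
all-zero proportion block decodes to the uniform mix; the weekly-hours cap
is repaired by shrinking session duration (never by dropping sessions), and
`t_max_weekly / n_sessions` always lies inside the duration bounds for the
default space. Weekly PE time is reported as `n_sessions × t_session`
hours/week; a per-day reading (dividing by 5–7 school days) is exposed by
`optimal_pe_time()` because both conventions appear in practice.

## Known limitations

* The dose–response layer is a modeling device: monotone, bounded,
  population-homogeneous (one global `response_params`), with no
  inter-individual response heterogeneity and no interaction between
  metrics beyond shared schedule inputs.
* Because all four metrics are co-monotone in schedule volume, intensity
  and aerobic share, the optimum is a corner of the feasible set and
  weight-sensitivity trade-offs are degenerate (see above).
* Instructor ratio and facility utilization are generated but never
  optimized; they are features of the data model only.
* The confidence intervals summarize replicate-to-replicate optimizer
  variability, not sampling variability of the cohort.
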