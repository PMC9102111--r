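---
title: "Compositional analysis of 24-hour movement behaviours: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compositional analysis of 24-hour movement behaviours: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moveshift)
```

## Why compositional?

A monitored day partitions 1440 minutes into sleep, sedentary time (SED),
light physical activity (LPA) and moderate-to-vigorous physical activity
(MVPA). Minutes in one behaviour can only grow at the expense of the
others, so the four variables are perfectly collinear by construction and
carry only *relative* information. Regressing an outcome on raw minutes
invites spurious findings; the compositional approach instead works in
Aitchison geometry, where a composition is an equivalence class under
scaling and the natural coordinates are log-ratios.

`moveshift` uses **pivot ilr (isometric log-ratio) coordinates**, the
standard realisation of sequential binary partitioning. For pivot order
$(x_1, x_2, x_3, x_4)$,

$$
z_1 = \sqrt{\tfrac{3}{4}}\,\ln\frac{x_1}{(x_2 x_3 x_4)^{1/3}},\qquad
z_2 = \sqrt{\tfrac{2}{3}}\,\ln\frac{x_2}{(x_3 x_4)^{1/2}},\qquad
z_3 = \sqrt{\tfrac{1}{2}}\,\ln\frac{x_3}{x_4}.
$$

The contrast matrix is orthonormal with zero row sums, so the transform is
an isometry from the simplex to $\mathbb{R}^3$ and is invariant to the
closure constant. The canonical part order is (sleep, SED, LPA, MVPA);
"rotations" move one behaviour to the front while keeping the rest in
canonical relative order. That convention is a modelling choice: the
coordinates differ across rotations, but since each rotation is an
orthogonal change of basis, fitted values, $R^2$ and all predictions are
identical (verified to 1e-8 in the tests). Only the *interpretation* of
the coefficients changes, with $z_1$ always readable as "this behaviour
versus the geometric mean of the others".

## The regression and reallocation procedure

1. **Validity filter.** A day is valid when wear time is at least 16 h
   (inclusive); a participant enters the analysis with at least 4 valid
   days and 3 valid nights. Night validity arrives as a flag computed by
   the upstream sleep-detection pipeline; this package only counts it.
2. **Averaging.** Each participant's valid days are averaged
   arithmetically in minute space and closed to 1440 min. Arithmetic
   averaging is the plain reading of "average of valid days"; a
   compositional (geometric) alternative is available via `comp_mean()`
   but is not the default.
3. **Zero screening.** ilr coordinates need strictly positive parts.
   The default policy replaces a zero with 1 minute before closure and
   reports the replacement; a strict `reject` policy is available. One
   minute per day is below any accelerometer's effective resolution for a
   behaviour that was genuinely observed at zero, which keeps the
   perturbation small while retaining the participant.
4. **Models.** OLS of the outcome on $(z_1, z_2, z_3)$, crude and
   adjusted. Covariates are coded sex female = 0 / male = 1, genotype
   homozygous = 0 / heterozygous = 1, age in years (continuous).
   Coefficient p-values are two-sided t-tests on the residual degrees of
   freedom; the model p-value is the overall F-test — the standard OLS
   machinery, via `stats::lm()`. Missing covariates are dropped
   complete-case with a reported count. ilr coordinates are not centred or
   standardised: raw coordinates keep the "vs rest" interpretation and do
   not affect predictions.
5. **Reallocation.** The reference composition is the cohort's
   compositional mean closed to 1440 min. Moving $\delta$ minutes from
   behaviour $a$ to $b$ yields a new composition; because the model is
   linear in ilr space, the intercept and covariate terms cancel between
   the two predictions and
   $\Delta = \beta^\top(z_\text{new} - z_\text{ref})$, with
   $\mathrm{CI} = \Delta \pm t_{\nu}\sqrt{d^\top V_\beta d}$,
   $d = z_\text{new} - z_\text{ref}$ restricted to the ilr block. The grid
   covers all 12 ordered pairs at 10/20/30 min by default. $\Delta$ is
   asymmetric under swapping $a$ and $b$ — log-ratio perturbations are
   largest for small parts, so removing 20 min of a 30-min MVPA budget
   moves the coordinates much further than adding 20 min does.

### Feasibility

A reallocation must leave every part strictly positive (the bound is
strict: a zero-minute behaviour is not a valid composition). Infeasible
grid cells are kept and flagged `feasible = FALSE` rather than erroring or
silently vanishing, because stratum-level reference compositions with
small MVPA means routinely make 30-min displacements out of MVPA
impossible. Notably, the paediatric preset's compositional MVPA mean of
0.02 of the day (28.8 min) makes those cells infeasible at the population
reference — a faithful consequence of the target means, not a defect.

### Stratified grids

`stratified_grid()` refits the model *within* each stratum — crude by
default, since the pooled grid is also reported from the crude model — and
uses each stratum's own reference composition. Both choices are
configurable (`covariates =`, `reference = "overall"`) because neither is
forced by the method. Strata under `min_n = 8` are skipped with a warning;
strata under 15 are analysed but flagged `small_sample`, a pragmatic floor
for a 4-coefficient OLS.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `kappa` | 1440 | min | one day; ilr is closure-invariant, so results are unchanged by rescaling to 1 |
| `min_wear_hours` | 16 | h | inclusive day-validity threshold |
| `min_days`, `min_nights` | 4, 3 | days | inclusion rule |
| `replace_value` | 1 | min | zero-replacement magnitude |
| `deltas` | 10, 20, 30 | min | reallocation grid |
| `ci_level` | 0.95 | — | two-sided t intervals |
| `min_n`, `warn_n` | 8, 15 | participants | stratum floors |
| `resolution` | 64 | — | ternary grid subdivisions per edge |

## What the synthetic generator emulates — and what it does not

`generator_config()` defines a logistic-normal population: ilr coordinates
are multivariate normal, so compositions are strictly positive by
construction, the population compositional mean is exactly
`ilr_inverse(ilr_mean)`, and every regression or reallocation truth is
available in closed form. A Dirichlet alternative was rejected because the
analysis model is linear in ilr coordinates; matching the generative and
analysis geometries makes parameter recovery well-posed and the truth
exact. The outcome is linear in $z$ with additive covariate effects and
homoscedastic Gaussian noise.

Preset populations: `children_like()` (n = 86, compositional mean
0.34/0.22/0.39/0.02 of the day, ages 8–17.9, outcome centred at 86
percentage points) and `adults_like()` (n = 43, 0.33/0.23/0.37/0.06, ages
18–35, centred at 63). Defaults chosen once: `ilr_cov = diag(0.10, 0.12,
0.45)` (MVPA, entering the most log-ratios with a small mean, varies
most), `beta = (16, −7, −5)` and `noise_sd = 18` percentage points, which
together put the crude model's expected $R^2$ near 0.11 — the order
observed in paediatric movement-behaviour cohorts — and the adjusted model
near 0.18; covariate effects (sex +6.9, age −1.4/yr, genotype +2.5) are of
the magnitude reported for such cohorts. Day-level generation adds
multiplicative log-normal jitter (SD 0.15 on the log scale) re-closed to
1440, a normal wear-hours model, and an explicit constructed-failure
mechanism so the filter's inclusion set is known exactly.

What it does **not** emulate: accelerometer measurement error and
brand/cut-point differences, outcome floors/ceilings and skew,
heteroscedasticity, correlation between composition and covariates
(covariates are drawn independently, which is also what makes the
"covariate adjustment leaves ilr coefficients unchanged in expectation"
check meaningful), disease progression, or informative missingness.
Passing tests therefore demonstrate the *statistical machinery* is
correct and calibrated under the stated model; they do not validate the
model against real cohort data.

## Numerical choices

- **Tolerances** live in one table (`R/utils.R`): closure 1e-9 relative,
  ilr round-trip 1e-9 min, basis orthonormality 1e-12, rotation agreement
  1e-8.
- **Closure idempotence** is exact: rows already summing to `kappa`
  within 1e-12 relative pass through unchanged, since rescaling them
  would drift by an ulp.
- **Variation matrix** uses the unbiased $n-1$ sample variance of each
  pairwise log-ratio; entries are non-negative by definition. (Published
  tables occasionally print signed pairwise statistics under this name;
  those are not log-ratio variances and are not reproduced.)
- **Degenerate inputs** fail loudly with classed conditions: zero or
  negative parts, rank-deficient designs (named), undersized groups,
  infeasible reallocations (with the available-minutes bound), non-finite
  coordinates.
- **Exactness of identities**: `reallocate()` works in plain minute
  arithmetic, so a displacement followed by its reverse returns the
  reference bit-exactly, and $\delta = 0$ gives $\Delta = 0$ with a
  degenerate interval, exactly.
- **Ternary grids** compute the third barycentric coordinate from grid
  integers so the boundary mask ("any implied part ≤ 0") is exact.

## Reporting conventions

The coefficient report offers two labelling conventions because the
mapping from printed rows to coordinates is ambiguous in parts of the
applied literature: `"coordinates"` lists $z_1, z_2, z_3$ of each rotation
labelled by what each contrasts, and `"first_pivot"` collects each
behaviour's own vs-rest coefficient from its rotation. Reallocation
intervals are always emitted as (low, high). Significance is starred at
$p \le 0.05$, inclusive.

## Verification scale

The test suite exercises: geometry round-trips on 1000 random
compositions; normal-equations oracle equality on 20 cohorts of n = 50;
rotation invariance on full grids; exact recovery on noiseless cohorts;
coefficient recovery across 200 replicates at n = 1000 (within ±3 SE of
truth at ≥ 99%, relative bias < 5%); 95%-interval coverage for the
30-minute sleep-to-SED reallocation across 500 replicates at n = 130
(required within 93–97%); byte-identical pipeline reruns; and
generator-fidelity checks at n = 5000 (compositional mean within 0.005 per
part). These sizes keep the full suite under a minute on one CPU while
leaving Monte-Carlo margins well inside the asserted bands.

## Known limitations

- Cross-sectional OLS only: no longitudinal decline modelling, no
  mixed effects, no robust/outlier-resistant compositional estimators.
- Fixed to 4-part compositions of the 24-h day (the generic pivot
  formulas would extend, but nothing else is plumbed for D ≠ 4).
- Day averaging takes recorded minutes at face value; partial non-wear
  days are not rescaled (total wear is logged instead).
- The delta-method/t interval for $\Delta$ assumes the OLS error model;
  under real-data heteroscedasticity its coverage is not guaranteed.
- Figures are deterministic in content but not checksummed across
  graphics-library versions; byte-reproducibility guarantees cover the
  tables and manifest.
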