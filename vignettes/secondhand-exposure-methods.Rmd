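---
title: "Methods: from exhaled breath to non-user intake"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from exhaled breath to non-user intake}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(secondair)
```

## Overview

`secondair` estimates the exposure a non-user may receive when sharing an
indoor space with electronic vapor product (EVP) users. The chain has four
stages, each usable on its own:

1. **Synthetic crossover study** (`generate_study()`): paired sham/product
   exhaled-breath collections in a four-period, four-sequence crossover with
   detection-limit censoring.
2. **Sham-corrected ANCOVA** (`fit_sham_ancova()`,
   `estimate_emission_factors()`): least-squares (LS) means per product per
   analyte, converted to per-mg emission factors.
3. **Well-mixed indoor-air model** (`simulate_box()`,
   `partition_equilibrium()`): transient single-box concentration dynamics
   with equilibrium vapor/particle partitioning.
4. **Intake and benchmarking** (`run_scenario()`, `fold_difference()`,
   `limit_reference_intake()`): non-user inhaled mass compared against
   cigarette sidestream sources and 8-h occupational exposure limits.

## The synthetic study generator

The generator emulates a 32-subject, four-sequence (ABDC, BCAD, CDBA, DACB)
crossover in which each subject uses one of four e-liquids per day and
provides two trapping collections: collection 1 for nicotine, propylene
glycol, glycerin and menthol, collection 2 for formaldehyde, acetaldehyde
and acrolein. One record is produced per subject, period and analyte, with
a sham (empty cartridge, dead battery) and a product measurement.

The measurement model is multiplicative. For subject $s$, analyte $a$ and
product $p$,

$$ y_{sap} = (\mu_{ap} + b_a)\, u_{sa}\, \varepsilon,\qquad
   \mathrm{sham}_{sa} = b_a\, u_{sa}\, \varepsilon', $$

where $u_{sa}$ is a lognormal subject effect shared across that subject's
sessions (CV `cv_between`), $\varepsilon,\varepsilon'$ are lognormal
residuals (CV `cv_within`), $\mu_{ap}$ is the true per-product exhaled mass
per 10 puffs, and $b_a$ is the endogenous breath background. Both draws are
mean-preserving, so with both CVs at zero the product value equals
$\mu_{ap}+b_a$ exactly. Lognormal noise keeps masses positive and
reproduces the right-skewed, outlier-prone distributions seen in real
exhaled-breath data. Values below the analyte's minimum detectable level
(MDL) are replaced by the MDL and flagged (`apply_mdl_censoring()`), in
both arms. E-liquid consumption per session is a normal truncated at zero
with per-product, per-collection means and SDs (defaults: means
33.7–41.2 mg).

Choices worth noting:

* **Default true means** are the published LS means for the four detected
  analytes; menthol is zero for non-mentholated products, and the two
  carbonyls acetaldehyde/acrolein are zero everywhere, so after censoring
  they are below-MDL in every sample — the pattern the downstream
  below-MDL handling must reproduce.
* **Backgrounds** default to zero except formaldehyde (0.30 µg), whose
  endogenous breath level is comparable to the product signal. With a
  nonzero shared background the covariate-adjusted LS mean includes a
  residual background component, so parameter-recovery checks are run
  under zero-background conditions where the generating truth is
  unambiguous.
* **MDLs are not published.** The defaults (nicotine 1, propylene glycol
  20, glycerin 50, menthol 2, formaldehyde 0.15, carbonyls 0.5 µg) were
  chosen once so that default-parameter censoring rates land near the
  reported ones: menthol ≈ 50% (every non-mentholated session) and
  formaldehyde ≈ 17%.
* **Default CVs** (between 0.8, within 0.9) match the width of the
  published nicotine confidence interval (total CV ≈ 1.2 at $n=32$);
  recovery simulations use moderate CVs (0.35/0.25) where normal-theory
  intervals are well calibrated.
* **Sex is not modeled**: randomization was stratified by sex in the
  emulated design, but sex enters none of the downstream statistics.

What the generator does *not* emulate: assay-level measurement error
structure, correlation between analytes beyond the shared subject effect,
period-by-product interactions, or ad-libitum use behavior. Passing tests
therefore demonstrate the pipeline's statistical machinery, not the
biology of any particular product.

## The sham-corrected ANCOVA

For each analyte the model is

$$ y = \mu + \text{sequence} + \text{period} + \text{product}
     + \beta\,\text{sham} + \text{subject(sequence)} + \varepsilon, $$

fitted by REML (`lmer`) on the MDL-substituted values. LS means are
marginal means balanced over sequence and period and evaluated at the mean
sham value — the standard covariate-adjustment convention; the evaluation
point matters only when $\beta \neq 0$. Confidence intervals and the test
of "sham-corrected mean ≠ 0" use Satterthwaite degrees of freedom. Because
the published analysis did not state its degrees-of-freedom method, exact
CI widths are treated as property-tested (coverage ≈ 95% under the
generator) rather than value-matched.

When the residual variance degenerates (noise-free data) or the mixed fit
fails, the implementation falls back to a fixed-effects fit without the
subject term; a constant sham covariate is dropped. The fallback
reproduces the degenerate-case contract: with zero noise and equal true
means every LS mean equals the truth exactly and the nonzero-mean test has
p ≈ 0.

Emission factors divide the LS mean (µg per 10 puffs) by the reference
e-liquid consumption for that collection (40 mg for collection 1, 41 mg
for collection 2 — the rounded product-C session means). Reported values
use the table convention — two decimals at ≥ 0.1 µg/mg, two significant
figures below — while full precision is retained for modeling. Analytes
censored in *all* sham and product samples are mapped to factor exactly 0
with status `BELOW_MDL`; the alternative MDL-based upper bound is exposed
as `below_mdl_policy = "mdl_upper_bound"` but is not the default, because
an MDL-substituted "signal" would be an artifact of the censoring rule.

## The well-mixed indoor-air model

A single-box mass balance governs each constituent:

$$ V \frac{dC}{dt} = S(t) - \lambda V C, $$

with volume $V$ (m³), air-change rate $\lambda$ (1/h) and source $S$
(µg/h). Concentration is spatially uniform at every instant; the model is
appropriate when ventilation mixes the space on a time scale much shorter
than the exposure duration. Sources are continuous (constant rate) or
puff-resolved (a train of discrete releases); in both modes the
time-integral equals the total emitted mass.

Numerics: the source is discretised as piecewise-constant on the output
grid (a puff's mass is released uniformly across the step containing it)
and each step is advanced with the exact exponential solution, so grid
values are exact for the discretised source and the only approximation is
the in-step placement of puffs. The default grid spacing is
`duration/1000`; a spacing coarser than `duration/100`, or coarser than
the smallest inter-puff gap, is rejected. Time averages use trapezoidal
integration on the grid (`average_concentration()`), and
`mass_balance_residual()` audits
$M = V\Delta C + \lambda V \int C\,dt$, closing to well under 0.1% at the
default spacing.

Vapor/particle partitioning is single-component equilibrium against the
saturation mass concentration $C^*$: vapor $=\min(C, C^*)$, particle
$=C-C^*$ above saturation. Equilibration of submicron droplets is
sub-millisecond, so partitioning is applied instantaneously at each grid
point. The default registry treats all EVP constituents as fully volatile
(no $C^*$), consistent with their high volatility relative to smoke
particles; a finite $C^*$ can be supplied per constituent for sensitivity
studies. Multicomponent (Raoult/activity) coupling and particle-specific
loss processes such as surface deposition are out of scope — no published
parameters exist for them in this context, and the linearity of the
published intake tables across constituents is consistent with a single
common first-order loss.

## Scenarios, intake and benchmarks

A scenario is a space (volume), a ventilation rate, a duration and a
source population. EVP users emit
`n_users × (daily consumption / hours of use) × emission factor`
(defaults 902 mg/day over 16 h); smokers emit
`n_users × 1 cigarette/h × sidestream emission`. Cigarette sources use
sidestream emissions only — exhaled-mainstream contributions are not
included, a known downward bias for the cigarette comparator. Non-users
and users share the single well-mixed concentration; occupant counts do
not introduce per-person sinks.

Non-user intake over a window is
`average concentration × duration × minute ventilation`, with minute
ventilation 0.36 m³/h (500 mL × 12 breaths/min) and 100% absorption
assumed. The reference scale is the intake accumulated over an 8-h shift
at a constituent's occupational limit concentration: `limit × 2.88 m³`
with the default breathing model. Fold differences (cigarette/EVP) reduce,
under the linear box model, to per-user source-rate ratios and are
independent of the space, ventilation, duration and user count.

**Air-change rates are reconstructions.** Published per-scenario
ventilation rates are not available; the shipped defaults (car closed
25.06/h, car open 52.48/h, meeting room 1.637/h, restaurant 4.881/h) were
obtained once with `calibrate_ach()` — a bracketed monotone root-find that
inverts the transient time-averaged concentration through the same
simulate-and-average path as `run_scenario()` (relative tolerance 1e-6) —
so that each space's nicotine intake matches the published intake table.
They should be read as plausible high-ventilation settings, not
measurements. A target at or above the zero-ventilation average
$ST/(2V)$ is reported as infeasible together with the achievable range.

Statuses are explicit sentinels end to end: `BELOW_MDL` constituents
(acetaldehyde, acrolein under EVP use) carry intake exactly 0, and
constituents without sidestream data (propylene glycol, glycerin) carry
`NA` in cigarette scenarios — never empty cells.

## Worked example

```{r example, eval = FALSE}
sessions <- generate_study(study_design(), generation_params(seed = 1))
factors <- estimate_emission_factors(sessions)          # per-mg factors
car <- default_scenarios("evp")$car_closed
run_scenario(car)                                       # intakes + limits
source_fold_difference(default_constituents()$nicotine) # ~ 23.5
```

The end-to-end `run_pipeline()` wraps these stages and writes
`sessions.csv`, `ancova_estimates.csv`, `emission_factors.csv`,
`intake_table.csv`, `trajectories.csv` and a seed-stamped manifest; reruns
with the same configuration are bit-identical.

## Problem sizes and limitations

Simulations in the test suite use the full 32-subject design with 1000-step
trajectories; parameter-recovery checks use 100 replicate studies at
moderate CVs, sizes at which the mixed-model fits are fast and
normal-theory coverage is stable. Known limitations: no uncertainty
propagation from ANCOVA intervals into intakes (point estimates only); no
three-dimensional air-flow modeling, humidity, temperature, coagulation or
size-resolved aerosol dynamics; censored values handled by MDL
substitution (as in the emulated analysis) rather than likelihood-based
censored regression; and the cigarette comparator omits exhaled
mainstream smoke.
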