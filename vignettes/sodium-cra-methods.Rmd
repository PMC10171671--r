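---
title: "Methods: sodium-reduction comparative risk assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sodium-reduction comparative risk assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its model: the assumptions
behind each stage, the tunable parameters and their defaults, the numerical
choices, what the synthetic-data generator does and does not emulate, and the
known limitations. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The pipeline

The package estimates how many cause-specific cardiovascular (CVD) deaths a
population could avert by lowering sodium intake. Four stages:

1. **Reformulation** (`cap_to_targets()`, `aggregate_profiles()`,
   `daily_sodium()`): cap branded-product sodium densities at category
   benchmark targets, rebuild the aggregate food profiles that recall food
   codes resolve to, and recompute each respondent-day's sodium intake.
2. **Intake scenarios** (`estimate_usual_distribution()`,
   `build_proportional_scenario()`, `build_reformulation_scenario()`):
   summarise recall microdata into per-stratum usual-intake distributions
   (mean, SD) and construct counterfactual distributions, either from the
   reformulated supply or by proportional scaling to a population target.
3. **Comparative risk assessment** (`deaths_averted()`,
   `monte_carlo_ui()`): convert each stratum's intake shift into
   cause-specific deaths averted through the salt → systolic blood pressure
   (SBP) → mortality pathway, with Monte Carlo uncertainty intervals.
4. **Reporting** (`render_summary()`, `run_pipeline()`): render the
   cross-scenario summary and a run manifest.

Strata are sex × the four adult DRI age groups (19–30, 31–50, 51–70, 71+).
Mortality is sex × five-year band (20–24 … 85+) × seven ICD-10 cause groups.
A five-year band maps to the DRI group containing its **midpoint** (open-ended
bands use start + 2.5 y), with nearest-range fallback; the same rule matches
bands to the dose-response entries. The crosswalk is a modelling choice — the
underlying surveys never state one.

All risk computation is in grams of salt per day (salt g = sodium mg × 2.5 /
1000); sodium mg appears only at the I/O boundary.

## 2. Exposure model and potential impact fraction

Each stratum–scenario pair carries a parametric usual-intake distribution.
The default family is **normal, truncated at zero and renormalized**: the
published inputs supply only a mean and SD, and several strata have
coefficients of variation large enough (0.5–1.2) that an untruncated normal
would place visible mass below zero. A lognormal form is available
(`form = "lognormal"`), with one caveat: a log-linear RR has no finite
expectation against a full lognormal tail (the lognormal
moment-generating function diverges), so the lognormal expectation clips the
integral at the 1 − 10⁻⁶ quantile and renormalizes. This excludes negligible
mass at realistic intakes but makes the integral well-defined.

Risk is log-linear in SBP, parameterized per 20 mmHg, and SBP is linear in
salt with an age-specific slope β, so the per-cell tilt coefficient is
k = ln(RR₂₀)/20 · β and

$$\mathrm{PIF} \;=\; 1 - \frac{E_{cf}\!\left[e^{kX}\right]}{E_{b}\!\left[e^{kX}\right]},$$

independent of the RR curve's reference intake (which cancels; a test checks
invariance to 10⁻¹⁰). For a truncated normal the expectation has the closed
form

$$E\!\left[e^{kX}\right] = e^{k\mu + k^2\sigma^2/2}\,
  \frac{\Phi(\mu/\sigma + k\sigma)}{\Phi(\mu/\sigma)},$$

which the engine uses by default (`method = "analytic"`); adaptive quadrature
(`stats::integrate`, relative tolerance 10⁻¹², log-scale integrand to avoid
tail underflow) is the generic path and the two agree to ~10⁻¹⁰ in tests.
`sd = 0` is treated as a point mass. Deaths averted are `deaths × PIF` per
cell; counterfactual deaths are carried per cell so baseline − averted =
counterfactual holds exactly.

The engine integrates over the full intake distribution rather than applying
only the mean shift. The distinction matters: scenario definitions that
shrink the SD as well as the mean (reformulation compresses the intake
distribution) yield a larger PIF under distribution-aware integration. A
`mean_shift_only` switch reruns any analysis with the counterfactual SD tied
to the baseline SD, as a sensitivity for comparison with engines that only
shift means.

## 3. Epidemiological parameters

β (mmHg SBP per g/day salt) and RR₂₀ (relative risk per 20 mmHg usual SBP,
by ICD-10 cause group and age range) are **not hard-coded**. They live in a
versioned YAML file — bundled default
`inst/extdata/default_parameters.yaml` — in which every entry carries a
provenance string naming the meta-analytic source it was transcribed from
(the salt/BP dose-response literature for β, with the response increasing
with age from 0.55 to 1.25 mmHg per g salt; prospective-cohort
per-20-mmHg hazard ratios for the vascular causes, attenuating with age;
weaker, conservative associations for pulmonary embolism and rheumatic heart
disease; the steepest gradient for deaths coded to hypertensive disease
itself). Loading validates coverage (all seven causes), β ≥ 0, RR₂₀ ≥ 1, and
no duplicate entries; files round-trip bit-identically through
`write_parameters()`/`load_parameters()`. Log-scale standard errors are
derived from the 95% CIs as (ln U − ln L)/(2·1.96).

Monte Carlo correlation structure: per iteration, **one** β draw per age
range and **one** ln RR₂₀ draw per (cause, age-range) entry, shared across
sexes and across the five-year bands that resolve to the same entry.
Negative β draws are truncated at zero. This treats parameter uncertainty as
systematic across the population — the plausible behaviour for shared
meta-analytic parameters — rather than independent noise per cell, and it
widens the intervals relative to cell-independent draws. Uncertainty
intervals are the 2.5th/97.5th percentiles of the iteration totals; the point
estimate is computed at the parameter means, so zero SEs collapse the
interval onto it exactly.

## 4. Scenario construction

**Reformulation (scenario A).** Products with a category target above their
density are capped *to* the target (`min(density, target)`); uncategorized
products and categories without published targets pass through (the 2016
benchmark list did not cover all foods). Capping is idempotent and never
increases a density, so per-respondent scenario intakes are bounded above by
baseline intakes. Aggregate profiles take the **unweighted** arithmetic mean
of their matched products — sales-weighting is out of scope — and unmatched
profiles keep their generic densities. Aggregation is per recall food code
(profile), the granularity at which recall items resolve.

**Proportional scaling (scenarios B/C).** One ratio r = target / population
baseline mean scales every stratum mean, and SDs scale by the same factor so
each stratum's coefficient of variation is preserved exactly — consequently
the weighted population mean hits the target exactly, for any weight vector.
When mimicking the published national analysis the anchor is the all-ages
population mean (2,758 mg/d), which includes age groups outside the adult
table; that choice reproduces the published counterfactual means to within
1 mg at the printed integer precision (printed tables round their inputs, so
exact agreement to the last mg is not attainable, and comparisons allow
±1 mg slack). A target at or above the anchor triggers a warning and clamps
r to 1. By default, if no anchor is given, the anchor is the weighted mean
of the stratum means provided.

**DRI cut-point statistics.** Survey-weighted proportions with usual intake
≤ AI (1,500 mg/d; "at or below" is inclusive) and strictly > CDRR
(2,300 mg/d), per stratum; both cut-points are configurable.

**Misreporting.** Reported energy / estimated energy requirement ≤ 0.70 →
under-reporter (the boundary itself counts as under); > 1.42 → over-reporter;
otherwise plausible. The EER is accepted as an input column; predicting it
from anthropometry is out of scope.

## 5. Usual-intake estimation: a moment-based stand-in

Full usual-intake methodology (Box–Cox two-part nonlinear mixed models with
recall-sequence, weekday and misreporting covariates) is deliberately out of
scope. The package uses a documented moment-based decomposition: the stratum
mean is the survey-weighted mean of person-level recall means, and

$$\hat\sigma_b^2 = \max\!\big(\widehat{\mathrm{Var}}(\bar y_i)
  - \hat\sigma_w^2 / \bar d,\ \text{floor}\big),$$

with the within-person variance estimated as half the mean squared
day-1/day-2 difference among repeat respondents and \(\bar d\) the mean
number of recall days. The floor (`sd_floor`, default 1 mg/d) guards strata
where the decomposition goes non-positive; strata with no repeat respondents
fall back to the total person-mean SD with a warning; a one-person stratum is
an error. With a mixed 1/2-day design the estimator carries a small positive
bias of order \(\sigma_w^2(E[1/d] - 1/\bar d)\), well under the 10% recovery
tolerance the tests use. What the stand-in does *not* do: shrink individual
intakes, model consumption-day probability, or adjust for covariates — so
percentile-level statements inherit the parametric form rather than an
NCI-style estimated distribution.

## 6. What the synthetic generator emulates — and what it does not

`synthetic_config()` defaults are the study-like conditions:

* eight adult strata with sampling shares and true usual-intake means/SDs
  taken from the bundled published baseline column;
* one 24-h recall per respondent, a second day for 35%;
* within-person day-to-day variation as mean-one lognormal noise with CV
  0.4 — repeat-recall surveys show within-person variance comparable to or
  larger than between-person variance for sodium, but no single published
  value exists for this design, so the CV is a fixed realistic choice;
* person-level usual intakes drawn **lognormal** matched to the stratum
  mean/SD. A zero-truncated normal would inflate realized stratum means by
  several percent at the published CVs, so the generator uses the
  positive-support family that matches its targets exactly (the CRA engine's
  default exposure family is unaffected);
* a branded supply of 1,000 products in 40 categories, category targets
  uniform on 200–800 mg/100 g, a configurable fraction (default 0.5) of
  categorized products above target, 10% uncategorized; recall items are
  priced at the supply's aggregate profile densities and partitioned so they
  re-sum to each day's intake exactly;
* mortality with a log-linear age gradient of 0.075 per year of age
  (deaths multiply by ≈1.45 per five-year band, placing roughly 70% of CVD
  deaths at 75+, consistent with national vital statistics), an open-band
  factor of 2 for 85+, per-sex cause shares dominated by ischaemic heart
  disease, and sex totals 30,663 male / 27,813 female (the 2019 Canadian
  all-CVD totals), hit exactly by largest-remainder rounding.

The generator covers **adults only** by default. Child strata could be
supplied through the `strata` argument, but every downstream consumer in the
package (the scenario builders and the mortality pathway) is adults-only, so
the default stratum table stops at 19+.

Not emulated: the survey's cluster/stratum sampling design and bootstrap
replicate weights (person-level weights only), day-of-week and recall-mode
effects, item-level food co-occurrence structure, and correlation between
energy and sodium misreporting. Passing tests therefore demonstrate that the
pipeline's estimators recover the parameters of *this* data-generating
process — not that they would be unbiased under the full complexity of real
recall surveys.

## 7. Numerical and reporting conventions

* Quadrature: `stats::integrate` with rel.tol 10⁻¹², log-scale integrands.
* Truncated-normal expectations: closed form with `pnorm`; point masses
  (`sd = 0`) short-circuit to `exp(kμ)`.
* Mortality scaling uses largest-remainder rounding so sex totals are met
  exactly by integer death counts.
* Printed percentages round half-up to one decimal (`round_half_up()`), the
  convention of the published summary tables.
* Totals are the sum over the seven mutually exclusive ICD-10 cause groups.
  Published PRIME outputs note their totals fall slightly below the
  per-cause sum ("double counting" adjustments); the mechanism is not
  published, so this package reports the exclusive sum and the per-cause
  rows without adjustment.
* Reference-year deaths for percentage columns default to the input
  mortality table's own total.
* The pipeline's run manifest records seed, iteration count, parameter-file
  hash and input-file hashes (MD5).

## 8. Problem sizes and test design

The test suite exercises: parameter recovery on a two-day, single-stratum
design at n = 2,000 (between-SD within 10%) and a mixed-design survey at
n = 2,000–5,000 (stratum means within 2 estimated SEs); Monte Carlo
contracts at 10,000 iterations (seed determinism, interval collapse under
zero uncertainty, cross-seed stability of interval bounds within 2%);
property checks (PIF reference-invariance, conservation, capping
idempotence, CV preservation, exact population-target attainment) on
desk-scale fixtures; and the full synthetic pipeline end to end at a few
hundred respondents. These sizes are the package's own choices: large enough
for the stated tolerances, small enough to run a full check in well under a
minute per file.

## 9. Known limitations

* Static, lag-free accounting: "averted or delayed" deaths in the reference
  year, not life-years or a time course.
* Mortality only — no morbidity, DALYs, or non-CVD outcomes (chronic kidney
  disease and gastric cancer are plausibly sodium-related but outside the
  modelled pathway).
* Log-linear RR extrapolation with no floor or threshold in salt intake; any
  true threshold behaviour would make large-shift estimates optimistic.
* The distribution-aware PIF rewards variance contraction. Scenario
  definitions whose counterfactual SDs shrink sharply relative to baseline
  produce materially larger totals than mean-shift-only engines; use
  `mean_shift_only = TRUE` to bound the sensitivity.
* The β/RR parameter defaults are transcriptions from the cited literature
  with simplified age structure; analyses needing exact replication of any
  specific tool should supply that tool's parameter file.
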