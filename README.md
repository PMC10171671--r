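# sodiumcra

Comparative risk assessment of population sodium-reduction scenarios.

Excess dietary sodium raises systolic blood pressure (SBP), and raised SBP is
the dominant metabolic risk factor for cardiovascular disease (CVD) mortality.
`sodiumcra` is an R package for quantifying how many cause-specific CVD deaths
a population could avert by lowering its sodium intake — either by
*reformulating* the packaged food supply (capping each product's sodium
density at its category's benchmark target and re-deriving intakes from
24-hour dietary recall microdata) or by *proportionally scaling* every
age/sex stratum's usual-intake distribution down to a population target such
as 2,300, 2,000 (WHO) or 1,500 mg/day (Adequate Intake). It is aimed at
nutrition epidemiologists and public-health modellers who need a tested,
reproducible alternative to spreadsheet-based macrosimulation.

## The model

The engine is a PRIME-style comparative risk assessment over the pathway
salt → SBP → cause-specific CVD mortality, stratified by sex, five-year age
band and seven ICD-10 cause groups (I20-25, I60-69, I50, I71, I26, I05-09,
I10-15):

* Intakes are converted as salt (g/d) = sodium (mg/d) × 2.5 / 1000; all
  internal computation is in grams of salt.
* The salt→SBP link is linear with an age-specific slope β (mmHg per g/d of
  salt): ΔSBP = β·Δx.
* Relative risk is log-linear in SBP, parameterized per 20 mmHg:
  RR(x) = exp( ln(RR₂₀)/20 · β · (x − x_ref) ).
* For each mortality cell, the potential impact fraction of a shift from the
  baseline usual-intake distribution F_b to a counterfactual F_cf is

      PIF = 1 − E_cf[RR(X)] / E_b[RR(X)],

  with expectations over zero-truncated normal intake distributions
  (closed-form or adaptive quadrature; lognormal optional), and
  deaths averted = deaths × PIF.
* 95% uncertainty intervals come from 10,000 Monte Carlo iterations drawing
  β ~ Normal(β, SE) (truncated at 0) and ln RR₂₀ ~ Normal(ln RR₂₀, SE), one
  draw per parameter entry per iteration, shared across sexes.

β and RR₂₀ values are not hard-coded: they live in a versioned YAML parameter
file (`inst/extdata/default_parameters.yaml`) whose entries carry provenance
strings pointing at the meta-analytic literature they were transcribed from.

A synthetic-data module generates every input the pipeline needs — branded
food supply with benchmark targets, linked recall microdata with repeat days
and survey weights, and sex × age-band × cause mortality tables — so the full
pipeline runs end to end with no access to restricted survey data.

## Worked example

Estimate deaths averted had Canadian adults met the WHO sodium recommendation
(2,000 mg/d), using the bundled published intake summaries and a synthetic
2019-like mortality table:

```r
library(sodiumcra)

tab       <- baseline_intake_table()                       # published intake summaries
mortality <- generate_demography(synthetic_config(seed = 1))
params    <- load_parameters()
params
#> <rr_parameter_set> version 1 - 4 SBP slope entries, 35 RR-per-20-mmHg entries across 7 cause groups

shifts <- scenario_shift_table(tab, "b")                   # baseline -> 2000 mg/d
res    <- monte_carlo_ui(mortality, shifts, params, iterations = 10000, seed = 1)
res
#> <scenario_result> 3640 deaths averted (95% UI 2181-5125; 10000 iterations)

render_summary(list(B = res))
#> # A tibble: 3 × 6
#>   scenario sex    deaths_averted ui_lo ui_hi pct_of_reference
#>   <chr>    <fct>           <dbl> <dbl> <dbl>            <dbl>
#> 1 B        male            2067. 1246. 2901.              3.5
#> 2 B        female          1574.  934. 2220.              2.7
#> 3 B        total           3640. 2181. 5125.              6.2
```

Reading the output: meeting the WHO target would avert or delay about 3,640
of the 58,476 reference-year CVD deaths (6.2%), with the uncertainty interval
reflecting the spread of the epidemiological parameters, not sampling noise.
About 57% of the averted deaths are in men, mainly from ischaemic heart
disease, stroke and hypertensive disease.

The full synthetic pipeline — generate data, reformulate the food supply,
rebuild intake scenarios, estimate impacts, render the summary, write a run
manifest — is one call:

```r
run_pipeline(synthetic_config(seed = 1), out_dir = "run1")
```

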