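# pecost

A decision-analytic cost model for triaging suspected preeclampsia with
the sFlt-1/PlGF ratio test, from the perspective of the Japanese
healthcare payer.

Women who present with suspected preeclampsia are, under standard
practice, admitted on clinical judgment alone; most never develop the
condition in the short term, so many admissions are avoidable. The serum
sFlt-1/PlGF ratio at a cutoff of 38 rules preeclampsia out within one
week with an NPV of 98.6% (95.1% within four weeks) and rules it in with
a PPV of 30.3% within four weeks. `pecost` quantifies what ratio-guided
admission is worth: per-patient cost saving and whole-population budget
impact, for health-economics analysts and HTA groups evaluating the
test.

## The model

Two decision trees are evaluated as expectations over a model cohort of
`n = 31,000` women with suspected preeclampsia:

* **no-test**: a fraction `p0 = 26/180 ≈ 14.4%` (the observed
  standard-care rate in the 180-woman Japanese analysis cohort) is
  admitted before preeclampsia onset;
* **test**: women split at the cutoff into a low-risk stratum
  (`s_L = 143/180 ≈ 79.4%`, admitted with probability `p_L = 0.56%`) and
  a high-risk stratum (`s_H = 37/180`, admitted with probability
  `p_H = 40%`), giving an overall admission rate
  `s_L·p_L + s_H·p_H ≈ 8.7%`.

Each arm accrues outpatient care (57,053 JPY, every woman), the test
(9,000 JPY, test scenario only), the 4-day pre-onset admission at
87,300 JPY/day plus a 1,752 JPY corticosteroid course, the birth episode
(13.6 / 9.3 days with / without preeclampsia; identical across scenarios,
cancels in savings), and NICU care for neonatal respiratory distress
syndrome: a 12% RDS risk in neonates of admitted mothers, reduced by 20%
under ratio-guided management, at 101,302 JPY per NICU day. The one
unpublished parameter — the NICU length of stay — is recovered in closed
form by `calibrate_nicu_days()`, because the saving is affine in it.

A patient-level cohort simulator (`simulate_cohort()`) realizes the same
tree stochastically and serves as a Monte Carlo oracle for the analytic
expectations; `run_sensitivity()` reruns the model over the published
one-way scenarios or arbitrary parameter overrides.

## Worked example

```r
library(pecost)

pars <- pe_parameters()                       # published defaults
pars <- set_nicu_days(pars, calibrate_nicu_days(pars))
pars$stays$nicu_days
#> [1] 14.51464

per_patient_saving(pars)
#> Introduction of the sFlt-1/PlGF ratio test
#>   per-patient saving: 16,373 JPY
#>   budget impact (n = 31,000): 507,560,536 JPY
#>   component deltas (no-test minus test, cohort JPY):
#>     outpatient                               0
#>     testing                       -279,000,000
#>     pre_onset_hospitalization      625,407,888
#>     corticosteroid                   3,137,785
#>     birth_hospitalization                    0
#>     nicu                           158,014,863
```

Reading the output: introducing the test costs 279M JPY in assays but
avoids 625M JPY of pre-onset hospitalization (the admission rate falls
from 14.4% to 8.7%), 3.1M JPY of corticosteroids, and 158M JPY of NICU
care (537.17 → 429.73 RDS admissions), netting 16,373 JPY saved per
woman — 507.6M JPY across the 31,000-woman population. The calibrated
NICU stay, 14.5 days, is a plausible RDS admission length.

One-way sensitivity over the published scenario set:

```r
run_sensitivity(builtin_scenarios(), pars)
#> One-way sensitivity analysis (per-patient saving, JPY)
#>               scenario no_test_rate_pct test_cost_jpy retest low_rate_pct high_rate_pct saving_jpy
#>              base_case             14.4          9000  FALSE         0.56            40      16373
#>   no_test_rate_26.9pct             26.9          9000  FALSE         0.56            40      64481
#>  test_cost_minus_20pct             14.4          7200  FALSE         0.56            40      18173
#>   test_cost_plus_20pct             14.4         10800  FALSE         0.56            40      14573
#>     retest_every_woman             14.4          9000   TRUE         0.56            40       7373
#>        p_hosp_low_4pct             14.4          9000  FALSE         4.00            40       6782
#>        p_hosp_low_0pct             14.4          9000  FALSE         0.00            40      17934
#>      p_hosp_high_50pct             14.4          9000  FALSE         0.56            50       9159
#> scenarios flagged approximate: no_test_rate_26.9pct
```

The saving stays positive in every scenario, including charging the test
twice per woman. The 26.9% row is flagged `approximate`: its published
value is not recoverable from the model structure (see the methods
vignette, `vignettes/cost-model.Rmd`).

File-based runs go through the command functions or the thin CLI
wrapper:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","pecost.R",package="pecost"))')" \
  base-case --out-dir out/
```

which writes `base_case_breakdown.csv`, `base_case_saving.json` and a
run manifest; `sensitivity`, `simulate` and `calibrate` subcommands
work the same way from a JSON configuration
(`inst/extdata/default_config.json` is the packaged base case).

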