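# ponatdm

Therapeutic drug monitoring (TDM) and dose decision support for ponatinib in
chronic myeloid leukemia (CML).

Ponatinib is effective after failure of earlier BCR-ABL1 inhibitors, but its
vascular toxicity is dose-dependent, so clinicians want the lowest dose whose
steady-state trough concentration (C_min) still clears the relevant efficacy
threshold: 10 nM (5.3 ng/mL, minimal efficacy), 20 nM (10.7 ng/mL,
efficacious in BCR-ABL1-unmutated disease) or 40 nM (21.3 ng/mL, suppression
of newly mutated clones). Clinic samples are drawn at a random — but
recorded — time after the morning dose, not at trough. This package is for
clinical pharmacologists and hematology study teams who need to turn such
sparse random-time measurements into trough estimates and transparent dose
recommendations.

What it provides:

* **PK forward model** — two-compartment disposition, transit-compartment
  absorption, first-order elimination; solved exactly via the matrix
  exponential (`simulate_pk()`, `steady_state_cmin()`, `concentration_at()`).
* **Empirical-Bayes trough prediction** — MAP estimation of individual
  parameters θ·exp(η), η ~ N(0, Ω), from sparse samples under a combined
  residual-error model, minimizing
  −2[Σ log N(y; f, (σ_add + σ_prop f)²) + log N(η; 0, Ω)]
  (`map_estimate()`, `predict_cmin_from_single_sample()`).
* **Exact statistics** — two-sided Fisher (point-probability convention) and
  its Freeman–Halton r×c generalization, implemented from first principles
  with enumeration guards; Pearson chi-squared; standard rank tests
  (`fisher_exact_two_sided()`, `freeman_halton_exact()`, `pearson_chi2()`,
  `compare_continuous_groups()`).
* **Classification** — molar/mass threshold conversion and banding of
  troughs and of BCR-ABL1/ABL1 IS% molecular response (MR2/MR3/DMR)
  (`classify_cmin()`, `classify_molecular_response()`).
* **Dose rule engine** — cardiovascular-risk-stratified starting doses and
  on-treatment adjustments with auditable rationale traces
  (`recommend_starting_dose()`, `recommend_adjustment()`).
* **Synthetic cohort generator** — stochastic cohorts with the study design's
  structure, plus a deterministic 38-row counts-matched fixture
  (`generate_cohort()`, `counts_matched_fixture()`).
* **Analysis pipeline** — attainment and response cross-tabulations with
  exact tests and structured JSON/markdown reports (`run_report()`).

## Worked example

Predict a steady-state trough from one random-time sample, classify it, and
get a dose recommendation:

```r
library(ponatdm)

prior <- population_prior()          # synthetic population defaults
s <- concentration_samples(t_since_dose_h = 6, conc_ng_ml = 45,
                           dose_mg = 30)
cmin <- predict_cmin_from_single_sample(s, prior)
cmin
#> [1] 17.50423
as.character(classify_cmin(cmin))
#> [1] "UNMUTATED_EFFICACIOUS"

recommend_adjustment(patient_state(
  cv_risk = "high", current_mr = "MR3", months_on_current_dose = 7,
  current_dose_mg = 30, cmin_ng_per_ml = cmin))
#> Recommendation: reduce_to_15 (strict molecular monitoring)
#>   rationale: dose_30 -> mr_at_least_mr3 -> cmin_above_threshold -> six_months_on_30_with_mr3_and_level
```

A 45 ng/mL concentration six hours post-dose implies a ~17.5 ng/mL predicted
trough — efficacious for unmutated BCR-ABL1 (above 10.7 ng/mL) though below
the 21.3 ng/mL mutation-suppression threshold — and a high-risk patient with
MR3 after 6+ months at 30 mg/day with a trough above 10.7 ng/mL is stepped
down to 15 mg/day under strict molecular monitoring.

Run the cohort pipeline on the counts-matched fixture:

```r
report <- run_report(counts_matched_fixture())
report$pooled_attainment[["10.7"]][c("numerator", "denominator", "percent")]
#> $numerator
#> [1] 27
#> $denominator
#> [1] 38
#> $percent
#> [1] 71.1
round(report$mr_by_threshold[["10.7"]][["MR3"]]$p, 3)
#> [1] 0.268
```

27/38 dose-occasions (71.1%) attain the 10.7 ng/mL threshold, and MR3
attainment does not differ significantly across that threshold (two-sided
Fisher p = 0.268).

## Not in scope

Population (SAEM/FOCE) estimation of PK parameters; computation of
SCORE2/SCORE2-OP cardiovascular risk (the risk category is an input); assay
processing and IS standardization of raw PCR data; any claim of certified
clinical decision support.
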