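# amlrisk

Risk stratification of acute myeloid leukemia (AML) patients on a
six-parameter prognostic scale built around the ex vivo chemosensitivity of
their tumor cells, plus the complete statistical battery needed to evaluate
such a scale against therapy response and overall survival.

Standard AML risk stratification leans on cytogenetic and molecular
markers, but primary resistance of leukemic blasts to the induction drugs —
the multidrug-resistance (MDR) phenotype, marked by *MDR1*/P-glycoprotein
expression — is a major cause of induction failure that those markers see
only indirectly. The scale implemented here scores six parameters at 0–2
points each:

| Parameter | 0 | 1 | 2 |
|---|---|---|---|
| Tumor cell drug sensitivity (IC50 category, averaged over drugs) | high | moderate | low |
| *MDR1* mRNA expression | weak | moderate | strong |
| Tumor origin | primary | — | secondary |
| Unfavorable cytogenetic mutations | 0 | 1 | > 1 |
| Age | < 40 y | 40–60 y | > 60 y |
| Aberrant immunophenotype markers | 0 | 1 | > 1 |

Total score 0–12; risk groups: **0–2 low, 3–5 intermediate, 6–12 high**.
Sensitivity categories come from IC50 breakpoints (daunorubicin 0.25 / 0.5
μM, cytarabine 1.5 / 8 μM); IC50s right-censored at the top tested dose
are low-sensitivity by convention.

The package covers the whole path from raw assays to evaluation:

- **Assay quantification** — WST-1 dual-wavelength viability curves,
  two-parameter log-logistic IC50 fits with interpolation fallback and
  right-censoring (`compute_viability()`, `estimate_ic50()`), and ΔΔCt
  relative *MDR1* expression (`relative_expression()`,
  `categorize_expression()`).
- **Scoring** — `classify_drug_sensitivity()`, `sensitivity_subscore()`,
  `score_patient()`, `assign_risk_group()`, `score_cohort()`, with
  explicit policies for fractional subscores and missing parameters.
- **Evaluation** — Spearman correlation matrices with strength bands and
  exact small-sample p-values (`spearman_cor()`, `correlation_matrix()`),
  Kaplan–Meier and log-rank (`km_estimate()`, `log_rank()`), ROC with
  Hanley–McNeil SE and Youden cutoff (`roc_analysis()`), univariate and
  multivariate Cox regression (`cox_univariate()`, `cox_multivariate()`),
  and therapy-response classification (`classify_therapy_response()`).
- **Synthetic cohorts** — `generate_cohort()` draws fully reproducible
  cohorts with a latent resistance burden inducing the correlation
  structure the analysis assumes, an ordinal response model on the true
  score and proportional-hazards survival, so every stage is testable
  without patient data. `generate_plate()` produces raw plate fixtures.
- **Pipeline** — `run_pipeline()` orchestrates simulate/load → score →
  evaluate per treatment arm and writes a reproducible report bundle; a
  thin CLI lives at `inst/cli/amlrisk.R`
  (`simulate | quantify | score | evaluate | run`).

## Worked example

```r
library(amlrisk)

# one patient
rec <- list(age_years = 50, origin = "primary", n_unfavorable_mutations = 1,
            mdr1_category = "moderate", n_aberrant_markers = 1,
            ic50_daunorubicin = 0.4, ic50_cytarabine = 4)
score_patient(rec)
#> Prognostic scale score: total 5 (intermediate risk)
#>   sensitivity 1 | MDR1 1 | origin 0 | cytogenetics 1 | age 1 | immunophenotype 1
```

Both drugs are moderately sensitive (1 point after averaging), every other
parameter sits in its middle band: total 5, the top of the intermediate
risk group.

```r
# a synthetic 53-patient cohort, scored and evaluated
cohort <- generate_cohort(synthetic_config(n_patients = 53, seed = 7))
scored <- score_cohort(cohort)
table(scored$risk_group)
#>          low intermediate         high
#>            6           22           25

log_rank(scored$os_days, scored$death_event, droplevels(scored$risk_group))
#> Log-rank test: chi-square = 11.304, df = 2, p = 0.003511 (n = 53)

roc_analysis(scored$total_score, scored$therapy_response != "remission")
#> ROC analysis: AUC = 0.850 +/- 0.052 (95% CI 0.748-0.952), p = 1.44e-11 [very good]
#>   Youden cutoff 5: sensitivity 81.8%, specificity 85.0% (J = 0.668); model valid

cox_univariate(scored, "risk_group")
#> Cox proportional-hazards fit: n = 53, events = 51
#>   risk_group                   HR 2.14 (95% CI 1.34-3.42), p = 0.00143
#>   model likelihood-ratio p = 0.000733
```

The generated cohort separates by risk group (log-rank p ≈ 0.004), the
scale discriminates responders from non-responders (AUC 0.85, "very good"
band, Youden cutoff at 5 points), and each risk-group step roughly doubles
the death hazard — the structure the generator is built to emulate.

```r
# raw assays
est <- estimate_ic50(compute_viability(
  generate_plate("daunorubicin", ic50_true = 0.4, hill = 1,
                 noise_sd = 0.02, seed = 3)))
est
#> IC50: 0.412 uM (loglogistic_fit)
#>   hill = 1.02, rss = 0.000206

relative_expression(c(25, 25.2, 24.8), c(20, 20, 20),
                    c(27, 27, 27), c(20, 20, 20), thresholds = c(2, 10))
#> ddCt = -2, fold = 2^-ddCt = 4
#> category: moderate
```

End-to-end, with a report bundle on disk:

```r
run_pipeline(pipeline_config(synthetic = synthetic_config(),
                             out_dir = "report", seed = 1))
```

writes `scored_cohort.csv`, per-arm `correlations_*.csv`,
`km_summary.csv`, `roc_results.json`, `cox_results.json`, `run.log` and a
`manifest.json` sufficient to regenerate the bundle byte-identically.

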