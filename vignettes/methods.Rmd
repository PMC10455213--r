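---
title: "Methods: a chemosensitivity-based prognostic scale for AML and its evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a chemosensitivity-based prognostic scale for AML and its evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amlrisk)
```

## The problem and the model

Risk stratification of newly diagnosed acute myeloid leukemia (AML) is
dominated by cytogenetic and molecular markers, yet primary chemoresistance
of the leukemic blasts — a multidrug-resistance (MDR) phenotype driven in
large part by drug-efflux transporters such as P-glycoprotein, the product
of the *MDR1* gene — remains a major cause of induction failure that those
markers capture only indirectly. `amlrisk` implements a six-parameter
additive prognostic scale that injects direct ex vivo measurements of tumor
cell drug responsiveness into risk stratification, together with the full
statistical battery used to evaluate such a scale against therapy response
and overall survival.

Each parameter contributes 0–2 points:

| Parameter | 0 | 1 | 2 |
|---|---|---|---|
| Sensitivity to chemotherapeutic drugs* | high | moderate | low |
| *MDR1* mRNA expression | weak | moderate | strong |
| Tumor origin | primary | — | secondary |
| Unfavorable cytogenetic mutations | none | one | more than one |
| Age | < 40 y | 40–60 y | > 60 y |
| Aberrant immunophenotype markers | none | one | more than one |

\* per-drug categories are mapped to points and averaged over the assayed
drugs, so the sensitivity parameter contributes at most 2 regardless of how
many drugs were tested.

The total lies in 0–12 and maps to three risk groups: 0–2 low, 3–5
intermediate, 6–12 high.

Drug-sensitivity categories come from IC50 breakpoints (μM): daunorubicin
high ≤ 0.25, moderate ≤ 0.5, low above; cytarabine high ≤ 1.5, moderate
≤ 8, low above. The printed breakpoint intervals overlap at their ends, so
the package resolves boundary values to the *more sensitive* category
(right-closed on the sensitive side); an IC50 exactly at 0.25 μM
daunorubicin is therefore high sensitivity. An IC50 right-censored at the
top tested dose is always low sensitivity.

## Raw-assay quantification

**Viability and IC50.** The WST-1 readout is a paired 450/620 nm
absorbance; the per-well signal is `a450 − a620`, the mean cell-free blank
signal is subtracted, and viability at dose *c* is the ratio of the
blank-corrected treated signal to the blank-corrected zero-dose signal
(zero-dose viability is exactly 1 by construction). The IC50 is estimated
by least squares on the two-parameter log-logistic
$v(c) = 1/(1+(c/\mathrm{IC50})^{h})$ with the upper asymptote fixed at 1
and the lower at 0 — an 8-point dose grid cannot support four free
parameters reliably — optimised over a log-spaced multi-start grid of IC50
candidates crossed with Hill slopes 0.5/1/2 (Nelder–Mead on the log scale,
relative tolerance 1e−12). A fit whose optimum runs more than a decade
outside the tested concentration range is rejected in favour of linear
interpolation of the 50% crossing in log-concentration. When every mean
viability exceeds 0.5 the estimate is right-censored at the maximum tested
dose and recorded as such (`">2"` in CSVs) rather than given an invented
numeric value; downstream it classifies as low sensitivity. The estimator
is scale-equivariant because every internal reference point derives from
the dose grid itself.

**MDR1 expression.** Relative expression follows the ΔΔCt convention:
ΔCt = mean target Ct − mean reference Ct per condition, ΔΔCt =
ΔCt~sample~ − ΔCt~calibrator~, fold = 2^−ΔΔCt^, with GAPDH as the
reference gene. The weak/moderate/strong cut points are *package defaults*
(2- and 10-fold), clearly labelled as configuration: the laboratory
calibration they would come from is not part of this package, and no claim
is made that these reproduce any particular study's thresholds. Category
intervals are right-closed below (a fold of exactly 2 is weak).

## Scoring decisions where the scale is underspecified

*Fractional subscores.* Averaging two drug categories can give 0.5 or 1.5
points while the risk bands are integer. Default: round half-up, keeping
totals on the integer band scale. Alternative (`keep_fraction`): keep the
fraction and band fractional totals at the midpoint cuts 2.5/5.5.

*Missing parameters.* Cytogenetics fail in a material fraction of real
cohorts (the generator defaults to 19%). Neither scoring convention can be
claimed as "the" correct one, so both are provided:
`score_zero_and_flag` (default) scores the missing parameter 0 and records
it in `imputed_parameters`; `exclude_and_rescale` rescales the attainable
total to the full 0–12 range (`total × 12 / attainable max`). The flag is
always recorded, and the pipeline logs every imputed record.

## The evaluation battery

**Spearman correlation.** r is the Pearson correlation of midranks (ties
averaged). The two-sided p-value is exact by full permutation enumeration
for n ≤ 10 complete pairs — study subgroups are small — and the
t-approximation otherwise. Strength bands on |r|: < 0.01 uninformative,
0.01–0.29 weak, 0.30–0.69 moderate, 0.70–1.00 strong; negative
correlations are banded by magnitude with the sign carried by r. Because
the sign of a rank correlation with a categorical variable depends
entirely on how its levels are ordered, all categorical variables enter
through an explicit ordinal coding (`variable_coding()`), ordered
best-to-worst by default and echoed into every report.

**Kaplan–Meier / log-rank.** Product-limit estimation and the unweighted
log-rank test are delegated to the `survival` package behind the module
interface; the median is the first event time with survival ≤ 0.5 and
horizon survival is reported at 180/365/1095 days (6-month, 1-year,
3-year).

**ROC.** The AUC is the tie-corrected rank (Wilcoxon–Mann–Whitney)
statistic; its standard error uses the Hanley–McNeil formula, matching the
"AUC ± SE" presentation convention (DeLong-style variance is deliberately
not the default); the 95% CI is AUC ± 1.96·SE truncated to [0, 1]; the
p-value tests AUC against 0.5 by the normal approximation. The operating
cutoff maximizes the Youden index J = sensitivity + specificity − 1 over
all observed score values, taking the lowest cutoff on ties. Model quality
is banded (0.9–1.0 excellent, 0.8–0.9 very good, 0.7–0.8 good, 0.6–0.7
moderate, 0.5–0.6 bad) and a validity verdict requires p < 0.05, AUC >
0.5 and both sensitivity and specificity above 60%. Outcome
binarization for the two standard ROC questions: therapy response uses
remission vs {relapse, refractory}; overall survival uses death before
last follow-up vs censored alive. Both are package conventions, stated
here because the underlying questions ("achieving or not achieving the
response") admit alternatives.

**Cox regression.** Univariate and multivariate partial-likelihood fits
(Efron tie handling, via `survival::coxph`) with Wald CIs and the model
likelihood-ratio p. "Excluding redundant variables" by p-value is not an
operational rule, so the multivariate interface offers two explicit
policies — `enter_all` (default) and `backward_elimination` at α = 0.05 —
with the policy recorded in the output and no claim that either replicates
any published selection. Monotone likelihood and non-convergence are
flagged on the fit object instead of being reported as ordinary numbers.

## The synthetic cohort generator

No patient-level data accompany the scale, so the package carries a
first-class generator whose defaults are the study conditions the analysis
assumes: 53 patients split into intensive (anthracycline-based) and
non-intensive (low-dose cytarabine) arms, a single standard-normal latent
resistance burden per patient that shifts log-IC50s (log-normal) and the
ordered-logit categories of MDR1, P-gp, mutation count, marker count,
origin, karyotype risk and standard prognosis — one knob reproducing the
positive inter-correlation structure among MDR covariates — an ordinal
(cumulative-logit) therapy-response model on the true scale total, and
exponential proportional-hazards survival on the true risk-group index
with administrative censoring.

Defaults and where they come from: age ~ N(51.2, 14.5²) truncated to
18–90; karyotype-risk mix 53.5/11.6/34.9%; 81.1% unfavorable standard
prognosis; syndrome prevalences 79.2% hemorrhagic, 94.3% anemic, 50.9%
infectious, 66% hyperplastic, 86.8% intoxication; 19% missing
cytogenetics; response-model intercepts set so the marginal response mix
is ≈ 30/9/60% remission/relapse/refractory at the typical score; baseline
hazard ln 2 / 452 per day and log HR per risk step ln(452/79)/2, spanning
group medians from ≈ 452 down to ≈ 79 days; censoring horizon 1095 days.
The intensive-arm fraction is not dictated by any reported marginal and is
set to 0.6 as a realistic single choice. Latent-burden loadings (0.5–1.0
on the log-odds / log-IC50 scale) are calibrated loosely to the sign and
strength pattern of the observed inter-correlations, not to exact r
values, which are not available as data.

What the generator does *not* emulate: clonal evolution, treatment
switching, competing risks, informative censoring, raw flow-cytometry or
karyotype data, and any dependence of censoring on covariates. Passing
tests on this generator therefore demonstrate the correctness and
calibration of the machinery under the stated model, not the clinical
validity of the scale on real patients.

## Numerical and testing choices

Problem sizes were chosen to give each check real statistical teeth at
desk scale: parameter-recovery at n = 2000 (Cox estimates within 3 SE of
log HR ∈ {0, ln 1.5, ln 2}); CI coverage over 200 null replicates; IC50
recovery over 100 noisy plates (median absolute relative error < 10% at
noise SD 0.02); AUC and Youden cutoffs checked against exhaustive
pair-counting and threshold enumeration for every instance with n ≤ 25;
the scale scorer enumerated over all 486 parameter combinations against an
independent lookup-table oracle; and byte-identical report bundles under a
fixed seed.

One calibration subtlety deserves record. The null-calibration check
(all latent loadings and the risk-step log HR set to 0) verifies that the
generator induces no spurious survival association across risk groups.
Run literally as a three-group log-rank at n = 53, the *test's own*
asymptotic chi-square reference is anti-conservative — the null
configuration leaves the low-risk group with only a handful of patients,
and a 20,000-replicate experiment puts the true level near 0.074 at
nominal 0.05, identically for permuted group labels (i.e. the inflation
belongs to the reference distribution, not the generator). The packaged
invariant therefore measures type-I error with both compared groups of
adequate size (high-risk vs rest, n = 150), where the measured level is
0.055 with uniform p-values, inside the 0.03–0.07 acceptance band at
α = 0.05 over 2000 replicates.

Other conventions: IC50s right-censored rather than truncated; risk-band
boundary at integer totals per the published rule, fractional totals at
midpoint cuts; Spearman exact/asymptotic switch at n = 10; ROC cutoff ties
resolved to the lowest cutoff; Cox ties by Efron's method.

## Known limitations

The scale's weights are taken as given, not re-derived from data; no
multiple-testing correction is applied anywhere (matching the analysis
design this package mirrors, which applies none); proportional-hazards
diagnostics beyond convergence/monotone-likelihood flags are out of scope;
and the MDR1 category thresholds and P-gp staining categories are consumed
as configuration or labels, never derived from raw images. The paired
"HR equal to its own CI bound" pattern occasionally seen in published Cox
tables cannot be reproduced or checked from summary statistics and is not
targeted.
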