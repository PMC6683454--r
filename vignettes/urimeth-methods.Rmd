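---
title: "Methods: urinary methylation biomarkers of prostate-cancer misclassification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: urinary methylation biomarkers of prostate-cancer misclassification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(urimeth)
```

## The problem

A substantial fraction of prostate-cancer patients is assigned a different
Gleason grade group or tumour stage after radical prostatectomy (RP) than at
biopsy. *Upgrading* (pathological grade group pGG exceeding the clinical
grade group cGG) and *upstaging* (extraprostatic disease, pT ≥ T3a, found at
surgery when the clinical stage was organ-confined) both move patients into
a higher risk group after the treatment decision has already been made.
`urimeth` implements an analysis pipeline for evaluating urinary DNA
methylation of three tumour-suppressor genes (*RARB*, *RASSF1*, *GSTP1*),
serum PSA and Partin nomogram probabilities as pre-operative predictors of
these migrations.

## qMSP quantification

Quantitative methylation-specific PCR reports a quantification cycle (Cq)
per well. The methylation level of gene *g* in sample *s* is expressed as a
percentage of an in-vitro fully methylated control (MC), via the
delta-delta-Cq method with *ACTB* as the endogenous control:

$$
\Delta\Delta C_q = (C_q^{s,g} - C_q^{s,ACTB}) - (C_q^{MC,g} - C_q^{MC,ACTB}),
\qquad \text{level} = 100 \cdot 2^{-\Delta\Delta C_q}.
$$

Validity rules are enforced before any level is reported:

* a **run** is valid per assay when the MC amplified (any finite Cq) and the
  no-template control did not amplify at all; a failed control invalidates
  only that gene's results on that plate, because controls are per-assay;
* a **sample** is valid when *ACTB* gave Cq < 40 in all three replicates —
  fewer than three replicates cannot satisfy the rule and fail it;
* replicate Cq values are aggregated by the arithmetic mean of the
  replicates that amplified (standard qPCR practice; with at most three
  replicates the median differs only in the presence of outliers).

Three deliberate conventions, each fixed so calls are reproducible:

* a target gene that does not amplify in a *valid* sample is a true zero
  (`level = 0`, call `FALSE`), not a missing value — methylation
  frequencies are computed over all valid samples;
* the 0.1 % calling threshold is **inclusive** (level ≥ 0.1 % is
  methylated). The threshold is a configurable constant: it was originally
  chosen from assay repeatability and the technical limit of detection,
  a derivation that cannot be repeated from plate data alone;
* levels above 100 % of MC are possible (a sample more methylated than the
  calibrator at the assayed locus) and are reported with a warning rather
  than capped, since no capping rule is defined for the assay.

The three-gene panel is positive when at least one gene is called
methylated. Whether the MC "positive signal" should additionally respect a
Cq ceiling is unspecified for the assay; any finite Cq is accepted here.

## Clinical classification

Grade groups follow the ISUP 2014 compression of Gleason patterns
(GG1: sum ≤ 6; GG2: 3+4; GG3: 4+3; GG4: sum 8; GG5: sum 9–10). Stages use
the ordered substage scale T1a < … < T2c < T3a < T3b < T4; substage letters
are required on input because the risk rules reference them.

* upgrading: pGG > cGG; downgrading: pGG < cGG;
* upstaging: pT ≥ T3a and cT < T3a ("clinically unsuspected" is read
  literally as cT < T3a); downstaging is the mirror image;
* misclassification: upgraded and/or upstaged;
* pre-operative risk: low (cGG 1 and ≤ cT2a), intermediate (cGG 2–3 and/or
  cT2b), high (cGG 4–5 and/or ≥ cT2c);
* post-operative risk: low (pGG 1, ≤ pT2c), intermediate (pGG 2–3, ≤ pT2c),
  high (pGG 4–5 and/or ≥ pT3a).

The overlapping "and/or" clauses are resolved **highest-wins** (high checked
first, then intermediate, else low) — the only resolution consistent with
D'Amico-style grouping; this makes both risk maps monotone in grade at fixed
stage and in stage at fixed grade, which the test suite asserts.

Patients without an evaluable pathological grade group stay in the staging
denominator but are excluded from grading, misclassification and risk-change
denominators. This reproduces the mixed denominators of the reference
cohort (e.g. upgrading out of 1025 gradable patients versus upstaging out of
all 1056). A patient with unknown pGG but pT ≥ T3a is still post-operatively
high-risk, since the stage alone forces the assignment.

## Biomarker statistics

**ROC and AUC.** The empirical ROC is evaluated at every distinct score
cut-off (test-positive means score ≥ cut-off) plus a sentinel at +∞, so the
curve always spans (0,0)–(1,1). The AUC is the Mann-Whitney pairwise win
probability with ties counting one half, which makes the identity
AUC = U/(n₁n₂) exact; the suite verifies it against brute-force pair
enumeration. The AUC standard error, the p-value against AUC = 0.5 and the
paired/unpaired comparison of two AUCs use DeLong's placement-value
covariance estimator (the default of the MedCalc software family this
analysis style comes from). The unpaired comparison is referred to the
normal distribution; some implementations use a Student-t approximation,
which differs negligibly at these sample sizes.

**Youden threshold.** The operating point maximises J = sensitivity +
specificity − 1 by exhaustive scan over observed cut-offs. Ties are broken
toward higher specificity, then toward the higher threshold — fixed so the
selected threshold is reproducible. On a completely uninformative, constant
score the scan degenerates to the (sens 0, spec 1) corner; predictive
values are undefined (NaN) there, which is reported rather than masked.

**Predictive values.** Sensitivity and specificity at the Youden threshold
are converted to PPV/NPV with an externally supplied prevalence via the
Bayes identities

$$
PPV = \frac{se \cdot p}{se \cdot p + (1-sp)(1-p)}, \qquad
NPV = \frac{sp(1-p)}{sp(1-p) + (1-se)\,p},
$$

using the outcome rates of the full 1056-patient cohort (upstaging
214/1056, upgrading 279/1025, risk change 245/1025) rather than the rate of
the urine subset being evaluated: the urine cohorts are enriched subsets
and the full-cohort rate is the relevant pre-test probability.
Recomputing the published predictive-value tables from their printed
sensitivity/specificity under exactly these prevalences reproduces 30 of 36
rows to within 0.2 percentage points (most within 0.1, i.e. rounding of the
printed inputs). The remaining six rows contain printed values that are
arithmetically inconsistent with their own printed inputs under *any*
single prevalence — no p solving the PPV identity also solves the NPV one —
and are flagged `consistent = FALSE` in
`reported_test_performance()`; they are treated as data discrepancies of
the source tables, not as tolerance failures.

**Combined scores.** How the published analysis combined "gene methylation
+ PSA" into one score is not stated; this package uses binomial logistic
regression on monotonically transformed features — log₁₀(PSA), log₁₀ of the
Partin odds, and log₁₀(level + 0.01) per gene — with the linear predictor as
the combined score. This is the standard combined-ROC construction, keeps
single-feature combined ROCs identical to the feature's own ROC, and is
deterministic given the data. The +0.01 offset keeps zero levels finite
while preserving order (it sits an order of magnitude below the 0.1 %
calling threshold). Complete separation is detected from non-convergence or
exploding coefficients and triggers a ridge-penalised Newton refit with a
small fixed penalty (λ = 10⁻³ on standardised-scale coefficients), flagged
in the fitted object. Because the combination rule is an assumption, the
published combined AUC values are not used as acceptance anchors.

**Odds ratios** come from the 2×2 of the Youden-dichotomised test against
the outcome: the cross-product estimate with Woolf's logit 95 % interval,
and the Haldane–Anscombe +0.5 correction applied to all cells whenever a
cell is zero, so the estimate and interval stay finite (the very wide
published intervals are what sparse cells produce under this construction).
No multiplicity correction is applied anywhere, matching the source
analysis; two-sided 0.05 is the significance convention. Group comparisons
use the two-sided Fisher exact test (categorical) and the Mann-Whitney test
(continuous; midranks for ties, exact small-sample p only in the untied
case, tie-corrected normal approximation otherwise).

## Synthetic cohorts

`generate_cohort()` emulates the structure the analysis assumes, so the
whole pipeline is testable without patient data:

* per-gene methylation levels are **zero-inflated log₁₀-normal**: a level
  is non-zero with a route-specific detection probability, and the non-zero
  level is 10^Normal(μ + δ·adverse, σ) in % of MC. Defaults place detection
  near 0.2–0.6 per gene (panel positivity ≈ 0.80 voided / 0.84
  catheterized), means within the 0.6–15 % range seen in urinary assays,
  with *RASSF1*/*GSTP1* differing by collection route, and small effect
  shifts δ (≈ 0.05–0.15 log₁₀) giving single-gene AUCs near 0.5–0.6 — i.e.
  weakly informative single markers;
* PSA is log-normal (median 7 ng/mL, log₁₀ SD 0.25) with a small adverse
  shift; the synthetic Partin probability is a noisy logit signal of true
  upstaging, since the nomogram itself is consumed as an input, never
  computed;
* cGG and cT come from categorical priors; pGG and pT are drawn from
  row-stochastic transition matrices whose defaults give upgrade/upstage
  rates near 0.27–0.30 and 0.20;
* the "adverse" group receiving the shifts is configurable
  (misclassified by default).

What the generator does **not** emulate: correlation between genes beyond
the shared outcome (real panels correlate through tumour DNA shedding),
plate/batch effects, assay censoring near the limit of detection, and the
clinico-pathological differences between the voided and catheterized
cohorts beyond the level distributions. Passing tests therefore demonstrate
correctness of the machinery under the assumed structure, not clinical
performance on real urine.

Fixed problem sizes used by the calibration checks, chosen to keep
Monte-Carlo error well inside the asserted bounds: two-normal closed-form
AUC recovery at n = 5000 (tolerance 0.02 against Φ(δ/σ√2)), parameter
recovery at n = 10000–20000, DeLong null calibration at 2000 replicates of
30 cases/30 controls (type-I error asserted within 0.05 ± 0.02; binomial SE
≈ 0.005).

## The printed-counts fixture

`build_printed_fixture()` constructs a deterministic 1056-patient cohort
whose classification reproduces every published cohort count: 279/1025
upgraded (241 from cGG1, 208 of those to pGG2), 214/1056 upstaged (105 from
cT1c), 400/1025 misclassified, 245/1025 risk-increased decomposed as
111 grade-only / 55 both / 79 stage-only with 171 pre-operatively low-risk,
and 151/188 voided, 273/326 catheterized panel-positive urine samples. The
construction is arithmetic: the upgraded∧upstaged overlap is forced to
279 + 214 − 400 = 93 by inclusion–exclusion (assuming all upstaged patients
are gradable — the only allocation consistent with the three printed
denominators), blocks of minimal grade/stage templates are laid out in the
order both → grade-only → stage-only, and every count budget must be
consumed exactly, otherwise construction stops naming the violated
identity. Unconstrained patients receive neutral values (cGG2/pGG2,
cT2a/pT2a, PSA 7 ng/mL); the 31 patients without pGG are built
non-upstaged so staging denominators still match. The fixture's round trip
through `classify_cohort()`/`summarize_rates()` is the central regression
test; note one rounding quirk of the source: the both-causes share is
printed as 22.5 % while 55/245 = 22.449 %.

```{r fixture}
rates <- summarize_rates(classify_cohort(build_printed_fixture()))
rates
```

## Known limitations

* The 0.1 % threshold and the logistic combination rule are documented
  assumptions, not derivations; both are configurable.
* Predictive-value recomputation can only validate rows whose printed
  inputs are internally consistent (30 of 36; see above).
* The generator's independence assumptions understate between-gene
  correlation, so combined-marker AUC gains on synthetic data are likely
  optimistic relative to real urine panels.
* Tertiary Gleason patterns, nodal status, margins and time-to-event
  outcomes are out of scope.
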