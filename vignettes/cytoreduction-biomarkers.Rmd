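---
title: "Predicting cytoreductive surgery outcome from serum biomarkers: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting cytoreductive surgery outcome from serum biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytoROC)
```

## The clinical question

Advanced epithelial ovarian cancer (EOC) is treated by cytoreductive
("debulking") surgery followed by platinum–taxane chemotherapy. Survival
depends strongly on whether cytoreduction is *optimal* (residual tumour
< 1 cm) or *suboptimal* (≥ 1 cm). Predicting before surgery which patients
are likely to end up suboptimally debulked usually requires CT or MRI, which
are not universally available; a preoperative serum test would be far more
accessible. cytoROC implements and stress-tests a prediction procedure built
on three serum markers: CA-125 (U/mL), fatty acid synthase (FASN, ng/mL) and
glutaminase (GLS, ng/mL), each elevated in more aggressive disease.

Throughout the package the **positive class is suboptimal cytoreduction**
(the clinically unfavourable outcome, and the higher-marker group for all
three markers), and a patient is **test-positive when the marker or score is
strictly greater than the cutoff**. The strict inequality is forced by the
category coding of the combined scores (category 1 when ≤ cutoff, 2 when
> cutoff): the two rules must agree at the boundary or the single-marker and
combined analyses would classify the same patient differently.

## The procedure

For a marker $X$ with $n_+$ suboptimal and $n_-$ optimal patients:

1. **ROC curve.** Candidate thresholds are the midpoints between consecutive
   distinct pooled values, plus $\pm\infty$ sentinels. At each threshold $t$,
   $\mathrm{TPR}(t) = P(X > t \mid \text{suboptimal})$ and
   $\mathrm{FPR}(t) = P(X > t \mid \text{optimal})$. Midpoints are used
   rather than the observed values themselves: they realize exactly the same
   set of operating points while making the boundary rule unambiguous, and
   the reference study's cutoffs (248.55, 0.445, 22.895, 29.16) carry the
   extra decimals typical of midpoints.
2. **AUC.** Two independent routes: trapezoidal integration of the
   (FPR, TPR) trace, and the Mann–Whitney identity
   $\mathrm{AUC} = U/(n_+ n_-)$ with ties counted one half. They agree to
   machine precision by construction of the curve; the test suite asserts
   this on a thousand random cohorts so either route can serve as the
   oracle for the other.
3. **Cutoff.** The cut-off point (COP) maximizes Youden's
   $J = \mathrm{sens} + \mathrm{spec} - 1$. The selection criterion had to
   be a design choice: reporting a single sensitivity/specificity pair per
   marker is only consistent with a scalar criterion, and Youden's J is the
   standard one for ROC-derived cutoffs. Ties in $J$ are broken toward the
   *smaller* cutoff, i.e. toward sensitivity, because a missed suboptimal
   prediction (a false negative) sends a patient to surgery without the
   imaging work-up the test is meant to replace.
4. **Diagnostics.** Sensitivity, specificity, accuracy, PPV and NPV are
   exact ratios of the integer 2×2 counts; predictive values with a zero
   denominator are reported as undefined (`NA`), never coerced to 0 or 1.
   Percentages are rounded half-up to one decimal.
5. **AUC confidence interval.** The Hanley–McNeil closed form
   $SE^2 = [A(1-A) + (n_+ - 1)(Q_1 - A^2) + (n_- - 1)(Q_2 - A^2)]/(n_+ n_-)$,
   $Q_1 = A/(2-A)$, $Q_2 = 2A^2/(1+A)$, with $z_{0.975} = 1.959964$. This
   needs only $(A, n_+, n_-)$ and reproduces the reference study's CA-125
   interval (67.8–85.6%) exactly; the other printed intervals deviate by up
   to 0.0035, consistent with the original software using a
   data-dependent (distribution-free) standard error that cannot be
   recomputed without the raw data. The closed form is documented as an
   approximation to it.

### Combined scores

The combined panels multiply one marker's numeric level by the {1, 2}
category values of the others:

- CA-125 + FASN: FASN numeric × category(CA-125)
- CA-125 + GLS: GLS numeric × category(CA-125)
- CA-125 + FASN + GLS: FASN numeric × category(CA-125) × category(GLS)

The published description names the category markers but not which marker
stays numeric; the assignment above is the only one consistent with the
published panel ranges (e.g. suboptimal CA-125+GLS maximum 75.00 = GLS
maximum 37.50 × 2; triple suboptimal minimum 0.22 = FASN minimum 0.11 × 2 ×
1; optimal triple minimum 0.03 = 0.03 × 1 × 1). `run_study()` follows the
original two-stage order: single-marker cutoffs are frozen first, then the
panels are built with those cutoffs as category thresholds and the same
ROC/Youden machinery is re-run on the panel scores. No joint optimization of
cutoffs is attempted, and no model-based (e.g. logistic) combination is
offered — the multiplicative score is the procedure under study.

### Between-group tests

Group comparisons report both the Mann–Whitney U (normal approximation with
tie-corrected variance and continuity correction) and the Welch t, labelled,
for every marker and panel. The source tables print two unlabelled p-value
columns per row; rather than guessing which test produced which, both are
always reported. A normality pre-test is deliberately not used to switch
between them: pre-testing distorts the operating characteristics of the
downstream test, and reporting both is more informative. Chi-square (without
continuity correction) covers categorical tables and errors loudly on a
zero expected count instead of falling back to an exact test.

## The synthetic cohort

The 109-patient dataset behind the reference study is not publicly
deposited, so the package ships a generator
(`default_study_params()` + `generate_cohort()`) that emulates its two
groups (56 suboptimal, 53 optimal) from the published summary statistics:

- **CA-125 and FASN** have group means far above their medians (CA-125:
  1157.62 vs 600.00 suboptimal) — strong right skew — and are modelled as
  lognormal. The published (mean, median) pair identifies the parameters in
  closed form: $\mu = \log(\text{median})$,
  $\sigma = \sqrt{2\log(\text{mean}/\text{median})}$
  (`fit_lognormal_from_mean_median()`).
- **GLS** has mean ≈ median (25.19 vs 25.25) and is modelled normal with
  the published mean and SD.
- All six marker-by-group distributions are **truncated to the published
  min–max ranges** by rejection sampling, keeping values clinically
  plausible. Truncation perturbs the realized means/medians slightly from
  their targets (upper-tail mass of at most a few percent is cut); the test
  tolerances (median within 10% at n = 10,000/group, truncated-normal mean
  within 5% of its closed-form truncation-adjusted expectation) absorb this.
- **Stage and histology** are sampled from the published per-group
  proportions, independently of the markers. The published cohort includes
  stage II patients although the stated inclusion criteria are stage
  III–IV; the generator follows the table as printed.

What the generator deliberately does **not** emulate: correlation between
markers within a patient (no correlation structure is published; markers
are drawn independently per group), covariate effects on marker levels,
and measurement error of the ELISA assays. Consequently, passing tests on
synthetic cohorts demonstrate that the *pipeline machinery* is correct and
stable at the study's sample sizes — not that the synthetic AUCs estimate
the clinical AUCs. Independent lognormals with these parameters separate
the CA-125 groups somewhat more cleanly (AUC ≈ 0.84 in expectation) than
the real data did (0.767), which is expected: real serum data are not
exactly lognormal and real markers are correlated.

The generator takes an explicit seed and is bit-reproducible for a given
`(params, seed)`; generation aborts if rejection sampling accepts less than
1% of draws (inconsistent bounds) rather than looping forever.

## Verifying the published table without the raw data

With only printed rates, exact verification is still possible because the
group sizes are known: a sensitivity printed to one decimal pins the unique
integer `tp` in [0, 56] (`reconstruct_confusion()`), and accuracy, PPV and
NPV then follow from exact integer arithmetic. `verify_published_table()`
does this for all six rows and flags every cell where the print disagrees
with the half-up rounding of the exact ratio. Four cells disagree, each by
exactly one unit in the last decimal and each explainable as truncation
instead of rounding (73.3 vs 73.39, 61.4 vs 61.47, 77.9 vs 77.98, 76.6 vs
76.67). One figure legend is internally inconsistent: the CA-125+GLS panel's
AUC of 85.4% implies 93 of 109 patients predicted correctly, not the printed
91, while the other five legends match `round(AUC × 109)` exactly. These are
reported as discrepancies, not errors in the verification.

```{r verify}
verify_published_table()
```

## Numerical choices and degenerate inputs

- Percentage reporting uses half-up rounding to one decimal (`round_half_up()`),
  with a `1e-9` guard against binary representation of exact ties.
- Youden ties break to the smallest candidate cutoff; equality of J is
  tested with a `1e-12` slack to be robust to float noise in `sens + spec`.
- Single-class inputs error in `roc_curve()`/`confusion_at_cutoff()`; a
  degenerate all-tied cohort yields AUC 0.5 and J = 0.
- `mann_whitney_u()` on two identical constant samples returns
  `U = n_x n_y / 2`, `p = 1`; `t_test_unpaired()` returns `t = 0, p = 1`
  when both samples are constant with equal means and errors when the
  means differ (t is undefined there).
- All randomness flows through explicit seed arguments.

## Problem sizes used in the test suite

The property suites run at the scales the procedure's claims are made at:
1,000 random cohorts for the AUC route equivalence, 200 for the Youden
exhaustive scan, 10,000 patients per group for generator moment recovery,
and 2,000 null replicates (50 + 50) for test-size calibration; the whole
suite completes in well under a minute on a single CPU.

## A complete run

```{r study}
cohort <- generate_cohort(default_study_params(), seed = 42)
report <- run_study(cohort, pinned_cutoffs = c(ca125 = 248.55, gls = 22.895))
as.data.frame(report)
```

Pinning the CA-125 and GLS category cutoffs to the published values (as
above) reproduces the published worked examples; omitting `pinned_cutoffs`
re-derives every cutoff from the cohort at hand by Youden's J, which is the
mode a user would apply to their own data via `read_cohort_csv()`.

## Known limitations

- Single-marker cutoffs and AUCs from synthetic cohorts are *not* expected
  to match the published ones numerically — the raw data is not available,
  and the generator makes an independence assumption the data need not obey.
- The Hanley–McNeil interval is an approximation to whatever standard error
  the original analysis used (only the CA-125 interval reproduces exactly).
- No DeLong paired AUC comparison, partial AUC, smoothed ROC, exact
  small-sample Mann–Whitney p-values, or multiple-testing correction: the
  source analysis used none of these.
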