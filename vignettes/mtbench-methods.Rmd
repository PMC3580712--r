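---
title: "Methods: massive-transfusion score validation with mtbench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: massive-transfusion score validation with mtbench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtbench)
```

## The problem

Massive transfusion (MT) — here, ten or more units of packed red blood cells
between emergency-room arrival and ICU admission — must be anticipated within
minutes of admission, from variables available at the bedside: vital signs,
point-of-care labs (haemoglobin, base excess, lactate, INR), sonography and
basic injury assessment. `mtbench` implements six published bedside scores for
this decision and the statistical machinery to validate and compare them on a
single cohort, together with a synthetic cohort generator so the whole
pipeline is exercisable and testable without registry access.

## The scoring model

Every score is a set of *banded components*: a component reads one input
variable, its ordered bands are comparator–threshold pairs with integer
points, and the first (most severe) matching band contributes. Component
contributions are summed, with one exception: the TASH fracture block, where
the unstable-pelvis (AIS ≥ 5, 6 points) and severe-femur (AIS ≥ 3, 3 points)
contributions compete and only the larger counts. Summing them instead would
allow 31 points, contradicting the score's published 0–28 range; the max
aggregation is the only reading consistent with that range, and the test
suite verifies by exhaustive band enumeration that each score attains exactly
its published maximum (28, 19, 5, 4, 3, 4) and minimum 0.

Boundary semantics are preserved exactly as printed: TASH fires at heart rate
strictly above 120 bpm while ABC and PWH fire at 120 exactly; PWH's systolic
pressure band includes 90 mmHg while TASH's most severe band requires strictly
below 100; Larson's haemoglobin band is strictly below 11 g/dl while
Vandromme's and Schreiber's include 11.0. "Base deficit > 5 mmol/l" is
evaluated as base excess < −5. Two published PWH haemoglobin bands, "≤ 7" and
"7.1 to 10", leave the interval (7.0, 7.1) unassigned; `mtbench` assigns it to
the 10-point band (Hb < 7.1), the only choice that keeps the score monotone in
haemoglobin. "Displaced pelvic fracture" is operationalised as pelvic AIS ≥ 4
and TASH's "clinically unstable" pelvis as AIS ≥ 5, following the registry
annotations that accompany the printed component tables.

The TASH risk transform is implemented exactly as printed,
`p = 1/(1 + exp(5.4 − 0.3·TASH))` (computed as `plogis(0.3(TASH − 18))` so the
midpoint score 18 maps to exactly 0.5). Prose claims sometimes attached to
this score — that 16 points imply > 50% MT risk, or 27 points ~100% — are
inconsistent with that formula, which gives p(16) ≈ 0.35 and p(27) ≈ 0.94;
`mtbench` follows the formula and does not guess alternative coefficients.

Scores are data, not code: `score_definitions()` exposes the component
tables, and the test suite enumerates them mechanically (band representative
values, monotonicity under worsening physiology, within-band invariance).

## Eligibility filters and missing data

`apply_eligibility_filters()` applies, in a fixed order chosen for
deterministic, reportable attrition: age ≥ 18 → primary admission → survived
to ICU → pRBC count known → no hemostatic agents → complete case. Each
removal is attributed to the first rule failed. The complete-case rule spans
the union of variables needed by all requested scores (global complete case,
mirroring a one-dataset-for-all-scores validation design); passing a subset
of `score_ids` gives per-score complete-case behaviour. Missing values are
empty CSV fields throughout — no numeric sentinels — so a written cohort
round-trips exactly, missingness pattern included.

## ROC conventions

* **Thresholds** are the midpoints between consecutive distinct observed
  scores plus `±Inf` sentinels, with classification "positive if score ≥
  threshold". On integer scores this yields the half-point cut-offs (≥ 8.5,
  ≥ 2.5, …) familiar from published comparison tables.
* **AUC** is computed in concordance form from midranks, so a case–control
  tie contributes exactly ½ (the standard Mann–Whitney treatment). The test
  suite checks, over randomized small instances with heavy ties, that this
  equals the trapezoidal area under the midpoint ROC to 10⁻¹².
* **Confidence intervals**: DeLong's placement-variance interval is the
  default; Hanley–McNeil and a seeded stratified percentile bootstrap are
  provided because the estimator behind any given published interval is
  often unstated. Normal-theory intervals are clipped to [0, 1].
* **Cut-off selection**: "best relationship between sensitivity and
  specificity" is operationalised as Youden's J = sens + spec − 1, ties
  broken toward the smaller threshold. Rationale: a tie resolved toward the
  lower cut-off keeps sensitivity, the priority in MT screening.
* **AUC comparison**: `compare_aucs_ci_method()` recovers each SE from its
  95% CI as (high − low)/(2 × 1.959964) and refers
  z = ΔAUC/√(SE₁² + SE₂²) to the standard normal. At registry scale the
  difference from a finite-df t reference is negligible; the implementation
  requires CIs symmetric about their AUCs (tolerance 10⁻⁶) and otherwise
  directs the caller to supply SEs. The two curves are treated as
  independent — the comparison ignores the correlation induced by computing
  both scores on the same patients, exactly as the CI-only construction
  implies.
* A metric with an empty denominator (e.g. PPV when nothing is flagged) is
  reported as `NA`, never 0.

## The synthetic cohort generator

The generator emulates the *statistical structure* the validation assumes,
not any real registry. One latent severity factor `s ~ N(0,1)` per patient
induces all cross-variable dependence:

* **Continuous variables** are `μ + σ(ρ·s + √(1−ρ²)·ε)` clamped to
  physiological ranges (HR [0,250], SBP [30,300], Hb [2,20], BE [−30,20],
  lactate [0,30], INR [0.8,10], age [18,100], Quick [5,150], ISS [0,75]).
  Default marginal means/SDs are those of a published registry extract (age
  45.7 ± 19.3 y, HR 89.7 ± 20 bpm, SBP 125.3 ± 28.6 mmHg, Hb 11.8 ± 2.6 g/dl,
  BE −2.6 ± 4.3 mmol/l, lactate 3.1 ± 5.2 mmol/l, Quick 81.2 ± 21.1%,
  ISS 24.3 ± 13.2). Because clamping biases moments, the normal variables use
  a location shift solved (closed-form clamped mean + `uniroot`) so the
  *clamped* mean equals its target; lactate and INR, whose SD exceeds or
  approaches their mean (impossible for a symmetric nonnegative variable),
  are lognormal with both clamped moments matched numerically — naively
  matching the unclipped lognormal and then clipping lactate at 30 mmol/l
  would deflate its SD by roughly a fifth.
* **Loadings** default to ±0.5 with the physiological signs (HR, lactate,
  INR, ISS positive; SBP, Hb, BE, Quick negative; age 0). The INR marginal
  (mean 1.2, SD 0.5) is the package's own choice — plausible alongside a mean
  Quick of ~81% — since only Quick appears in the published baseline table.
* **GCS** is drawn from {3..15} via a severity-linked severe/non-severe split
  anchored at P(GCS ≤ 8) = 0.2 by default, with within-group weights favouring
  3 and 15 (the registry-typical U-shape); P(GCS ≤ 8) is increasing in `s` by
  construction. **Injury flags** are Bernoulli with unit-slope logistic
  dependence on `s`, intercept-calibrated by quadrature to their prevalences:
  displaced pelvis (AIS ≥ 4) 0.10 — of which 60% unstable (AIS 5) — femur
  fracture (AIS ≥ 3) 0.06, FAST+ 0.15, CT free fluid 0.10. These prevalences
  are generator parameters, not claims about any registry, which publishes no
  such marginals. Sex (73.4% male) and mechanism (95% blunt) are independent
  of severity by default: the published table gives no joint information, so
  independence is the explicit neutral choice (configurable via loadings only
  for continuous variables).
* **Outcome**: MT ~ Bernoulli(plogis(α + β·s)) with β = 2 by default and α
  calibrated by bisection so that E[plogis(α + β·S)] under the standard
  normal (Gauss quadrature via `integrate`) equals the target prevalence,
  5.6% by default. pRBC units are then constructed to agree with the outcome:
  10 + Poisson(4) for MT patients, min(Geometric(0.6), 9) otherwise, so
  `derive_mt_outcome()` recovers the generator's flag for every record.
* **Determinism**: the spec carries the seed; identical spec + seed yields a
  bit-identical cohort and, via the canonical writer, identical CSV bytes.
  Missingness injection and ineligible-record injection (each appended record
  violates exactly one filter rule) use derived seeds and exist to exercise
  the filters.

What passing tests on this generator do and do not show: they verify the
pipeline's *mechanics* — marginal recovery within 4σ/√n, calibrated
prevalence, scores wired to the severity axis that drives the outcome, the
qualitative ordering in which weighted multi-variable scores out-discriminate
the unweighted ABC. They do not reproduce real-registry effect sizes: a single
latent factor with uniform ±0.5 loadings understates the tail dependence of
real hemorrhagic shock, so synthetic AUCs (≈ 0.66–0.79) sit below published
registry values (0.76–0.89), and synthetic Youden cut-offs need not equal the
published ones. Inter-hospital structure, temporal trends, ISS–AIS
consistency and skewness beyond the lognormal choice are out of scope.

## Numerical choices and degenerate inputs

* Bisection for intercepts runs on [−20, 20] to an absolute prevalence
  tolerance (10⁻⁸ inside the generator); `β = 0` short-circuits to
  `qlogis(target)` exactly.
* Continuous values are rounded to registry-style precision (integers for HR,
  SBP, Quick, age, ISS; 0.1 for Hb, BE, lactate; 0.01 for INR), which keeps
  CSV round-trips exact and leaves moment recovery within its sampling
  tolerances.
* ROC on a single-class outcome, summaries of empty cohorts, probabilities
  outside (0,1) and malformed spec fields raise immediate errors naming the
  offending field; an all-tied score vector degenerates to the two sentinel
  points with AUC 0.5.
* Problem sizes in the shipped tests and acceptance script — 5,000 for
  marginal recovery, 20,000 for prevalence calibration and the synthetic
  validation, 10,000 bootstrap replicates at n = 500, ~2,300 enumerated TASH
  band combinations — were chosen so each check is decisively powered while
  the whole suite runs in well under a minute per file.

## Package shape

The validation step follows the classic modelling idiom: `mt_validate()` is
the single fitting-style entry point returning a classed object with `print`,
`summary`, `plot` and `as.data.frame` methods, while the stages around it
(cohort I/O, filters, score functions, generator, `cmd_*` pipeline drivers
and the `mtbench` command-line script) are plain functions. The ROC/AUC
machinery is implemented in-package — threshold convention, tie handling and
the CI-derived comparison are part of what is being validated — with an
independent external implementation (`pROC`) used in the test suite as a
cross-check oracle only.

## Known limitations

* The CI-derived AUC comparison inherits the independence approximation of
  its construction; correlated-curve tests (paired DeLong) are deliberately
  not provided.
* No Quick↔INR conversion is implemented; `quick_er` is descriptive only and
  scores requiring INR read `inr_er` directly.
* The generator matches means and SDs (and range constraints), not full
  quantile functions; published medians/IQRs of skewed variables are not
  targeted beyond the lognormal choice for lactate and INR.
* No multiple-testing correction across pairwise AUC comparisons is applied;
  the comparison function tests one pair at a time.
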