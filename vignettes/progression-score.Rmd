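---
title: "Methods: the fragmentomic Progression Score pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the fragmentomic Progression Score pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragps)
```

## The measurement model

The assay estimates the concentration of two nested cfDNA size classes in
plasma by qPCR on high-copy retrotransposon targets. An amplicon of length
*L* amplifies only templates of at least *L* bp, so the 80 bp ALU amplicon
measures the ">80 bp" class (short marker, SM) and the 105 bp amplicon the
">105 bp" class (mid marker, MM); their difference is the 80–105 bp
short-fragment excess in which tumor-derived DNA is enriched. Two
multiplexes are run per sample: multiplex 1 carries the 80 bp ALU target
(FAM), multiplex 2 the 105 bp ALU target (FAM); both carry a 265 bp SVA
amplicon (Cy5) used as a cross-multiplex concordance control and a 172 bp
synthetic internal positive control (HEX) that flags PCR inhibition.

Quantification uses the universal log-linear calibration
$C_t = m \log_{10} q + b$ with $m < 0$, fitted by least squares to a
dilution series; amplification efficiency is $10^{-1/m} - 1$. Triplicate
wells are averaged on the Ct scale (scatter above 0.5 Ct, replicate
dropout, and total non-amplification are flagged), inverted through the
curve, and converted to plasma concentration with the protocol volumes
(2 µL of a 60 µL eluate extracted from 500 µL plasma: one copy per reaction
is 60 copies/mL). Duplicate extractions are averaged at the concentration
level, after curve inversion, because extraction replicates differ in
recovered template rather than in amplification kinetics.

## Eligibility and run-quality gates

All stated windows are inclusive at both ends; only the transit bound is a
strict inequality, because it is phrased as an exclusion of samples *more
than* 120 h in transit:

| rule | bound | behavior at the bound |
|---|---|---|
| transit per draw | ≤ 120 h | 120.0 h passes |
| second draw after first treatment | 12–21 days | both ends pass |
| assessment scan after first draw | 9–12 weeks | both ends pass |
| imaging progression | ≥ 20% diameter-sum increase | 20.0% is progression |

Two run-level rules have no published numeric threshold, so the defaults
are conventional qPCR acceptance values and both are configurable: the IPC
shift bound is 1.0 Ct against the run median (≈2-fold amplification
deficit), and SVA cross-multiplex concordance allows a 30% relative
difference with a symmetric-mean denominator (so the verdict does not
depend on which multiplex is called first). A missing IPC is total
inhibition and fails outright; indeterminate verdicts (missing timestamps,
non-positive SVA quantities) are treated as failures but flagged
distinctly. Clinical exclusions (secondary malignancy, active autoimmune
treatment, recent DVT/PE/sepsis) cannot be diagnosed from the assay and
enter as boolean manifest columns.

## Derived variables and the fragmentomic cancellation

`Frag1 = max(SM1 − MM1, 0)` and `Frag2 = max(SM2 − MM2, 0)` floor only the
per-draw excesses: a negative excess is measurement noise, since the >80 bp
class contains the >105 bp class. The between-draw changes
`FragDiff = Frag2 − Frag1` and `MMDiff = MM2 − MM1` are deliberately
signed — the candidate models use MMDiff as a noise-cleanup covariate whose
expected coefficient is negative, which requires sign information.

The cancellation property that motivates the design: DNA released by
white-blood-cell lysis or by acute non-cancer conditions is dominated by
mononucleosomal (~166 bp) fragments, which amplify in *both* size classes.
Adding a common quantity $g$ to SM and MM of a draw inflates raw
concentrations arbitrarily (10-fold lysis spikes occur in shipped samples)
but leaves $SM - MM$ unchanged. A genuine tumor signal, by contrast, lands
preferentially below 105 bp and moves FragDiff.

## Model selection, LOOCV, and the score

Six pre-defined logistic models on subsets of {FragDiff, Frag1, SM1,
MMDiff} are fitted by maximum likelihood (Fisher-scoring IRLS, tolerance
1e-8, ≤100 iterations; quasi-complete separation is flagged, not penalized
— at n ≈ 128 with ≤3 predictors regularization is unnecessary and would
bias the score scale). The candidate set is fixed in advance; no
data-driven feature selection. Per model we report the training ROC AUC
(rank-based, ties counting one half), a likelihood-ratio p-value against
the intercept-only model with a Bonferroni multiplier of 6 (the size of the
pre-defined family — the most direct reading of a model-level adjustment),
and Wald significance of each coefficient.

Selection takes the highest training AUC, with two refinements. Exact ties
break toward fewer predictors, then table order. By default
(`parsimony_on_flag = TRUE`) a model whose *added* predictors are not Wald
significant at 0.05 is set aside before the argmax: a richer nested model
maximizes likelihood, not AUC, so a ~0.002 AUC edge from a non-significant
extra term is noise, and the score a clinician receives should come from
the leanest model that earns its terms. The literal argmax is available
with `parsimony_on_flag = FALSE`.

Honest discrimination is estimated by leave-one-out cross-validation: n
refits on n−1 patients, the held-out probabilities pooled and scored once.
The fold structure is per patient, so row order is irrelevant. A fold whose
training set loses a class predicts the training prevalence and is counted
in an attribute.

**Null behavior of pooled LOOCV.** Pooled leave-one-out probabilities are
*pessimistic* under a pure-noise model: leaving out a case lowers that
fold's training prevalence, so the intercept component of every held-out
prediction is perfectly anti-ranked with the outcome. When a predictor
carries no signal this small systematic term dominates and the null
expectation of the pooled LOOCV AUC sits near 0.36 at n = 200 (measured
over 30 replicates; single replicates range from 0 to ~0.6) rather than
0.5. With real signal the effect is negligible — training-vs-LOOCV
comparisons in the signal regime behave as expected — but a chance-level
band of 0.4–0.6 for single null runs is not a property this estimator has,
and the test suite asserts the aggregate behavior instead.

The Progression Score is `100 × predicted probability`, rounded to one
decimal. The mapping is the simplest one consistent with a 0–100 report
with one-decimal granularity; no additional recalibration is applied.

## Bootstrap expected-PPV calibration

The call cut-point is chosen to guarantee the *expected* positive
predictive value of a call, estimated by a B = 1000 bootstrap: each
iteration resamples the cohort with replacement, **refits** the selected
model on the resample (propagating coefficient uncertainty into the
estimate; a fixed-model variant exists behind `refit = FALSE`), scores the
resample, and records PPV(t) = TP/(TP+FP) at every integer threshold
t = 0…100. Thresholds at which an iteration makes no call contribute
nothing there — imputing PPV = 1 for empty calls would inflate the curve
exactly where it matters. The expected PPV at t is the mean over defined
iterations.

`select_cutpoint()` returns the smallest threshold whose expected PPV meets
the target (default 99%) *and remains at or above it at every larger
defined threshold*. The stability condition guards against isolated upward
blips: empirical PPV is not globally monotone in the threshold (a single
high-scoring control can sink it at the top), so qualification must look
rightward. A call is made at `PS ≥ cutpoint`; the boundary calls
progression.

## The synthetic cohort generator

The generator emulates the study conditions the pipeline was designed for:
128 patients, progression prevalence 20/128, two draws with
eligibility-consistent timestamps, and the pre-analytical artifact
processes the QC stage must catch. Since no concentration scales or
variances are published for this assay, the marginals are plausible
choices, documented here and fixed:

| parameter | default | rationale |
|---|---|---|
| MM1 | lognormal(log 2000, 0.7) copies/mL | positive, right-skewed background |
| Frag1 | lognormal(log 250, 0.8) | short excess an order below background |
| draw-2 excess noise | sdlog 0.25 | stable non-progressing disease |
| progression effect on FragDiff | + lognormal(log 600, 1.3) | wide spread: some progressors nearly silent at the second draw, so discrimination is strong but imperfect |
| MM drift | sdlog 0.15 | slow background change between draws |
| lysis | 3% per draw, 2–10× raw inflation | common additive spike to both classes |
| PCR inhibition | 2% of samples, +2.5 Ct all targets | caught by the IPC rule |
| non-cancer elevation | 2% of patients, 3× total cfDNA, 5% sub-105 bp tail | mononucleosome-dominated event DNA |
| Ct noise | sd 0.15 per well | typical multiplex qPCR replicate scatter |

Under these defaults the composed pipeline lands in the intended regime
(training AUC roughly 0.88–0.97 across seeds, cut-points in the 80s–100,
zero training false positives at the selected cut-point, a substantial
fraction of progressors below the cut).

The interference panel (`generate_noncancer_panel()`) mirrors the
specificity sub-study sizes (stroke 3, asthma 2, COPD 3, DKA 3, IBD 4,
MI 2, RA 5, seizure 3, viral 5; 9 healthy volunteers) and offers two
elevation modes: `"proportional"` event DNA counted by both amplicons
(both classes rise, the excess barely moves — the cancellation case) and
`"short_only"` (the same quantity confined to the >80 bp class, a
progression mimic). `compute_ps_change()` reports scores relative to the
healthy-panel mean.

What the generator does **not** emulate: biophysical fragment-length
distributions (size classes are generated directly, not from a fragment
model), batch and operator effects, inter-site handling differences,
standard-curve drift between runs, and any correlation between cancer type
and cfDNA level. Passing tests therefore demonstrate the pipeline's
statistical machinery under the stated generative assumptions, not
clinical performance on real cohorts.

## Numerical choices and degenerate inputs

* Problem sizes in the test suite: cohorts of 128 (study scale) for
  end-to-end checks, 2000×200 replicates for coefficient recovery, 4000 for
  effect-recovery, B = 1000 for calibration checks — all chosen to keep the
  full suite around a minute while leaving Monte-Carlo margins wide.
* Seeds are fixed wherever randomness enters a test; the pipeline derives
  its bootstrap seed from the run seed, keeping derived seeds below 2^31.
* Missing Ct is a non-amplification sentinel, never zero; inverting a
  missing mean Ct yields quantity 0 (below detection).
* "Undetermined" plate exports parse to missing; dye–target mismatches are
  flagged per well and surfaced as QC error records rather than dropped.
* A patient lacking an informative target in either draw is flagged
  `unquantifiable` and excluded from modeling with a reason row.
* Outcomes may be missing at scoring time (prospective use); fitting and
  calibration require them.
* Degenerate outcomes (single class), empty cohorts, inverted standard
  curves, and fewer than three dilution levels are hard errors with named
  stages.

## Known limitations

* The cut-point and all performance numbers are training-cohort quantities;
  the bootstrap propagates sampling and coefficient uncertainty but not
  distribution shift. Real deployment needs an independent cohort.
* The expected-PPV estimand is the per-threshold mean over resamples; a
  lower confidence bound would be more conservative and is noted as an
  alternative, not implemented as the default.
* Pooled LOOCV AUC is pessimistic under null signal (see above), which
  makes it an honest, slightly conservative summary in the signal regime.
* The parsimony-on-flag selection rule is a documented judgment call; both
  behaviors are implemented and switchable.
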