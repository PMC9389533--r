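---
title: "From frame tags to video diagnoses: methods behind ttroi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From frame tags to video diagnoses: methods behind ttroi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ttroi)
```

## The problem

A frame-wise lesion classifier running on magnifying optical-enhancement
endoscopy video emits one label per frame — `cancer`, `benign`, `background`
or `none` — at up to 30 frames/s. Frame labels are noisy and flicker; a
clinical diagnosis is made per *video* (per patient, for the most serious
lesion). `ttroi` implements the aggregation that bridges the two levels and
the full diagnostic-accuracy evaluation of the resulting video-level test,
plus a synthetic generator of frame streams so every stage can be exercised,
calibrated and regression-tested without any video data.

The positive class throughout is early gastric cancer (EGC), defined by the
revised Vienna classification: categories C4 (mucosal high-grade neoplasia)
and C5 (submucosal invasion) are cancer; C1–C3, including low-grade
intraepithelial neoplasia (LGIN, C3), are non-cancerous.

## ROIs and the TTROI statistic

Cancer tags cluster in time while the endoscopist dwells on a suspicious
lesion. A *region of interest* (ROI) starts at any cancer recognition tag
and ends when no new cancer tag arrives within 3 s. Formally, the
cancer-tagged timestamps are partitioned into maximal runs in which
consecutive tags are at most `gap_s = 3` seconds apart; each run is one ROI.
The video-level statistic is the *total time of the regions of interest*:

$$\mathrm{TTROI} = \sum_{i} (\text{end}_i - \text{start}_i).$$

Three conventions needed fixing where the verbal rule is ambiguous:

* **Closed gap comparison.** "Within 3 s" includes the boundary: tags 3.000 s
  apart join, 3.001 s apart do not.
* **ROI end = last tag.** The run ends where recognition stopped, at the
  timestamp of its last cancer tag, not 3 s later. The alternative
  (`roi_end = "last_tag_plus_gap"`) is implemented because it is a defensible
  reading, but it inflates every TTROI by up to 3 s per ROI; only the default
  is used anywhere in the analyses.
* **Isolated tags.** A single isolated tag is an ROI of zero duration. It
  contributes nothing to TTROI but does make `has_roi` true, which matters
  because the "no ROI" proportion (videos with zero cancer tags) is itself a
  reported group-level statistic.

Timestamps are real-valued seconds and are used as-is — no snapping to a
frame grid — since streams may have dropped frames. Duplicate timestamps
(several boxes on one frame) are collapsed first by the priority rule
cancer > benign > background > none, so a frame contributes one label.

The implementation is a linear scan over sorted tag times; the test suite
proves it equivalent to an independent $O(n^2)$ transitive-closure
clustering oracle on thousands of random streams, along with the structural
invariants (disjointness, separation by more than the gap, monotonicity in
added tags and in the gap, invariance to non-cancer labels).

## Cutoff selection and classification

A video is called cancer iff $\mathrm{TTROI} \ge c$. The operating cutoff
used in the headline evaluation is $c = 1$ s; `roc_points()` also selects a
cutoff in-sample. Candidate thresholds are the unique observed TTROI values
plus $+\infty$ — reproducible and sufficient for a step-function ROC — and
the AUC is the trapezoidal area over the (FPR, sensitivity) polyline closed
at (0,0) and (1,1), which the tests verify equals the tie-corrected
Mann–Whitney statistic $U/(n_1 n_2)$ exactly.

The "best" cutoff maximises Youden's $J = \text{sens} + \text{spec} - 1$,
the standard convention when no criterion is stated. Ties in $J$ break
toward the **smallest** threshold: for a rule-out test the valuable property
is a low negative likelihood ratio, and the smaller threshold is the more
sensitive operating point. The positive call is a closed inequality
($\ge$), which makes "cutoff = smallest positive observed TTROI" well
behaved: at that cutoff every zero-TTROI video is negative and every
tag-bearing video positive.

## Diagnostic accuracy and agreement statistics

From the 2×2 video-level table the package reports sensitivity,
specificity, accuracy, PLR $= \text{sens}/(1-\text{spec})$ and NLR
$= (1-\text{sens})/\text{spec}$.

* **Proportion CIs: Wilson score.** Chosen because it is well behaved at
  small $n$ and at the boundaries (1/1 correct gives roughly 0.21–1.00),
  and because it reproduces the intervals printed in the clinical
  evaluation this pipeline mirrors (21/24 → 0.69–0.96), which Wald and
  Clopper–Pearson do not.
* **Likelihood-ratio CIs: log method** (Simel), $\exp(\log LR \pm z\,se)$
  with $se^2 = 1/\mathrm{TP} - 1/(\mathrm{TP{+}FN}) + 1/\mathrm{FP} -
  1/(\mathrm{FP{+}TN})$ for the PLR and the FN/TN analogue for the NLR. A
  zero denominator yields an infinite LR, reported as `Inf` with a flag
  rather than an error, since perfect strata legitimately occur.
* **Pearson chi-square without continuity correction** for 2×2 group
  comparisons; the Yates correction would roughly triple the p-value of the
  severity analysis recomputed in the tests. Expected counts in these
  tables are small, so Fisher's exact test is provided as a companion, but
  the primary reported test remains the uncorrected chi-square.
* **McNemar, exact binomial by default.** Paired accuracy comparisons on a
  ~117-case set have single-digit discordant counts; the exact two-sided
  binomial test on $(b, c)$ with $p = \tfrac12$ is appropriate, the
  asymptotic chi-square form is available by flag, and $b = c = 0$ returns
  $p = 1$.
* **Mann–Whitney U with midranks** for TTROI group comparison: exact by
  enumeration when $n_1 n_2 \le 400$ and untied, otherwise the normal
  approximation with tie-corrected variance. At very small samples the
  exact null is a coarse lattice and the normal approximation can deviate
  by up to ~0.13 — the tests document this honestly rather than pretending
  a tighter agreement.
* **Cohen's kappa** with the large-sample interval
  $se = \sqrt{p_o(1-p_o)/n}/(1-p_e)$; undefined (error) when both raters
  are constant.
* **Rounding.** Reported values round half *up* (0.625 → 0.63), matching
  clinical reporting style, via `round_report()`; R's default half-to-even
  would disagree at exactly-half values. All arithmetic is done at full
  precision and rounded only for display.

## The synthetic frame-stream generator

No per-frame output of the real detector is deposited, so the generator is
a two-layer model calibrated against the *video-level* statistics that were
published, and it is deliberately generative at the frame level so that the
ROI stage is exercised on realistic clustered tag streams rather than on
pre-aggregated numbers.

**Viewing layer.** Video length is log-normal (median 300 s, log-sd 0.4 —
about 5-minute examinations, 117 videos ≈ 10 h). Each video contains
lesion-viewing episodes (Poisson count with mean 3, at least 1; gamma
length, mean 25 s, shape 2) during which the endoscope dwells on the
lesion; cancerous videos view `EGC` tissue there, non-cancerous ones
`benign_lesion`, and `background` otherwise.

**Emission layer.** Each frame's label is drawn from the viewed tissue's
row of a 3×4 confusion matrix, mixed with Markov persistence: with
probability `persistence_rho = 0.8` the frame copies the previous label.
Persistence changes run lengths, not marginals, and reproduces the streaky
flicker of real frame classifiers; setting it to 0 recovers i.i.d. draws
(verified by a chi-square goodness-of-fit test).

**Calibration anchors and their rationale:**

* Non-cancerous tissue emits **zero** cancer tags outside bursts. False
  positives instead arrive as rare *bursts*: with per-video probability
  `fp_burst_prob = 0.219` (14 of 64 non-cancerous videos carried an ROI)
  one exponential-length episode (mean 10 s) temporarily switches the
  emission row to the cancer-tissue row. This structure is forced by the
  data: 78.1% of real non-cancerous videos, ~9,000 frames each, had *no*
  cancer tag at all, which no realistic i.i.d. per-frame false-positive
  rate can produce.
* A cancerous video is "silent" with probability `fn_silent_prob = 0.094`
  (5 of 53 cancer videos had no ROI): its episodes emit as benign tissue.
* The EGC emission row (cancer on ~55% of viewed-lesion frames) is a free
  calibration choice; no per-frame error rate was published. Its value
  matters little for the video-level operating point because episodes are
  long relative to the 3-s gap — and the tests verify the intended
  monotonicity: video-level sensitivity rises with the frame-level cancer
  emission probability.
* `default_subtype_overrides()` optionally concentrates the false bursts in
  the subtypes the real detector confuses most (atrophy + intestinal
  metaplasia 6/16, LGIN 4/7, remaining benign subtypes 4/41, preserving the
  expectation of 14 false positives). The plain defaults keep the uniform
  0.219 instead, because the aggregate zero-ROI calibration — the property
  the package's acceptance checks measure — is defined at cohort level.

**Determinism.** Every simulation function takes an explicit seed, restores
the caller's RNG state, and derives per-video seeds from the master seed by
a fixed affine map modulo $2^{31}-1$, so cohorts are bit-reproducible and
videos are independently regenerable. Fresh labels are drawn by inverse-CDF
with the cancer label first, so under a shared seed the set of
cancer-tagged frames is monotone in the cancer emission probability — this
coupling is what makes the sensitivity-sweep test deterministic rather than
flaky.

**What the generator does not emulate.** Bounding-box geometry and
confidences (absent: the temporal rule ignores them), expert readers,
within-video drift of error rates, lesion reappearance statistics tied to
anatomy, and any image content. Consequently, passing tests show the
*pipeline* is correct and the *calibration targets* are met; they say
nothing about the real detector's frame-level behaviour beyond the
published video-level margins.

## Problem sizes and numerical choices

The test suite runs the oracle-equivalence checks on 1,000 random streams
and 1,000 random ROC instances, the calibration check on 100 replicate
cohorts of 64 non-cancerous videos (6,400 simulated videos, ~1M frames),
and the sensitivity sweep on 6 × 40 videos — sizes chosen so the whole
suite completes in about a minute on one core while leaving the Monte-Carlo
error of the calibration check (binomial sd ≈ 0.5 percentage points at
n = 6,400) well inside the ±1.5-point band it asserts.

Degenerate inputs are handled explicitly rather than by accident: empty
streams error; streams without cancer tags summarise to TTROI 0 with no
ROIs; single-class truth vectors make the ROC error; fully tied rank tests
return p = 1; a constant pair of raters makes kappa error; zero 2×2 margins
make the chi-square error and Fisher's test return 1.

## Known limitations

* The in-sample Youden cutoff is optimistically biased; no cross-validation
  is offered because the evaluated design reports a single in-sample cutoff.
* ROC confidence bands and multi-rater (>2) agreement are out of scope.
* The generator's burst model slightly exceeds the nominal zero-ROI rate
  (an exponentially short burst can emit no tag, ~+0.4 percentage points);
  this is a property of the chosen generative structure, documented rather
  than tuned away.
* All evaluation is at video level; nothing here localises lesions within a
  video beyond the ROI intervals themselves.
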