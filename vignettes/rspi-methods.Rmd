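---
title: "Scoring left-ventricular dyssynchrony with the Regional Strain Pattern Index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring left-ventricular dyssynchrony with the Regional Strain Pattern Index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rspi)
```

## The clinical problem

Cardiac resynchronization therapy (CRT) restores coordinated contraction in
heart failure with conduction delay, but roughly a third of implanted
patients do not remodel favourably. Mechanical dyssynchrony visible in
speckle-tracking longitudinal strain carries information that the QRS width
alone does not. In left bundle branch block the early-activated
(antero)septal wall contracts early and briefly while the late-activated
opposing wall is first stretched and then reaches its peak contraction after
aortic valve closure (AVC).

The Regional Strain Pattern Index (RSPI) turns this morphology into a
0–12 point score. In each of the three apical views (4-, 2- and 3-chamber),
four components are assessed on the basal and mid segments of the two
opposing walls, each worth one point:

1. **early contraction** of the early-activated wall — an evident negative
   peak of the strain curve during ejection;
2. **prestretch** of the late-activated wall — early-systolic positive
   strain;
3. the early peak falling **within the first 70% of the systolic ejection
   phase** (only assessable when component 1 is present);
4. **peak contraction of the late-activated wall after AVC**.

The total over the three views is the RSPI; patients at or above **7
points** form the high-RSPI group. The binary Risum-style pattern label is
derived from the same bits: a view fulfils the *classical* (LBBB-related)
pattern when all four components co-occur there, and one such view suffices
for the patient-level label; otherwise the pattern is *heterogeneous*.
Response to CRT is the usual volumetric definition: a reduction of LV
end-systolic volume of at least 15% at follow-up (boundary inclusive).

## From visual criteria to a decision rule

The published criteria are visual; this package makes them operational and
deterministic. All timing is measured from QRS onset (time zero), and the
ejection length `E` is the interval from QRS onset to AVC, taken from the
beat's timing annotations (AVC is an input, never detected from the traces).

Traces are frame-rate limited, so every detector works on the samples
themselves — the curve is treated as piecewise linear and extremum positions
are not interpolated. Ties always break to the earliest sample.

* An "evident" shortening peak (component 1) is an **interior local minimum**
  of strain in `[0, AVC]` with two-sided topographic prominence of at least
  `contraction_prominence` (default **2% strain**). Prominence is the rise on
  each side before the curve next drops below the minimum (or the window
  edge); the smaller side counts. An end-systolic minimum at the window edge
  never qualifies: component 1 encodes a distinct peak with rebound, not
  ordinary end-systolic shortening. Because the criterion in the source
  material is ambiguous about whether a rebound is required, a permissive
  mode (`require_rebound = FALSE`) also accepts a "contraction movement"
  whose drop from the preceding maximum reaches the threshold.
* Prestretch (component 2) is a strain sample of at least
  `prestretch_threshold` (default **+1%**) within the first
  `prestretch_window_fraction` of ejection (default the first half).
* Component 3 compares the **earliest qualifying** early-wall peak against
  `0.70 * E`, inclusively. The 70% fraction is a fixed constant of the
  index; the constructor refuses to change it.
* Component 4 asks whether the late wall's **global** strain minimum over
  `[0, AVC + 0.4 * E]` falls strictly after AVC. A peak exactly at AVC is
  the synchronous norm, hence the strict inequality. How far past AVC to
  search is not fixed by the index definition; 40% of the ejection length
  comfortably covers physiologic post-systolic shortening and is
  configurable (`late_peak_search_frac`).

Wall aggregation is existential — any one qualifying basal or mid segment
sets a component — and the wall roles are fixed anatomically: septal/lateral
(4CH), anteroseptal/posterior (3CH) and anterior/inferior (2CH). The
2-chamber view has no septum, so the anterior wall takes the early role
there; since the classical-pattern criteria are defined on (antero)septal
walls, whether the 2CH view may satisfy them is a genuine judgment call. By
default it may (`pattern_in_2ch = TRUE`), the minimal consistent extension
of the rule to all three views; the restrictive behaviour is one flag away
and the result records which views were considered. A data-driven wall
assignment (`wall_assignment = "data_driven"`) swaps the roles when the
nominal late wall peaks first, for rhythms where the anatomical assumption
fails.

A wall whose traces never reach the contraction prominence — akinetic or
scarred myocardium — simply contributes nothing to its components. This is a
deliberate property of the index: dyssynchrony in the remaining viable
regions still accumulates points.

## Comparison indexes

The classical dyssynchrony parameters are computed from timing annotations
and tissue-velocity traces: the diastolic filling fraction LVDFT/RR (%),
the interventricular mechanical delay IVMD (aortic minus pulmonary
pre-ejection, ms), the septal-to-posterior wall motion delay from M-mode
displacement peaks (signed, not assessable on flat traces), the per-view and
overall maximal time-to-peak-velocity delays, and the Yu index (standard
deviation of the 12 basal/mid times to peak systolic velocity). Two
conventions required a choice. The Yu index uses the sample (n−1) standard
deviation, the convention of the time-to-peak literature; the population
form is an option. The "maximal opposing wall delay" is computed
level-matched (basal vs basal, mid vs mid within each view) since the
pairing is not otherwise defined; it is reported separately from the
any-pair maximum time delay, and is never larger.

## Cohort evaluation

`run_pipeline()` assembles per-patient scores into the
responder-by-high-RSPI 2×2 table, from which sensitivity, specificity,
predictive values and the diagnostic odds ratio follow; the odds-ratio
confidence interval is Wald on the log scale (Haldane–Anscombe +0.5
correction available for zero cells, off by default). The ROC is the
empirical curve over integer thresholds 0–13 (positive at score ≥
threshold); its trapezoidal area equals the probability that a random
responder outscores a random non-responder with ties counting one half, and
the reported cutoff maximizes Youden's J, resolving ties toward the larger
(more specific) threshold. Univariate logistic regression is fitted by
iteratively reweighted least squares to a 1e-10 tolerance; for a binary
predictor the fitted odds ratio coincides with the 2×2 cross-product ratio,
an identity the tests verify to 1e-6. Complete or quasi-complete separation
is flagged and no estimate is returned. Group comparisons use Mann-Whitney,
Wilcoxon signed-rank, Pearson χ², McNemar and Spearman wrappers, with exact
small-sample p-values where the null permits (both groups ≤ 10 untied
observations) and continuity-corrected normal approximations otherwise.
p-values are descriptive; no multiplicity correction is applied.

## The synthetic waveform generator

No strain cohort is distributed with the package, so every layer is
exercised against synthesized data. Waveforms are sums of linear ramps,
logistic ramps and Gaussian bumps on a 5 ms grid spanning 1.5 ejection
lengths — smooth shapes that can realize each of the 16 admissible
component-bit combinations exactly:

* early wall with component 1: steady shortening straight into a sharp peak
  at `early_peak_fraction * E` (0.45 by default, 0.75 when the peak must
  exceed the 70% limit), then a rebound of about 6% and a mild late drift;
* early wall without component 1: steady shortening to a deep end-systolic
  minimum (1.35 × the peak-strain parameter, about −20%) — the wall without
  a distinct early peak is modelled as the better-contracting one;
* late wall: a Gaussian shortening peak placed either 60 ms after AVC
  (component 4) or at 88% of the ejection phase, preceded by an optional
  +3% prestretch bump at 15% of ejection, with the background shortening
  drift starting after the prestretch window when a bump is present.

Default amplitudes are a −15% early peak and +3% prestretch on a
representative dyssynchronous beat (RR 860 ms, ejection 330 ms, IVMD
40 ms, filling fraction ≈ 41%). Noise is additive white Gaussian on the
samples, except at the QRS-onset sample, which is the strain reference
frame and therefore exactly zero. One design constraint deserves mention:
with per-sample noise of σ = 0.5% against a 2% prominence threshold, any
flat or slowly drifting stretch of curve will occasionally let noise
fabricate an "evident" peak. The shapes above therefore descend at a
roughly uniform, maximal rate wherever a spurious peak could change a
component — which is also why the peakless wall is given the deeper
minimum. At zero noise the scorer recovers every admissible bit pattern in
every view exactly; at σ = 0.5% the measured per-view recovery rate is
about 97%.

What the generator does **not** emulate: correlated (speckle-tracking
drift) noise, beat-to-beat variability and averaging, apical segments,
atrial-fibrillation cycle-length variation, and genuinely pathological
morphologies such as sustained akinesia with passive motion. Passing
round-trip tests therefore demonstrate that the decision rule implements
the stated criteria, not that those thresholds are clinically optimal on
vendor data.

Cohorts are generated either with exact counts for each
responder-by-high-RSPI cell — score targets are spread across views
(balanced, at most 4 points per view) and volumes are drawn consistently
with the responder label (reductions of 15–45% for responders, −20–14%
otherwise, baseline LVESV 120–260 mL, LVEF 18–32%) — or stochastically from
per-group high-RSPI probabilities. Everything is reproducible from a single
integer seed, and the helpers restore the caller's RNG state.

## Worked example

```{r example}
v4 <- make_view("4CH", c(1, 1, 0, 1), prestretch_amp = 2.5,
                early_peak_fraction = 0.75)
score_view(v4)

coh <- make_cohort(tp = 18, fp = 1, fn = 18, tn = 12, seed = 7)
res <- run_pipeline(coh)
res$diagnostics
res$roc
```

The first block reproduces a 4-chamber view in which the mid-septal peak
arrives just past the 70% limit (components 1, 2 and 4 present: 3 points).
The cohort call builds 49 zero-noise patients whose high-RSPI and responder
labels form the requested 2×2; the pipeline then recovers an odds ratio of
12, 50% sensitivity, 92.3% specificity and an optimal ROC cutoff of 7.

## Numerical and testing choices

Detectors are O(n) scans with deterministic tie-breaking; the test suite
checks them against independent brute-force oracles on randomly generated
traces, and checks the ROC area against an all-pairs concordance count, the
logistic odds ratio against the cross-product identity, and the
time-to-peak panel against an exhaustive-pair recomputation (1000 random
12-tuples). Simulation sizes in the tests — 200 noisy round-trip
replicates, 1000 oracle cohorts, 200 logistic recovery fits at n = 500 —
keep the full suite under a minute on a single core while leaving the
binomial margins wide enough to be meaningful.

## Known limitations

* AVC and the other timing landmarks are trusted inputs; no attempt is made
  to detect them from the curves.
* Scoring uses basal and mid segments only, as the index prescribes; apical
  traces are accepted by the data model but ignored by design.
* A single representative beat is assumed; the package does not average
  beats.
* The prominence (2%) and prestretch (+1%) thresholds operationalize a
  visual judgment. They are configurable, and the score is monotone in
  them — raising either can only lower the score — but their clinical
  calibration against expert readers is outside the package's scope.
* The Wald interval for the odds ratio is first-order; with cells as small
  as 1 it is approximate at best, which is visible in the worked example.
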