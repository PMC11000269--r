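---
title: "Methods: simulating and scoring short-window single-lead Holter analysis"
author: "holterscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and scoring short-window single-lead Holter analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holterscan)
```

## The question the package addresses

Premature supraventricular and ventricular contractions (PSVC, PVC) are
usually quantified by 24-hour Holter monitoring; the clinically used
positivity rule is a burden of at least 30 events per hour — 720 events per
24 h recording, or 60 per 2 h recording. A wearable single-lead patch worn
for only two hours is far more comfortable, but a 2 h window subsamples the
day's events, so its positivity call can disagree with the 24 h reference
purely through sampling variability, on top of any beat-classification
error. `holterscan` provides the full chain needed to study that trade-off
without any patient data: an annotated single-lead ECG simulator, a QRS
detector and beat segmenter, a one-dimensional residual convolutional
network that classifies beats into N/PSVC/PVC, frequency-based positivity
calling, and the paired diagnostic-efficiency statistics (sensitivity,
specificity, predictive values, ROC, Bland-Altman) used to compare the short
window against the long one.

## The synthetic ECG generator

**Beat morphology.** Each beat class is a sum of Gaussian bumps
$\sum_i a_i \exp\{-(t - c_i)^2 / 2w_i^2\}$ in mV, with one row per wave (P,
Q, R, S, T). This standard analytic morphology model gives exact control of
the two features that define the classes: the sinus template has a P wave at
−180 ms and an 80 ms QRS; the PVC template has no P wave, a 160 ms QRS
(twice the sinus width) and a discordant T; the PSVC template has the sinus
QRS width but no preceding P wave. Amplitudes are typical of a chest
(CM2/V2-like) lead.

**Rhythm.** Sinus RR intervals are `Normal(60/mean_hr, rr_sd)` truncated to
> 0.2 s. Premature events arrive as independent Poisson processes (events /
hour). A PVC replaces a sinus slot at a coupling interval of 0.60 of the
preceding RR and leaves the next sinus beat on its original grid, so the
pre- plus post-intervals sum to exactly two sinus cycles when `rr_sd = 0` —
the compensatory pause. A PSVC fires at 0.70 of the preceding RR and resets
the sinus clock — the non-compensatory pause. Both identities are asserted
by the test suite on every generated schedule. Adjacent premature slots
(couplets, bigeminy) are out of scope; collisions are dropped with a
message. The rendered record adds a sinusoidal baseline wander (default
0.10 mV at 0.25 Hz) and white noise (default 0.03 mV).

**Defaults.** 250 Hz sampling, 70 beats/min, 2 h duration: typical
ambulatory values that keep simulated records small. Coupling fractions 0.60
(PVC) and 0.70 (PSVC) are textbook-typical prematurity; all are
configuration fields.

**Count-level cohorts.** For paired-window questions the waveform is
irrelevant, so `simulate_cohort()` works directly on counts: the 24 h count
is Poisson(rate × 24) and the 2 h count is Binomial(24 h count, 2/24) — the
short window subsamples the *same* realisation, matching simultaneous wear.
By Poisson thinning the 2 h count is marginally Poisson(rate × 2), which the
tests verify by moment matching, and the probability of a positive 2 h call
at true rate $\lambda$ per hour has the closed form
$1 - F_{\mathrm{Pois}(2\lambda)}(59)$, the package's analytic oracle. The
default cohort emulates a 170-patient case-mix (115 negative controls, 24
PSVC, 23 PVC, 8 with both). No burden distribution is published for such
cohorts, so the per-patient rates are a declared stand-in: log-normal draws
truncated below 20/h for negative patients and above 40/h for positive
ones, keeping every patient's true rate on the correct side of the 30/h
boundary while leaving realistic spread. Per-patient sub-seeds are derived
from the master seed by a fixed counter scheme, so cohorts are reproducible
patient by patient.

## Beat detection and segmentation

Preprocessing is a zero-phase order-3 Butterworth band-pass, 0.5–40 Hz:
wide enough to keep P waves and QRS morphology, tight enough to remove
baseline wander (a 0.2 Hz drift is attenuated by well over 20 dB) and
high-frequency noise. Zero-phase filtering leaves R-peak locations in place.

QRS detection follows the classic energy-detector recipe: band-pass 5–15 Hz,
differentiate, square, integrate over a 150 ms moving window, then pick
integrated-energy peaks against adaptive signal/noise thresholds with a
200 ms refractory period and a search-back pass for long gaps. Thresholds
are initialised from quantiles of the candidate-peak heights, which makes
detection translation-equivariant (zero-padding a record shifts every
detection exactly). Each detection is refined to the local absolute maximum
of the input signal within ±60 ms, so reported indices sit on the R peak
itself. On clean synthetic records recall and precision are exactly 1 at
±20 ms; under 0.05 mV noise they stay above 0.99 at ±50 ms.

Segments span 0.25 s before to 0.45 s after each R peak — enough to show
the P-wave region (the PVC/PSVC cue) and the full QRS-T at rates up to
roughly 100 beats/min. Each segment is standardised to zero mean and unit
variance individually, so patch calibration and electrode gain cannot leak
into classification. Beats whose window crosses a record edge are dropped
and counted rather than padded.

The inter-beat-interval scattergram (`ibi_scattergram()`) plots each RR
interval against the next; a compensatory PVC appears as one point below
the identity line (short coupling interval, long pause) and one above it,
symmetric about the sinus point — a geometry the tests check exactly at
`rr_sd = 0`.

## The residual network

The classifier maps a standardised segment to probabilities over
{N, PSVC, PVC}. It has eight residual blocks; each block is

> convolution → batch norm → ReLU → convolution → batch norm

added to a 1×1-convolution projection of the block input, with ReLU
between blocks, and a head of global average pooling over time followed by
one fully connected layer and a softmax. Both in-path convolutions use a
length-3 kernel with stride 1 and same padding, so every block preserves
the temporal length — a requirement for the residual addition. For a
single-lead series a "3 × 3" kernel degenerates to length 3 along time;
the kernel length is a configuration field, so a genuinely two-dimensional
variant could be swapped in for multi-lead data. Channel width (default 32;
experiments in this package use 16 or less, see *Problem sizes*), loss
(categorical cross-entropy), optimiser (Adam, learning rate $10^{-3}$) and
epochs are configuration choices, as no reference values exist for them.

Implementation notes, since the network is implemented directly on BLAS
matrix products with small compiled kernels for the memory-bound steps: the
time axis of a batch is unrolled into rows, a length-k convolution is one
wide matrix product followed by a fused shift-accumulate, and at inference
the batch-norm affine is folded into the convolution weights. The backward
pass is exact (the test suite checks analytic against finite-difference
gradients to ~1e-9 relative error). Two initialisation choices matter for
trainability at this depth: projection shortcuts start as the identity
(where shapes allow), so activation variance grows linearly rather than
exponentially with depth, and the final dense layer starts small so the
softmax is unsaturated at initialisation. Probability ties at prediction
resolve to N, the conservative non-event call.

Datasets are split by *patient* in an 8:1:1 ratio — no patient contributes
beats to more than one of train/validation/test, which the fit function
asserts rather than assumes. The parameters with the best validation loss
are retained. Training fails loudly if a class is absent from the training
patients.

## Burden calls and diagnostic statistics

A window's event count is compared against the inclusive thresholds 60 per
2 h or 720 per 24 h (both 30/hour; the constructor asserts the identity,
and the boundary is tested by exhaustive sweep). Other window lengths fall
back to a pro-rata ceiling threshold with a logged warning — an extension,
used only by scaled-down experiments.

With the 24 h calls as reference standard, the per-condition confusion
table gives sensitivity $tp/(tp+fn)$, specificity $tn/(tn+fp)$,
PPV $tp/(tp+fp)$ and NPV $tn/(tn+fn)$, reported as percentages rounded to
two decimals, half away from zero (detection rates round to one decimal).
Confidence intervals are Wald by default with clipping to [0, 100]; Wilson
intervals are available behind a flag. Wald is a declared choice — published
two-decimal tables of this kind rarely state their CI method, and
reconstructed cells generally match no standard method exactly, so CI
bounds are never treated as reproduction targets here.

Patients reference-positive for *both* conditions can either count as
positive for each condition (the default) or be excluded before tallying
(`exclude_dual_positive = TRUE`); the bundled 170-patient reconstruction
uses the exclusion convention because the published group denominators
(19/24 and 21/23) are single-condition groups. How the eight test-positive
negative-control patients split between PSVC and PVC false positives is not
published; the bundled split (6 PSVC / 3 PVC, one patient positive for
both) is inferred from the predictive values and documented as a
reconstruction.

The ROC uses the 2 h event count as the continuous predictor against the
24 h reference call — a declared choice, as summary tables do not identify
the thresholded quantity. The empirical curve sweeps all distinct counts;
the trapezoid area equals the pairwise concordance probability with ties
counted ½, which the tests verify against a brute-force all-pairs oracle to
1e-12. The AUC interval uses the Hanley–McNeil standard error. Bland-Altman
agreement is computed on the events-per-hour scale (24 h count / 24 versus
2 h count / 2) so the two windows are commensurate; limits of agreement are
mean ± 1.96 SD with the n−1 denominator.

## Problem sizes used by the tests and the acceptance script

The test suite trains on pooled segments from six 8-minute synthetic
recordings and runs one full-scale experiment: twenty 2-hour recordings
(about 168 000 beats) through detection, patient-disjoint training on a
class-balanced subsample, classification of every detected beat, and
positivity calling. The width-16 network and 15 training epochs are the
package's desk-scale defaults for this experiment; they recover held-out
beat labels essentially perfectly on clean synthetic data, and wider models
change nothing about the scientific conclusions while costing
proportionally more time. The acceptance script runs a ten-patient,
30-minute variant of the same experiment plus the count-level analyses at
10 000 simulated patients.

## What passing tests do and do not show

The simulator produces cleanly separable beat morphologies, stationary
noise, and homogeneous Poisson event streams. Real recordings add electrode
artefacts, non-stationary baseline, morphology drift, circadian burden
structure, couplets/bigeminy and rarer rhythms, none of which are modelled.
A pipeline that is perfect here can therefore only be said to implement the
method correctly — recovery results on this generator are upper bounds, not
clinical performance estimates. Conversely, the *sampling* component of
short-window disagreement (the Poisson tail behaviour near the 30/h
boundary, the degradation of 2 h vs 24 h agreement for near-threshold
patients) is exact in the count-level model and is the part of the analysis
most transferable to real cohorts.

## Known limitations

* Single lead only; the 2-D kernel toggle exists but no multi-lead
  templates are provided.
* The premature-beat model excludes couplets, runs, atrial fibrillation and
  conduction disease; the schedule model drops colliding premature events.
* The QRS detector's thresholds are tuned for the simulator's amplitude
  regime; real-device artefact classes (electrode pop, saturation) are not
  handled.
* Confidence intervals are Wald/Wilson only; no exact or bootstrap
  intervals.
* Published AUC values and CI bounds for this design are not recomputable
  from group-level summary counts, because the underlying per-patient
  predictor and the CI method are not identifiable from them; the package
  therefore checks its ROC and interval machinery by construction (oracle
  equivalence, coverage of the point estimate) rather than against printed
  values.
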