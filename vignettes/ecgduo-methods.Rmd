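---
title: "Two-way 12-lead ECG classification: models, data and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-way 12-lead ECG classification: models, data and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Standard 12-lead electrocardiography records 2.5 s of each of the 12
leads laid out in a 3 x 4 grid, plus a continuous 10-s lead II rhythm
strip. Clinically the same information circulates in two forms: the
digital signals themselves, and paper plots of them — increasingly
photographed with a phone. `ecgduo` implements a two-way classification
pipeline over both forms: per-condition binary convolutional
classifiers for nine classes (normal sinus, AF, I-AVB, LBBB, RBBB, PAC,
PVC, STD, STE), one trained on digital records (CNN-dig) and one on
rendered plot images (CNN-ima), together with the full data machinery:
standard-record construction, HDF5 storage, patient-disjoint splitting,
ECG-paper rendering, camera-acquisition simulation, and an evaluation
suite.

Because clinical 12-lead corpora cannot be bundled, the package ships a
seeded synthetic generator whose nine classes are separable by
construction. Everything downstream is exercised end to end on it.

## Standard records

A recording (12 x N samples at 500 Hz, 6–60 s) is cut into consecutive
10-s segments with no overlap; a trailing remainder shorter than 10 s
is discarded and recordings under 10 s are omitted entirely. Each
segment yields four standard records: record *w* (*w* = 0..3) pairs the
*w*-th 2.5-s slice of **all twelve** leads with the segment's full 10 s
of lead II. The four sibling records therefore share their long lead,
and their short blocks partition the segment exactly. Labels are
length-9 one-hot vectors in the fixed order Normal, AF, I-AVB, LBBB,
RBBB, PAC, PVC, STD, STE; several bits may be set.

Two conventions are ours and documented as constants: the row order of
every signal matrix is I, II, III, aVR, aVL, aVF, V1–V6 (lead II is
row 2), and the HDF5 store keeps samples as 32-bit floats with 8-bit
label entries. At float32 precision read(write(x)) is exact with
respect to the stored values, and a write/read cycle is idempotent
bit for bit.

Splitting is by whole patients, never by records: patients are shuffled
under the seed and assigned greedily to the holdout partition until its
target record fraction (default 0.17) is reached, then the remaining
development records are split the same way into training and internal
validation (default 0.05 of development). Exact fractions are not
achievable at whole-patient granularity; with ≥ 50 patients the
achieved fractions land within about two percentage points of target.

## The synthetic generator

Beat morphology is a sum of Gaussian bumps — P, Q, R, S, T — on a shared
time base, projected to the twelve leads by fixed per-lead gain vectors;
QRS complexes carry their own polarity vector so that conduction-block
patterns can be expressed. Each synthetic patient draws one template and
rhythm profile, reused across all of that patient's recordings, which is
what makes patient-disjoint splitting meaningful. One master seed feeds
a splittable per-patient stream; identical arguments give bit-identical
signals.

Class signatures follow the usual clinical definitions, expressed as
construction rules:

* **AF** — i.i.d. RR intervals (lognormal, CV drawn in 0.20–0.30), zero
  P-wave amplitude, and a 4–9 Hz fibrillatory baseline of ~0.05 mV
  built from eight random sinusoids per lead.
* **I-AVB** — PR interval drawn in 0.22–0.28 s (sinus default
  0.14–0.19 s).
* **LBBB / RBBB** — QRS duration 0.13–0.15 s with opposite dominant
  deflection patterns: LBBB positive lateral (I, aVL, V5, V6) and
  negative right-precordial (V1–V3); RBBB the reverse.
* **PAC / PVC** — ectopic beats at ~0.6 x mean RR coupling followed by a
  compensatory pause (insertion rate 0.15 per beat); PAC keeps the P
  wave and a narrow QRS, PVC drops the P wave, widens the QRS to
  0.13–0.15 s and inverts its polarity in the inferior leads.
* **STD / STE** — an ST-plateau offset of −0.12..−0.20 mV in II, V5, V6
  (STD) or +0.12..+0.25 mV in V1–V3 (STE), i.e. at least 0.1 mV in at
  least two leads.
* **Normal** — none of the above; |ST| < 0.05 mV, PR < 0.20 s,
  QRS < 0.12 s.

Disease effects compose additively (AF + PVC = irregular RR plus wide
inverted ectopics); Normal never co-occurs with a disease. A rule-based
measurer reads the generator's internal beat annotations — not the raw
signal — and confirms the defining feature of every label on every
generated record; this is the label-faithfulness property the tests
enforce.

What the generator does *not* emulate: electrode artifacts, baseline
wander, muscle noise, inter-lead timing physiology, or any realistic
covariance between conditions. Classes are separable **by
construction**, so a classifier that is perfect here says nothing
quantitative about clinical data; passing tests demonstrate that the
pipeline's machinery (data handling, rendering, training, evaluation)
is correct, not that the reported clinical accuracies are reproduced.

## Rendering and camera simulation

All plot geometry derives from one constants block: standard ECG paper
at 25 mm/s and 10 mm/mV, 1-mm small boxes (0.04 s), rasterized at
5 px/mm onto a fixed 675 x 1450 x 3 canvas. The 0.2-s calibration pulse
plus 10 s of trace span 10.2 s = 255 mm = 1275 px; the remaining 175 px
are margins and label gutters. Rows 1–3 hold the four 2.5-s panels in
the conventional clinical order (I, aVR, V1, V4 / II, aVL, V2, V5 /
III, aVF, V3, V6); row 4 is the rhythm strip. Every row starts with a
1-mV, 0.2-s calibration pulse, and each panel carries a small bitmap
lead label in dark gray.

Traces are crisp 2-px polylines rasterized column-wise **without**
anti-aliasing. That choice is deliberate: the geometry oracle
(`measure_trace()`) identifies exact trace-colored pixels and recovers
amplitude to the pixel quantum (0.02 mV at 5 px/mm) and duration to
about one column (0.008 s), well within the suite's ±0.05 mV / ±0.02 s
bounds, which an anti-aliased trace would blur. The grid is drawn in
two reds (light minor, darker major) on white — the classifiers are
template-agnostic, so colors are plain constants.

Camera acquisition is simulated as a random projective warp over a
procedural background. Each canvas corner is jittered uniformly within
±8 % of the corresponding dimension (configurable up to 25 %) and the
3 x 3 homography solving the 4-point correspondence exactly is applied
by inverse mapping with bilinear interpolation; output pixels whose
preimage falls outside the plot take the background. Backgrounds are
procedural (flat, speckle, cloth, wood grain from directionally
smoothed noise) rather than photographs so that runs are reproducible
with no assets. Degenerate corner draws are resampled internally.

The warp-inverse-warp round-trip bound (mean absolute error below
3/255) is an *interpolation* bound and is checked on band-limited
images (the procedural textures). A rendered plot contains
single-pixel black/white edges whose double resampling necessarily
averages tens of intensity levels at edge pixels regardless of the
interpolator; on such content the mean error is dominated by edge
density, not by warp correctness.

## The classifiers

Both networks are stacks of convolution → per-batch statistics
normalization → ReLU → dropout blocks, all convolutions with stride 2,
followed by flattening and a fully connected head ending in a single
sigmoid output P ∈ [0, 1]. CNN-dig is dual-branch: six blocks with
kernel length 17 over the 12 x 1250 short block and eight blocks over
the 1 x 5000 long lead (thirteen input signals in total — lead II
enters twice by design); the two feature vectors are concatenated
before the head. CNN-ima is a single stack of seven 7 x 7 blocks over
the 675 x 1450 x 3 image. One model is trained per condition, so a
panel emits nine independent probabilities per record with no softmax
coupling — this is what makes the system multi-label and extensible.

Choices the architecture description leaves open, fixed here as
defaults:

* **Padding.** All convolutions use symmetric zero padding of half the
  kernel. Unpadded stride-2 convolutions are geometrically impossible
  for a depth-7 stack of 7 x 7 kernels on 675 rows (the map shrinks
  below the kernel after six layers), and one padding rule for both
  networks keeps feature-map sizes reproducible:
  `out = floor((n - 1)/2) + 1`.
* **Channel widths** double from 16 and are capped at 256; an uncapped
  8-block doubling run would put tens of millions of parameters into a
  single layer. Dropout is 0.1 per block; the fully connected hidden
  layer has width 64. All are spec-object fields.
* **Training** uses Adam at learning rate 1e-4 (from the tested set
  1e-3..1e-6) with binary cross-entropy, batch size 256 (digital) or
  150 (image), at most 100 epochs. After every epoch the model is
  evaluated on the validation set; the checkpoint with the lowest
  validation loss is kept, and training stops after 10 (CNN-dig) or 5
  (CNN-ima) consecutive epochs without improvement. Validation loss is
  the monitored quantity; the seed drives initialization, shuffling and
  dropout, so runs are reproducible. With the tie rule documented in
  the evaluation module, P = 0.5 classifies as positive.

Convolutions are compiled (im2col + GEMM); everything else is plain R.
A numerical-gradient check in the test suite pins the backward pass of
every layer type to the analytic gradients at ~1e-10 relative error.

## Evaluation

The binary counts are kept both as integers and in their fractional
rate forms (detected/present, etc.), for which TP + FN = 1 and
TN + FP = 1 whenever the denominators are non-zero. Sensitivity,
specificity, PPV, NPV, accuracy and F1 follow the standard formulas; a
ratio with a zero denominator is reported as `NA` — never imputed as
zero, which would silently corrupt averages. ROC curves sweep the
unique scores plus sentinels so the curve always runs from (0,0) to
(1,1); AUC uses the trapezoidal rule and equals the Mann–Whitney
pairwise-concordance statistic, which the tests verify exhaustively at
small n. The 9 x 9 confusion matrix is restricted to records with
exactly one annotated *and* exactly one predicted class, and reports
how many records the restriction excluded.

The accuracy-versus-training-size analysis retrains a reduced-width
CNN-dig on nested subsets, evaluates accuracy on one fixed test set,
and fits y = a·sin(b·x + c) by multi-start Levenberg–Marquardt least
squares with a ∈ (0, 1] and b > 0. Two numerical decisions matter with
sparse size grids. First, b is bounded above so the phase advances at
most half a period between adjacent sample points — without this
Nyquist-style identifiability bound, arbitrarily fast sines interpolate
any three points exactly and the "fit" is pure aliasing. Second, ties
in residual sum of squares are broken toward the smallest b: when
several sines fit equally well, the smoothest is the identifiable
choice. A near-zero-frequency start guarantees the fit is never worse
than the best constant model.

## Scaled-down study sizes

The test and acceptance runs use problem sizes chosen so the whole
suite executes on a single CPU: CNN-dig learns AF-vs-Normal on 2,000
synthetic standard records (125 patients, reduced channel width 8,
learning rate 1e-3, six epochs) and CNN-ima on 300 quarter-resolution
rendered plots (168 x 362 x 3, width 4, learning rate 2e-3, twenty
epochs — the small 2-D net needs a longer optimization than its
full-width counterpart). Both reach held-out AUC 1.0 on the generator's
separable classes.

For the size sweep, the target condition is PAC rather than AF: AF's
signature (global RR irregularity plus the fibrillatory baseline)
saturates a classifier already at ~100 records, leaving no size effect
to fit, whereas PAC detection hinges on a few early beats per strip and
keeps improving across 100 → 500 → 2,000 training records, which is
the regime the sine-fit analysis is about.

## Known limitations

* Synthetic classes are caricatures; no claim transfers to clinical
  recordings (see above).
* The renderer draws one fixed template family; it does not reproduce
  any particular commercial ECG paper, nor PDF/print pipelines.
* The camera model covers perspective and background only — no lens
  distortion, motion blur, shadows, glare or compression artifacts.
* The CNN engine is single-CPU, double-precision R/C++; it is meant for
  correctness and moderate scale, not GPU-class throughput.
* With whole-patient greedy splitting, very small cohorts can deviate
  noticeably from target split fractions.
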