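---
title: "Reconstructing and recognizing EOG eye-writing: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing and recognizing EOG eye-writing: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eyescript)
```

## The problem

The electrooculogram (EOG) is the voltage measured by electrodes placed
around the eyes. It arises from the corneo-retinal standing potential and
varies approximately linearly with gaze angle over moderate ranges, so a
four-electrode montage — left and right of the eyes, above and below one
eye — tracks gaze continuously without a camera. *Eye-writing* exploits
this: a user traces the shape of a character with a sequence of saccades,
and the system reconstructs the gaze path and classifies it as one of ten
simplified Arabic-digit patterns. The intended users are people with
amyotrophic lateral sclerosis (ALS), for whom eye movement is often the
last reliable motor channel.

`eyescript` implements the complete chain: signal conditioning, blink
handling, saccade detection, reconstruction of a normalized 2-D writing
trace with calibration-free crosstalk removal, template classification by
dynamic time warping (DTW) or dynamic positional warping (DPW), optionally
combined with a support vector machine (SVM), and leave-one-subject-out
(LOSO) evaluation. A ground-truth-annotated simulator generates
four-channel EOG so every stage is testable without recorded data.

## Signal model and preprocessing

A recording holds `n x 4` samples in microvolts at a sampling rate
(2048 Hz in the acquisition setup the simulator emulates). Preprocessing
follows a fixed order:

1. **Downsample to 64 Hz** with a zero-phase FIR low-pass (windowed sinc,
   cutoff at 90% of the target Nyquist, unit DC gain, reflection-padded to
   suppress start-up transients), then **median filter** (31 ms window,
   3 samples at 64 Hz) to remove impulsive noise without blunting saccade
   edges.
2. **Blink detection** on the vertical bipolar channel (below).
3. **Baseline removal** per channel: subtract the median of the 100 ms
   preceding the writing epoch (the first 100 ms of the record when no
   epoch marker exists). A median resists outliers in the reference
   window.
4. **Bipolar derivation**: horizontal = right − left, vertical = above −
   below, cancelling common-mode potentials.
5. **Blink-gap interpolation**: samples inside each blink interval are
   replaced by the straight line joining the neighbouring clean samples.
6. **Drift removal**: subtract the ordinary least-squares line fitted over
   the whole epoch. One linear fit is intentional — the target artifact is
   slow electrode drift (a few microvolts per second), and anything more
   adaptive would start absorbing the writing itself.

Note that the epoch-level line fit does absorb a little of the writing's
net trend; a long pre-writing fixation (the writing protocol holds a
fixation mark for three seconds before each pattern) anchors the fit on
stationary data and keeps that distortion small.

## Blink detection

Blinks are large transients (typically 200–400 µV) on the vertical
channels that must be excised before saccade detection. The detector here
is the package's own design, built from first principles:

- A **multi-scale edge filter**: at each candidate width `W` (100, 150,
  200 ms) the response is the mean over the window just after a sample
  minus the mean just before it; the scale with the largest absolute
  response is kept. A blink produces a pronounced maximum (rising lid)
  followed by a minimum (falling lid); drift produces a near-constant,
  tiny response.
- **Pairing**: each local minimum below `−k·MAD` is paired with the
  nearest preceding local maximum above `+k·MAD` within 500 ms (`k = 6`,
  with a 30 µV absolute floor so noise-free recordings do not degenerate
  to a zero threshold). An isolated saccade step produces only one
  extremum and can never form a pair.
- **Two physiological vetoes**, needed because an up-stroke followed by a
  down-stroke within 500 ms also forms a max–min pair:
  - *Baseline return*: the eyelid returns to rest, so a blink's net
    pre-to-post level shift is small relative to its peak excursion; for a
    saccade sequence the two are comparable. Candidates with a shift above
    0.85 of the excursion are rejected (on simulated writing the two
    populations separate at ≤ 0.83 vs ≥ 0.91).
  - *Apex dwell*: a blink spends only about a third of its duration near
    its apex, whereas a saccade–fixation–saccade excursion holds its apex
    level for a full fixation (≥ 200 ms). Candidates dwelling above 70% of
    the apex deviation for more than 150 ms are rejected.
- **Support trimming**: the accepted interval (from the maximum minus `W`
  to the minimum plus `W`) is trimmed to the region where the signal
  actually deviates from the local baseline. Without trimming, the
  interpolation step removed neighbouring saccades along with the blink,
  which was by far the largest source of classification errors in
  simulation.

A blink that lands *on* a saccade of comparable amplitude is not
identifiable by any amplitude-based detector; such collisions are the main
residual error source and are visible in the simulator studies.

## Saccade detection

Saccades appear as steps in the bipolar components. The continuous wavelet
transform with a Haar mother wavelet responds maximally to steps: the
coefficient at position `b` and scale `a` is the scaled difference between
the sum of the half-window after `b` and the half-window before it. The
scale is fixed at 20 samples, the standard choice for EOG at this rate. A
sample is saccadic when the absolute coefficient exceeds a threshold
`theta` on the horizontal *or* vertical channel — the union, so oblique
strokes trigger on either. Runs separated by fewer than 2 samples are
merged and runs shorter than 2 samples dropped (mask hygiene; thresholds
this small never remove a true saccade at scale 20).

The default `theta = 120` sits at the robust center of the method's
operating range; `derive_threshold()` reproduces the data-driven
alternative: annotate saccadic regions on calibration epochs, summarize
each region by its peak absolute coefficient, and take the minimum across
regions — the largest threshold that would still detect every annotated
saccade. (Taking the literal minimum coefficient *within* a region would
always return the near-zero value at the region's edge, so the
region-peak reading is the only usable one.) `threshold_sweep()` exposes
the sensitivity of end-to-end accuracy to this choice.

## Trace reconstruction and crosstalk removal

The trace is the `(h, v)` sample sequence restricted to saccadic segments
— fixations carry no shape information and the digit templates contain
none. It is resampled to 128 points at equal arc-length spacing (so
point-to-point comparisons do not depend on writing speed; 128 gives the
densest template more than 10 points per stroke) and normalized so width
and height are exactly one. Aspect ratio is deliberately not preserved;
the templates receive the same treatment.

Electrode placement is never perfectly symmetric, so part of the
horizontal component leaks into the vertical one:
`v_observed = v_true + alpha * h`. The compensation subtracts
`alpha * x` from `y`. The coefficient is estimated *without calibration
data* from the epoch's own trace: differentiate both coordinates with the
central difference `s(t+1) − s(t−1)` (removing levels and drift) and take
the OLS slope of `dy` on `dx`. By construction the compensated differences
have exactly zero regression slope, so the procedure is a fixed point:
re-estimating on the compensated trace returns zero.

Two caveats, both consequences of the estimator's identifying assumption
(that intended writing has no net correlation between horizontal and
vertical increments):

- Shapes dominated by one oblique stroke (e.g. the digit-7 diagonal) have
  an inherent nonzero difference-space slope, which the estimator removes
  along with the true crosstalk, shearing the trace slightly. Because the
  distortion is consistent within a class and both warping measures
  compare local increments, classification is barely affected.
- The estimate lives in unit-box coordinates. The physical coefficient is
  recovered by rescaling with the raw vertical/horizontal extent ratio;
  `reconstruct()` reports both (`alpha`, `alpha_physical`). On
  axis-aligned patterns the physical coefficient is recovered to within
  ±0.05 across the ±0.4 operating range at trace-level noise of 0.01
  (noise in the differentiated abscissa attenuates the slope slightly
  toward zero — ordinary errors-in-variables shrinkage, about 10% of
  `alpha` at that noise level).

## Classification

Both dissimilarity measures operate on local increments (derivative form),
which makes them insensitive to residual offsets. The admissible warp
steps are `{(1, m), (m, 1) | 1 <= m <= M}` with `M = 8` by default (about
6% of the 128-point sequence, conventional slope-constraint territory).
Two-dimensional increments are compared with the L1 norm across axes (an
L2 option is provided); predecessor indices clamp at the first sample and
the origin cell costs zero.

- **DTW** always takes increments with respect to the immediate
  predecessor in each sequence and adds the cheapest admissible
  predecessor cell.
- **DPW** takes the increments with respect to the predecessor selected by
  the warp step itself, so warping acts on the value axis as well as time,
  and minimizes the increment cost and predecessor cost *jointly*. The
  joint minimization is a deliberate design decision: selecting the step
  by predecessor cost alone and paying the increment cost afterwards makes
  the measure anti-robust — under i.i.d. point noise of SD 0.01 the
  within-class dissimilarity exceeds between-class template distances,
  inverting the measure's purpose — whereas the joint form behaves as
  value-axis warping should. On 200 skewed/scaled digit variants the
  within-class to between-class mean ratio is 0.56 for DPW versus 0.83 for
  DTW.

The plain classifier assigns the nearest template (ties break to the
lowest digit, a documented determinism rule). The combined classifier
turns the ten dissimilarities into a feature vector, dividing each by its
class's normalization factor — the mean dissimilarity of training traces
of that class to their own template — and trains a linear one-vs-one SVM
(cost 1) on these 10-dimensional features. Features are measure-matched:
a DPW classifier uses DPW dissimilarities only. Linear is the defensible
default for 10-dimensional features from a few hundred training epochs;
the regularization constant matters little there.

## Evaluation

`loso_evaluate()` holds out one participant per fold, refits normalization
factors and the SVM on the remaining participants, and tests on the
held-out one; templates are canonical and never refitted. Dissimilarities
to the ten templates are computed once and shared across folds.
Participants named in `holdout` are tested but never trained on (the
pattern used for patient groups whose data must not enter the models).
Accuracy is reported overall (pooled) and per participant — the pooled
value equals the attempt-weighted mean of the per-participant values, and
both conventions are inspectable in the report. Per-digit precision,
recall, and F1 come from the pooled confusion matrix; a zero denominator
is reported as 0 with an explicit `defined = FALSE` flag so tables stay
rectangular. Failed reconstructions count as attempts and therefore as
errors, never silently dropped.

## The synthetic generator

`simulate_epoch()` drives gaze through a template's waypoints with
logistic-sigmoid saccades (60 ms default — smooth, two-parameter, a
reasonable stand-in for saccadic velocity profiles without a full
main-sequence model) separated by 250 ms fixations, with a 3 s lead
fixation mirroring the writing protocol and a 500 ms tail. The ideal
components are the amplitude-scaled gaze coordinates (80 µV per grid unit
by default); the emitted vertical component adds `alpha * h`. Channels
split each component symmetrically on top of fixed electrode offsets,
then per-channel linear drift (slope uniform in ±3 µV/s), Gaussian noise
(5 µV SD), and Poisson-placed blinks (rate 0.5/epoch, 300 µV, 300 ms,
raised-cosine on the above-eye channel with a 20% negative counterpart
below — producing the max-then-min filter signature of a real blink) are
applied. All randomness flows from one seed through deterministic
subject/trial/epoch streams.

`simulate_cohort()` draws subject-level parameters once per participant —
amplitude and stroke timing ±20%, noise ±30%, `alpha` uniform in ±0.2
(moderate physiological crosstalk; the operating range of the estimator is
tested separately to ±0.4) — and emits 3 trials × 10 digits per
participant, matching the validation design of 18 participants.

What the simulator does *not* emulate: EMG/EEG contamination, mains
interference, microsaccades and high-frequency ripples (a documented error
source in real recordings), electrode pops, head movement, or the slowed
saccades of oculomotor-impaired users (only exposed as the saccade
duration parameter). Passing the simulation studies therefore shows the
pipeline is correct under its stated signal model, not that it reaches any
particular accuracy on human recordings.

## Validation scale and numerical choices

The test suite and the acceptance script validate at these problem sizes:
oracle equivalence of the dynamic programs on all trace-pair lengths up to
6 with `M` up to 3 (against memo-free recursive evaluation) and of the
Haar transform on signals up to 200 samples (against direct inner-product
loops, 1e-9); crosstalk recovery over `alpha` in {−0.4 … 0.4} × 50 traces;
event recovery on 100 epochs at default noise; and a full 540-epoch LOSO
cohort. The cohort run dominates the cost (a few minutes on one core).

Degenerate inputs have defined behavior throughout: an empty saccade mask
raises a degenerate-trace error naming the stage; a zero-extent axis
normalizes to 0.5; a vertical-only trace (no horizontal variance) makes
the crosstalk estimator refuse rather than divide by zero; zero-denominator
metrics are flagged, not dropped; blink intervals touching a signal
boundary hold the nearest valid value. Ties in the warp arg-min take the
first step in the documented enumeration order, so results are
bit-reproducible.

## Known limitations

- The crosstalk estimator is biased on shapes that violate its
  balanced-stroke assumption; the bias is class-consistent and mostly
  harmless for classification, but `alpha_physical` from a single oblique
  digit should not be read as a calibration measurement.
- Blinks overlapping saccades of comparable amplitude are unresolvable in
  principle for amplitude-based detection; they are the residual error
  mode.
- The epoch-level linear drift fit removes a small part of the writing's
  net trend when the epoch lacks a stationary lead.
- Templates are transcriptions of the published pattern designs onto the
  integer lattice; stroke proportions of the originals are approximated,
  not measured.
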