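---
title: "Quantifying interpersonal movement coordination with duetsync"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying interpersonal movement coordination with duetsync}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

When two musicians improvise together, their ancillary body movements —
sway, head nods, torso leans — intermittently fall into visible
correspondence. Expert observers label such episodes as *bouts of
interaction*. `duetsync` quantifies the movement evidence for these bouts
from ordinary video (25 fps) and asks how well frame-wise movement and audio
features predict them.

The package covers the full chain: video region-of-interest (ROI) tracking
into movement traces, preprocessing into a radial movement signal,
wavelet and cross-wavelet analysis, annotation agreement and aggregation, a
twelve-predictor feature table, and classification with logistic regression
and random forests. A coupled-oscillator dyad simulator generates every kind
of input the pipeline consumes, so the whole chain is testable without any
recordings.

## The movement signal

Each performer's upper body is enclosed in an ROI (0-based pixels, origin
top-left, half-open on both axes — every interval in the package, in time or
space, is half-open). Per frame, the greyscale intensity-weighted centroid
(barycentre) of the ROI gives coordinates $(x_t, y_t)$. These are smoothed
with a Savitzky–Golay filter (order 3, window 5 frames), converted to polar
coordinates about the trace's time-mean position, and reduced to the radial
coordinate $\rho_t$, which is linearly detrended and min–max normalized to
$[0, 1]$.

Two choices here were genuinely open:

* **Polar origin.** The pole of the polar conversion is the trace's
  time-mean position. A per-window origin would leak non-stationarity into
  $\rho$; a fixed frame corner would make $\rho$ depend on where the ROI
  happens to sit. The time-mean is stationary and translation-invariant
  (shifting the scene leaves $\rho$ unchanged, which the tests check).
  A consequence worth knowing: motion that is perfectly circular about that
  origin has constant $\rho$ and is invisible to the radial signal, and any
  *zero-mean, half-wave-antisymmetric* oscillation through the origin
  appears in $\rho$ at twice its frequency. Real sway is asymmetric and
  rides on a wandering base position, so in practice $\rho$ keeps the sway
  fundamental; the simulator reproduces exactly those two properties (a
  second-harmonic component and slow positional wander) for the same
  reason.
* **Quantity of motion (QoM).** Frame differencing with adaptive background
  subtraction is implemented as: a pixel counts as *motion* if it is
  foreground against a running exponential background (learning rate 0.05
  per frame) *and* changed by more than the threshold (default 0.1 in
  normalized intensity) since the previous frame; QoM is the fraction of
  ROI pixels that count. Normalizing by ROI area makes differently sized
  ROIs comparable; raw counts are available.

## Wavelet and cross-wavelet analysis

The analysis engine is a continuous Morlet wavelet transform with centre
frequency $\omega_0 = 6$ (the conventional default, which makes frequency
$f \approx \omega_0 / (2\pi s)$ for scale $s$; that mapping is used
exactly). The analysis grid is log-spaced at 20 voices per octave over
0.3–2.0 Hz for movement — the range of musically plausible ancillary
movement at 25 fps — and 0.25–10 Hz for the audio envelope.

The wavelet is normalized so that a unit-amplitude sinusoid produces unit
coefficient modulus at its matching frequency row regardless of scale. This
amplitude-preserving convention makes amplitude profiles comparable across
frequencies and gives "energy" (squared modulus) a direct amplitude²
reading. The FFT-accelerated transform zero-pads past the truncated kernel
support, so it equals direct time-domain convolution with the sampled
kernel to numerical precision — the test suite carries an explicit $O(n^2)$
convolution oracle for this.

For two performers with transforms $W_a, W_b$, the cross-wavelet transform
is $W_{ab} = W_a \overline{W_b}$. Its modulus measures co-occurring
spectral energy; its argument is the relative phase (positive when the
first performer leads — a quarter-period delay of the second performer
reads $+\pi/2$). **Energy** is defined as $|W_{ab}|^2$ after Bartlett
(triangular) smoothing along time with a 1 s window; **phase** is taken
from the unsmoothed product by default (both choices are configurable —
the original analysis pipeline does not pin them down, so both variants
are exposed and the defaults documented here). The cone of influence marks
samples within $\sqrt{2}\,s$ (the wavelet envelope's e-folding time) of
either edge; band summaries can mask it, but the default policy is `keep`
because the predictor pipeline instead trims 5 s from each recording end,
which covers the cone at every analysis frequency.

Band summaries: `band_energy` is the per-time mean energy over the grid
rows in $[f_{lo}, f_{hi})$; `band_phase` is the energy-weighted circular
mean phase. The five narrow predictor bands have centres 0.3, 0.4, 0.6,
0.9 and 2.0 Hz; only the centres are canonical, so the edges are geometric
midpoints of adjacent centres with outer edges 0.26 and 2.3 Hz — the
log-symmetric rule, recorded in the table metadata. The same rule builds
the seven co-occurrence bands (0.29–2.00 Hz) used for the joint density of
the two performers' dominant frequencies (ties in the per-column argmax
resolve toward the lowest frequency).

## Audio features

The envelope is the block-mean rectified waveform at 100 Hz, onset-
emphasised by mixing the half-wave-rectified envelope difference with the
plain envelope as $(1-\lambda)\,\mathrm{hwr}(\Delta e) + \lambda e$ with
$\lambda = 0.1$, then Gaussian-smoothed with $\sigma = 3$ envelope samples.
The one-line published description of this step is ambiguous about the
mixing convention; the formula above is fixed and covered by tests.

Three envelope features feed the predictor table: sliding RMS (1 s window),
broad-band wavelet energy (0.25–10 Hz), and `pulse_clarity_simple` — per
5 s window, the height of the maximum normalized autocorrelation peak of
the differentiated envelope over lags 0.25–2 s, in $[0,1]$. This is a
deliberate simplification of full pulse-clarity models (no resonance
curves, no periodicity entropy) and its values are not calibrated to any
published implementation; the predictor is screened out of the final models
anyway, so only its ordinal behaviour matters (click trains score high,
sparse or jittered event streams score low — both tested). Tempo and event
density descriptors are similarly simple: autocorrelation peak in the
0.33–1 s lag range with a shortest-lag-near-maximum rule against octave
errors, and thresholded envelope peak counting.

## Annotations, agreement, aggregation

Interval tiers (half-open intervals, merged on overlap) are binarized onto
the frame grid. Pairwise agreement is Cohen's $\kappa$ on the frame
coincidence table, with the large-sample null z statistic. Before
computing $\kappa$, one series is aligned to the other by dynamic time
warping with an asymmetric step pattern ((1,0), (1,1), (1,2) — each
reference frame consumes exactly one output frame) inside a Sakoe–Chiba
band of ±2 s; the band default is a judgment call (the constraint is
canonical, its width is not) and the unaligned $\kappa$ is always reported
alongside. Consensus bouts are the samples marked by at least two
annotators, with aggregated bouts shorter than two frames discarded as
degenerate. Bout onsets are characterized by their relative position
within structural sections (5% bins, half-open; onsets outside any section
are dropped and counted) and histograms compared by homogeneity chi-square
with both-zero bins removed.

## The predictor table

Twelve frame-wise predictors at 25 Hz: broad-band cross-wavelet energy and
phase, five narrow-band cross-wavelet energies, summed single-performer
wavelet energy, summed QoM, audio RMS, broad-band audio wavelet energy and
pulse clarity (audio features are linearly resampled onto the frame grid).
The first and last 5 s of each recording are trimmed, frames decimated by
taking every 5th (no anti-alias filter — the features are already
band-limited by construction), and feature columns z-scored jointly over
the assembled set (per-recording standardization is available). The phase
column is exported as the signed angle to keep the twelve named columns;
note that z-scoring an angle is a linear rescaling and preserves its rank
information only.

## Classification

Logistic regression and 500-tree random forests
(`mtry = floor(sqrt(p))`), trained on a random 80% of rows and always
evaluated by AUC on the held-out 20%, with DeLong confidence intervals and
DeLong paired comparisons between models. A repeated 10-fold
cross-validation pass within the training set is available as a stability
diagnostic; because neither model has tuned hyperparameters it cannot
change the held-out AUC, and it can be skipped (`cv_repeats = 0`) in large
simulation loops. Univariate screening flags predictors whose
cross-validated AUC does not beat the majority-class rate. Class imbalance
is left unweighted; the Youden cutoff (max sensitivity + specificity − 1,
ties to the lowest threshold, gap midpoint under perfect separation)
provides the operating point, at which the confusion asymmetry (false
positive vs false negative rates) is reported.

The default frame-level random split mirrors how such frame-wise analyses
are usually run, but frames within a recording are strongly
autocorrelated, so that split leaks information between train and eval:
a forest can label an eval frame by matching temporally adjacent training
frames. `split_train_eval(by_recording = TRUE)` holds out whole
recordings and is the honest generalization estimate; the package's own
acceptance checks use it, and the leak is demonstrable — with coupling
switched off entirely, a frame-split forest still scores far above chance
while a recording-split forest sits at 0.5.

Excerpt selection for perceptual validation slides 7.5 s windows over the
prediction stream; a window joins a confusion cell (TP/TN/FP/FN) only if
both the annotation label and the thresholded prediction hold their class
for at least 4 of the 7.5 s, windows are median-split on summed QoM, and
up to 12 non-overlapping windows per cell are chosen, balanced across QoM
classes, preferring purer windows and never relaxing the majority rule.

## The simulator

`simulate_dyad` generates two performers as phase oscillators. Outside
bouts each performer sways at an individual frequency (defaults 0.45 and
1.6 Hz) that mean-reverts with small random drift. During a scheduled bout
with coupling $c \in [0,1]$, the natural frequency becomes
$(1-c)\,f_{solo} + c\,f_{shared}$ and performer B's phase is pulled toward
A's by a Kuramoto term $c\,K_0 \sin(\phi_A - \phi_B - \text{lag})$ with
$K_0 = 4$ rad/s; $c = 0$ therefore leaves the pair fully independent, and
in-bout cross-wavelet energy rises monotonically with $c$. The sway
waveform carries a second harmonic (relative amplitude 0.3) and the body
centre wanders slowly (spline through knots every 12 s, below the analysis
band) — both are the features of real sway that keep the radial signal at
the sway fundamental, as discussed above. The default solo frequencies
were chosen so that fundamentals *and* second harmonics of the two
performers stay spectrally disjoint within the Morlet bandwidth; with
overlapping harmonics the pair would share periodicity outside bouts,
contradicting the independent-sway construct the out-of-bout regime
represents.

Default study conditions mirror a typical improvising-duo corpus:
160 s recordings at 25 fps; non-pulsed sessions with five long bouts
(~9–14 s, ≈33% of frames positive) and alternating 40 s joint / 26 s solo
sections at a nominal 106 bpm; pulsed sessions with nine short ~4.5 s
bouts, 48 s joint / 8 s solo sections and a 132 bpm click-train with an
accent every four beats; non-pulsed audio is a sparse Poisson event stream
at 0.45 events/s. Annotators miss a bout with probability 0.1, jitter
boundaries with 0.3 s s.d., and add 0.2 false alarms per minute; three
annotators per recording.

What the simulator does **not** emulate: articulated human kinematics
(a performer is one oscillating blob), instrument acoustics (clicks and
noise bursts, not notes), visual annotation psychology (annotators see the
truth plus noise, not a percept), or camera artefacts. Passing tests
therefore show that the pipeline recovers coordination structure *of this
kind* — shared periodicity with phase coupling against independent
periodic baselines — not that it reproduces any particular corpus result.

## Numerical choices and degenerate inputs

* FFT transforms zero-pad to a highly composite length past 10 wavelet
  scales, removing circular wrap-around.
* Bartlett and Gaussian smoothing are edge-normalized (partial windows
  keep unit weight), so constants map to themselves.
* A constant movement trace preprocesses to all-zero $\rho$ (a relative
  tolerance guards against amplifying $10^{-13}$ filter noise into a
  full-scale signal); constant envelopes give RMS equal to the constant;
  silent envelopes give pulse clarity 0 and tempo `NA` by convention.
* Fully COI-masked band-summary columns yield `NA`, never 0.
* Chirp ridges are attributed to the nearest grid row or its neighbour
  (the half-step ambiguity at row midpoints is inherent to a discrete
  grid).
* All randomness flows through explicit seeds; identical (config, seed)
  pairs are bit-reproducible.

## Problem sizes used in the checks

The packaged checks run at deliberately modest sizes chosen to exercise
every code path: oracle equivalence on 1200–1500-sample signals at 5
frequencies; bout recovery on 20 session seeds × 4 duos × 160 s
(recording-level evaluation); the video loop at 40 runs of 30 s; audio
contrasts at 30 paired seeds of 40 s. These sizes are the package's own
test design, balancing statistical resolution against a test suite that
runs in minutes.

## Known limitations

* The radial reduction hides circular motion and halves the period of
  perfectly symmetric centred oscillation (see above); downstream users
  with unusual motion geometry should inspect traces before trusting
  $\rho$.
* Pulse clarity, tempo and event density are simplified descriptors, fit
  for ordinal contrasts only.
* The dense-optical-flow weighting of the barycentre is not implemented;
  the greyscale intensity-weighted centroid is the only backend, validated
  against synthetic motion rather than any external tracker.
* DeLong confidence intervals assume independent evaluation frames; with
  frame-level splits they inherit the same autocorrelation optimism as the
  AUC itself.
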