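---
title: "Concealing the remote photoplethysmography signal: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Concealing the remote photoplethysmography signal: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulseveil)
```

## The problem

Remote photoplethysmography (rPPG) recovers the blood-volume pulse — and
from it heart rate — from the minute periodic colour changes of facial skin
in ordinary video. The signal is tiny (on the order of one 8-bit count in
the green channel) but robustly extractable with classical signal
processing, which makes every camera a potential covert heart-rate sensor.
pulseveil implements the defensive side of this problem: cheap, per-frame
video modifications that destroy the pulse while keeping the image useful,
plus the complete measurement stack needed to quantify how well a
modification conceals (heart-rate error it induces) and how much it costs
(pixel-level damage).

## The modification pipeline

Each frame passes through three steps: *ROI extraction* builds a binary
mask of the pixels eligible for modification; the *operator* rewrites those
pixels; *ROI combination* overlays the result on the original frame, so
everything outside the mask is bit-identical to the input.

Three ROIs are supported:

* **full frame** — every pixel; no landmarks needed, fastest;
* **facial skin** — the filled convex hull of all face-mesh landmarks with
  the eye and mouth polygons subtracted;
* **forehead + cheeks** — the union of three separately filled convex
  hulls, the regions most strongly modulated by blood volume.

Landmarks come from a pluggable provider; the synthetic scene ships its
own exact provider, and an external face-mesh detector can be adapted to
the same two-argument interface. The rasterization convention is fixed for
reproducibility: a pixel belongs to a polygon iff its center
`(x + 0.5, y + 0.5)` lies inside or on the boundary; coordinates are
0-based with the origin at the top-left corner.

### The operators

| Code | Operator | Tunables (defaults) |
|------|----------|---------------------|
| MB   | median blur | kernel `k = 5` |
| GB   | Gaussian blur | kernel `k = 5`, `sigma = 0.3((k-1)/2 - 1) + 0.8` |
| BB   | bilateral blur | `sigma_space = sigma_range = 75`, diameter 9 |
| TA-C | cumulative temporal average | — |
| TA-S | sliding-window temporal average | window `f = 20` frames |
| AGN  | additive Gaussian noise | variance 0.01 (unit scale) |
| AGN-L| Gaussian noise, local variance | 3×3 local variance, floor 1e-6 |
| SPN  | salt-and-pepper noise | amount 0.05, salt ratio 0.5 |
| PoN  | Poisson (shot) noise | photon scale 256 |
| PeN  | pepper noise | amount 0.05 |
| SN   | speckle noise | variance 0.01 |
| NE   | no editing (baseline) | — |

Notes on the less obvious choices:

* **Noise parameters.** All six noise operators work on the unit-scaled
  copy `u = pixels/255` of the in-mask pixels, then clip, rescale and
  round. The defaults (Gaussian variance 0.01, impulse amount 0.05, salt
  ratio 0.5, Poisson scale 256) are the conventional image-toolkit
  defaults; every one is configurable through `filter_config()`.
* **AGN-L.** "Local variance" is concretized as the 3×3 neighborhood
  sample variance of the unit-scaled channel (reflection padded), floored
  at `1e-6` to avoid zero-variance degeneracy on flat regions. Other
  definitions exist; this one is documented rather than claimed canonical.
  In particular AGN-L generally does *not* degenerate to AGN here.
* **TA-S warm-up.** Before `f` frames have been seen, the sliding average
  runs over the frames available, so output is defined from frame 0 rather
  than emitting a burn-in of unmodified frames.
* **Masked blurring.** The spatial blurs are computed on the full frame
  and composited by the mask. This matches the overlay architecture and is
  cheap, but differs at ROI borders from masked-normalized convolution:
  in-mask border pixels see some out-of-mask context. Documented, not
  configurable.
* **Determinism.** Accumulation is in double precision with
  round-half-away-from-zero at the 8-bit boundary; borders use reflect-101
  padding; all stochastic operators draw from a private, seeded RNG stream
  that neither reads nor disturbs the caller's `.Random.seed`. Identical
  (input, config, seed) gives bit-identical output on every platform.

The sliding average has a closed-form frequency response: a pulse at
`fr` Hz under an `f`-frame window at `r` fps is attenuated by
`|sin(pi fr f / r)| / (f |sin(pi fr / r)|)` — e.g. gain 0.157 at 90 bpm
with `f = 20`, `r = 25`, and 0.042 at 72 bpm. This Dirichlet gain is used
as the oracle for the temporal-averaging tests.

## The estimation stack

The measurement side mirrors a standard rPPG pipeline: per frame, each
colour channel is averaged over square patches (side 9) centered on up to
100 equispaced landmarks across the forehead, cheeks and nose; the RGB
trace is cut into overlapping 8-second windows at a 1-second stride; each
window row is linearly detrended and bandpassed with a zero-phase
sixth-order Butterworth filter over 0.65–4.0 Hz (39–240 bpm); one of five
algorithms extracts the blood-volume pulse; and heart rate is read from
the peak of a Welch power spectrum (Hann taper, 50% segment overlap,
zero-padded so the bpm grid is finer than 0.25 bpm), restricted to the
physiological band.

The five pulse-extraction algorithms:

* **GREEN** — the bandpassed green channel.
* **ICA** — seeded deflation FastICA (tanh nonlinearity) unmixes the three
  bandpassed channels. Component order in ICA is arbitrary, so the pulse
  component must be identified rather than indexed: we return the
  component with the greatest in-band spectral concentration (power within
  0.1 Hz of its own peak relative to total in-band power), i.e. the most
  periodic component. A positional rule ("the second component") is only
  meaningful for a specific, unseeded implementation and selects noise on
  clean inputs.
* **CHROM** — chrominance combination `X = 3Rn − 2Gn`,
  `Y = 1.5Rn + Gn − 1.5Bn` of mean-normalized channels, output
  `X − (sd(X)/sd(Y)) Y`. Normalization uses the *raw* window means (the
  bandpassed rows are zero-mean, so normalizing them by themselves would
  be undefined); the adaptive ratio cancels whichever disturbance
  dominates the variance.
* **POS** — projection of the mean-normalized channels onto the plane
  orthogonal to the skin-tone axis, `P = [[0, 1, −1], [−2, 1, 1]]`, with
  the adaptive recombination `S1 + (sd(S1)/sd(S2)) S2`.
* **LGI** — the dominant left-singular direction `u1` of the **raw**
  3×L window is projected out (`P = I − u1 u1'`), the projected green row
  is taken, then detrended and bandpassed. On raw (mean-retaining) data
  `u1` is the mean-colour/illumination axis, which absorbs common-mode
  intensity changes. Computing the SVD on the *bandpassed* window instead
  is tempting but self-defeating: there the dominant direction is the
  pulse itself whenever the recording is clean, and the projection
  annihilates exactly the signal being estimated (we measured the residual
  peaking at the third harmonic). This degeneracy dictated the raw-signal
  form.

Ground-truth heart rate from the contact PPG runs through the *identical*
windowing, detrending, bandpass and spectral-peak code (skipping only the
trace and pulse-extraction stages), so estimator bias cancels in the error
metric.

## Evaluation metrics

For a method set evaluated on one scene:

* `delta_bpm` — mean absolute per-window difference between ground-truth
  and estimated heart rate (bpm). Higher = better concealment.
* `frame MSE` — mean squared pixel difference between original and
  modified frames, averaged over pixels, channels and frames. The printed
  formula indexes pixels only, so the channel handling is a convention; we
  divide by `m·n·3` by default and expose `per_channel_mean = FALSE` for
  the channel-sum reading. MSE is computed on the full frame by default
  (the ROI-restricted variant is available via the `mask` argument).
* `OS` — `(dbpm_n + (1 − MSE_n))/2`, both terms min-max normalized across
  the method set (heart-rate errors first averaged across rPPG
  techniques). OS is a *relative ranking within one run*: the method with
  maximal induced error and minimal damage scores exactly 1.
* `fps` — wall-clock throughput of the mask+filter+overlay path, reported
  as descriptive metadata only, since it is hardware-dependent.

All video persistence is lossless (PNG frame directories with a JSON
sidecar) because lossy compression perturbs precisely the low-amplitude
chrominance variation that both the pulse and its concealment live in; a
compressing writer would make concealment results unattributable.

## The synthetic scene

Everything is testable offline against scenes with a known embedded pulse:
an ellipsoidal skin region whose RGB intensities follow
`base + texture + amplitude · w(t) + flicker(t) + sensor noise`, dark
static eye/mouth rectangles inside the ellipse that carry no pulse, a
static background, a full landmark set per frame (36-point outer ring,
eye/mouth corners, and 103 forehead/cheek/nose grid points), and a
co-registered 60 Hz ground-truth PPG sharing the exact waveform `w(t)`
that drives the skin — which makes video-path vs PPG-path agreement an
exact oracle.

Default conditions: 128×128 px at 25 fps, 72 bpm sinusoidal pulse with
additive channel amplitudes (0.45, 1.5, 0.9) counts on a skin tone of
(180, 120, 100) — a linear small-signal model of blood-volume absorption,
strongest in green — and per-pixel sensor noise of 0.5 counts.

Two scene features deserve explanation because they are what makes the
measurement honest rather than convenient:

* **Static skin texture** (default sd 2 counts, drawn once per scene).
  Real skin is not a uniform colour, and the texture doubles as spatial
  dither: with a perfectly uniform surface, patch-averaged traces inherit
  the 8-bit quantization staircase, and the sub-count chrominance
  differences CHROM and POS rely on drown in staircase distortion. With
  texture, the patch mean responds linearly to pulse amplitudes well below
  one count, as a real sensor's spatial average does.
* **Illumination flicker** (default sd 0.5 counts common-mode across
  channels, plus 0.15 counts per-channel white-balance jitter). Per-pixel
  sensor noise averages away over the ~8000 patch pixels, which would
  leave a synthetic trace unrealistically clean. Flicker is the noise
  that does *not* average out — exactly the disturbance floor real
  ambient-light recordings have. It matters in both directions: it gives
  the adaptive, disturbance-cancelling estimators (CHROM, POS, LGI)
  something to cancel — on a literally disturbance-free scene their
  adaptive steps degenerate and cancel the pulse itself — and it is what
  buries the 24-fold-attenuated residual pulse after sliding-window
  averaging, so concealment is measurable.

"Clean" test scenes set the per-pixel sensor noise to zero and keep the
illumination model; a scene with every stochastic term zeroed is still
renderable (and is used to test determinism), but it is not a faithful
emulation of any camera.

What the generator deliberately does **not** emulate: photorealistic
faces, specular highlights, head rotation and non-rigid motion (talking),
skin-tone diversity, rolling-shutter artifacts, and compression. Passing
the recovery and concealment tests here therefore demonstrates that the
pipeline's signal path is correct and calibrated, not that concealment
magnitudes transfer to real recordings; on real data, errors are dominated
by motion and lighting phenomena this generator intentionally omits.
Rigid linear drift is supported to exercise landmark tracking, with the
texture fixed in frame coordinates (a simplification: real texture moves
with the face).

## Numerical choices

* Butterworth design via bilinear transform (`signal::butter(6, ...)`),
  applied forward-backward; windows are padded by odd reflection (three
  filter lengths) before `filtfilt` to suppress end transients.
* Welch segments of `min(L, 256)` samples; at the default 8 s × 25 fps a
  window is a single tapered segment, zero-padded to a ≤ 0.25 bpm grid.
  Residual per-window scatter of spectral peaks (a few tenths of a bpm,
  worst near the 0.65 Hz band edge where the negative-frequency image lobe
  interferes) is inherent to 8-second peak estimation, not a bug.
* FastICA whitening drops eigendirections below `1e-12` of the leading
  eigenvalue, so numerically rank-deficient mixtures reduce cleanly
  instead of amplifying quantization residue; deflation uses a fixed
  seeded initialization, making the decomposition bit-reproducible.
* Convex hulls come from `grDevices::chull`; rasterization does exact
  half-plane tests against pixel centers with a `1e-9` boundary slack and
  is verified against a brute-force point-in-polygon oracle in the tests.
* Division-by-zero guards: `sd(Y) = 0` in CHROM gives `alpha = 0`;
  `sd(S2) = 0` in POS drops the second term; an all-zero pulse signal is
  an explicit "undefined spectral peak" error rather than a silent 0.

## Problem sizes in the test suite

The shipped tests run on scenes of 30 s × 25 fps × 128×128 px for the
recovery and concealment checks (chosen to give 23 analysis windows, the
regime where window statistics stabilize), 10–12 s scenes for the
evaluation-harness checks, and 16×16–64×64 synthetic frames for the
pixel-exact operator oracles. These sizes keep the full suite under a
minute while leaving every quantitative claim at its stated tolerance.

## Known limitations

* Concealment magnitudes on synthetic scenes are not predictions for real
  videos; only orderings and mechanisms transfer.
* The facial-skin ROI is convex by construction; non-convex segmentation
  (hairlines, glasses) is out of scope.
* ICA on a three-channel trace can only separate three sources; with
  common-mode flicker, white-balance jitter and pulse present it sits at
  capacity, and its heart-rate estimates are accordingly the most
  seed-sensitive of the five methods.
* `evaluate_run()` scores are relative to the supplied method set (min-max
  normalization); do not compare OS values across runs with different
  method sets.
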