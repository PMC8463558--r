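---
title: "Methods: fibrosis quantification, optical mapping and ECG intervals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fibrosis quantification, optical mapping and ECG intervals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardioquant)
```

cardioquant packages three measurement pipelines that recur in cardiac
radioablation research — trichrome fibrosis quantification on whole-slide
images, optical-mapping electrophysiology, and ECG interval analysis — each
paired with a synthetic-data generator that carries exact ground truth.
This vignette documents the models, the tunable parameters and their
defaults, the numerical choices, and what the synthetic validations do and
do not demonstrate about real data.

## Fibrosis quantification

The pipeline has four steps, applied per sampling tile and aggregated:

1. **Sampling.** `plan_tiles()` lays `n_tiles` (default 900) square windows
   of `tile_px` (default 50) pixels on an $r \times c$ grid with
   $rc = n_{\mathrm{tiles}}$, choosing the divisor pair whose ratio is
   closest to the slide aspect ratio (30 × 30 for a square slide). Windows
   are equally spaced with the first and last touching the slide margins;
   when the stride equals the tile size the grid is contiguous and covers
   every pixel exactly once. The grid geometry is our design choice: "equally
   spaced windows spanning the slide" does not pin down a layout, and a
   margin-to-margin grid is the least surprising reading. Windows are read
   at the highest-resolution level of the source image.
2. **Preprocessing.** `superpixel_preprocess()` runs SLIC targeting
   $\lceil n_{\mathrm{px}} / \mathrm{ratio} \rceil$ superpixels (ratio
   default 50, i.e. a 1:50 compression), replaces each pixel by its
   superpixel's mean colour, and converts to CIE L\*a\*b\* (sRGB, D65 —
   a colour profile has to be assumed because slide scanners rarely embed
   one). SLIC is implemented as k-means in the 5-D feature space
   $(L, a, b,\; y\,m/S,\; x\,m/S)$ with compactness $m$ (default 10) and
   expected spacing $S=\sqrt{n_{\mathrm{px}}/k}$; at the tile sizes used
   here a full nearest-centre search replaces the classical $2S$ window,
   and superpixel connectivity is not enforced — both simplifications only
   affect which pixels share a mean, not the downstream formula. A ratio of
   1 is the identity and disables smoothing.
3. **Quantization.** `train_palette()` fits seeded `stats::kmeans` with
   $k$ clusters (default 4) on pooled labelled training pixels and maps
   clusters to the four classes — collagen, red blood cells, myocytes,
   background — by majority vote. Ambiguous maps (two clusters claiming one
   class, or a class unclaimed) raise an error rather than guessing; the
   documented remedies are a larger $k$, more training pixels, or another
   seed. The centroids are then **frozen**: inference never updates them.
4. **Calculation.** `assign_classes()` performs the Lloyd assignment step —
   nearest centroid in Euclidean L\*a\*b\* distance, ties toward the lowest
   class index — and `fibrosis_fraction()` computes
   $$\mathrm{fibrosis} = \frac{A_{\mathrm{collagen}}}
   {A_{\mathrm{collagen}} + A_{\mathrm{RBC}} + A_{\mathrm{myocytes}}},$$
   excluding background from the denominator, so injecting background-only
   pixels never moves the estimate. A zero denominator returns a flagged
   `NA`, never a silent 0.

```{r fibrosis-example}
sl <- make_trichrome_slide(trichrome_truth(noise_sd = 8, seed = 1), 500, 500)
res <- quantify_slide(sl, palette_from_means(),
                      plan_tiles(500, 500, tile_px = 50, n_tiles = 100))
glance(res)
```

The synthetic generator renders each class at a configurable mean colour
(defaults mimic a Masson trichrome: collagen blue, myocytes red-pink, RBC
orange-red, background near-white) plus per-channel Gaussian noise, with
two placement modes: `"iid"` per-pixel multinomial sampling, which makes
classification exactness testable, and `"blobs"` (default), smooth random
fields thresholded at order statistics so realized fractions match the
request to within one pixel per split while regions stay contiguous. An
optional multiplicative illumination ramp is available (default off). What
the generator does **not** emulate: stain batch variation, scanner blur and
stitching seams, nuclei, and intermediate pixel colours at class borders.
Passing recovery tests therefore demonstrates that the sampling,
quantization and formula machinery is unbiased under the declared colour
model — not that a palette trained on one scanner transfers to another.

## Optical mapping

Signals are min-max normalized per pixel to $[0,1]$
(`condition_signals()`), optionally after moving-average temporal smoothing
and separable Gaussian spatial smoothing (kernel rows renormalized at the
edges); all-constant pixels leave the mask. Activation time is the time of
the maximum forward-difference derivative, $(dV_m/dt)_{\max}$
(`activation_map()`). Two conventions are offered, because a discrete
derivative cannot satisfy both desiderata at once: `refine = "parabolic"`
(default) timestamps derivative samples at frame midpoints and takes the
vertex of the parabola through the three samples around the maximum — the
right estimator for band-limited upstrokes, exact to well under half a
frame on logistic upstrokes; `refine = "none"` reports the first frame at
the risen level, which is the natural answer for an ideal step. Pixels
whose maximum derivative does not exceed `noise_floor_k` (default 5) times
the baseline derivative SD are reported missing.

Conduction velocity (`conduction_velocity()`) regresses activation time on
absolute distance from the stimulation site along a one-pixel-wide ray at
the fiber angle and its perpendicular; $\mathrm{CV} = 1/\mathrm{slope}$.
Pixels within 1.5 px of the stimulus are excluded from the fit. When no
fiber angle is supplied, the orientation is estimated by fitting $t^2$ as a
quadratic form in the displacement (the activation-time ellipse) and taking
the eigenvector of the fastest direction; the faster ray is then labelled
longitudinal. Non-monotone or degenerate times (non-positive slope, or
$R^2 < 0.5$) raise a fit error carrying diagnostics instead of returning a
number.

APD80 (`apd80()`) is the time from activation until the trace first falls
to 20% of its local amplitude (pre-upstroke baseline to post-activation
peak), linearly interpolated between samples; for an exponential
repolarization with time constant $\tau$ this equals $\tau \ln 5$, which
the tests verify to under 1%. ERP (`erp_s1s2()`) decrements the S1–S2
coupling interval (default step 2 ms) until capture is lost and returns the
shortest interval that still captured, so the estimate sits within one step
above the true refractory period; capture at the range floor or failure at
the range ceiling are errors, not values. "Propagated capture" is defined
as a second upstroke at probe pixels at least 1 mm from the stimulus
(second-window maximum derivative exceeding half that pixel's S1 upstroke
derivative) — a criterion we had to fix ourselves, since pacing protocols
rarely state one.

The movie generator is kinematic, not ionic: an elliptical wavefront with
arrival time $t(p) = \sqrt{(u/\mathrm{CV}_L)^2 + (v/\mathrm{CV}_T)^2}$ for
displacement components $(u, v)$ along/across the fiber axis, followed by a
stereotyped action potential (logistic upstroke with its maximum slope
exactly at the arrival time, time constant 0.7 ms; 30%-of-APD plateau;
exponential repolarization reaching 20% of amplitude at activation + APD).
Refractoriness is binary — an S2 at the stimulation site captures iff the
coupling interval is at least the ERP — with no gradual restitution, and S1
and S2 waves combine by pointwise maximum. Defaults (CV 0.5/0.25 m/s, APD
40 ms, ERP 60 ms, 0.1 mm pixels, 2 kHz frame rate) are typical murine
ventricular values at the scale of a mapped mouse heart. Validation grids
use 48 × 48 px movies, conduction velocities 0.2–0.7 m/s, anisotropy ratios
1–2, noise SD 0 and 0.05, and ERPs 40–80 ms. Because wavefronts are ideal
ellipses, these tests certify the estimators' geometry and calculus, not
their behaviour on curved or blocked wavefronts around real scars; scar
regions in real data are handled by masking, not modelled.

```{r ep-example}
mv <- make_optical_movie(wave_truth(cv_long = 0.5, cv_trans = 0.25, seed = 2),
                         48, 48, duration_ms = 90)
tidy(ep_summary(mv, axis_angle = 0, erp_ms = 60))
```

## ECG intervals

`detect_beats()` finds R peaks from a moving-average-smoothed squared
derivative (window 3 ms, threshold 30% of maximum energy, merged within a
quarter of the median spacing); `average_beats()` averages fixed windows —
55% of the beat period before the anchor, 45% after — over up to 100 beats
(fewer are averaged with `n_averaged` recorded, so the $\sqrt{n}$ noise
reduction remains auditable). `measure_intervals()` then applies:

* **Isoelectric level**: median of a pre-P baseline window (up to 20% of
  the beat period ending at P onset), making all intervals invariant to DC
  offset.
* **Onsets** (P and QRS): walking back from the corresponding peak to the
  latest run of at least 0.4 ms of samples within a threshold of the
  isoelectric level. The threshold is `k_onset` (default 4) baseline SDs,
  with a tiny absolute floor so that noise-free templates are measured at
  full precision. Only the QRS **end** rule is dictated by convention in
  murine work; the onset detector is our design.
* **QRS end**: the first crossing of the isoelectric line after the S
  nadir, linearly interpolated between samples. The murine J wave begins
  after that crossing, so it is excluded from the QRS by construction —
  measurements with and without a J wave agree at the sampling resolution.

Generated beats are piecewise linear (triangular P, R–S complex whose S
limb crosses zero exactly `qrs` ms after onset, optional J wave, T wave),
which is what makes "within one sample at 4 kHz" a meaningful acceptance
bound: every fiducial of the template is exactly known. Real ECGs have
curved waveform feet where any threshold onset detector is biased by
filter settings; the synthetic checks certify the rules, not robustness to
morphology variants such as notched QRS or biphasic T waves, which are out
of scope.

`robust_shortening()` flags a serial pair when pre − post ≥ 25 ms — exact
at the boundary. `paired_wilcoxon()` implements the two-sided signed-rank
test: zero differences dropped, mid-ranks for ties, and for fewer than 20
usable pairs the exact null distribution obtained by dynamic programming
over all $2^n$ sign assignments (ranks doubled so mid-ranks stay integral);
otherwise a normal approximation with continuity and tie corrections. The
two-sided p is $\min(1,\, 2\min(P(W \le w), P(W \ge w)))$. Tests pin the
implementation to an exhaustive enumeration oracle for $n \le 8$, to
`stats::wilcox.test` on tie-free data, and to a Monte-Carlo type-I error in
$[0.03, 0.07]$ at $\alpha = 0.05$, $n = 19$.

```{r ecg-example}
e <- make_ecg(ecg_truth(heart_rate = 600, pr = 38, qrs = 12, n_beats = 120,
                        noise_sd = 0.01, seed = 5))
ecg_intervals(e, n_average = 100)
```

## Numerical and design notes

* **Coordinates** are 1-based `(row, col)` everywhere, matching R indexing;
  times are milliseconds from recording start.
* **Determinism**: every generator takes an explicit seed and restores the
  caller's RNG state (`withr::with_seed`); every estimator is a pure
  function of its inputs. Identical configuration and seed reproduce
  byte-identical run reports (`run_pipeline()` writes no timestamps).
* **Tie-breaks**: nearest-centroid ties go to the lowest class index;
  derivative-maximum ties to the earliest frame.
* **Degenerate inputs** raise classed errors (`cardioquant_param_error`,
  `_size_error`, `_fit_error`, `_range_error`, `_detection_error`,
  `_usage_error`) rather than returning sentinel values; undefined fibrosis
  fractions are flagged `NA`s.
* **Problem sizes.** The validation suite uses 1500 × 1500 px slides for
  fraction-recovery runs (the size at which the default plan is a
  contiguous 30 × 30 grid), 500 × 500 px for the exact-classification
  oracle, 48 × 48 px movies for CV grids and 24 × 24 px for ERP protocols,
  and 100-beat averages at 4 kHz for ECGs — large enough that every
  acceptance bound is exercised at its stated tolerance, while a full run
  completes on a laptop in a few minutes.
* **Known limitations.** The fibrosis palette is scanner-specific by
  design (frozen parameters, no stain normalization); SLIC connectivity is
  not enforced; CV estimation assumes a single stimulation site and
  elliptical spread near the site; the ECG onset detector presumes a
  dominant-R morphology; the signed-rank normal approximation is used from
  n = 20, where it is conventionally considered adequate.
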