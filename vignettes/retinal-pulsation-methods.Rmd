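---
title: "Measuring retinal vessel pulsation from cardiac-gated fundus video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring retinal vessel pulsation from cardiac-gated fundus video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retpulse)
```

## The measurement problem

Spontaneous retinal venous pulsation — the rhythmic, cardiac-synchronous
change in the appearance of retinal veins at the optic disc — is a clinical
sign whose absence matters in raised intracranial pressure, retinal vein
occlusion and glaucoma. It is normally assessed by eye, which makes it
subjective and observer-dependent. `retpulse` implements an objective
alternative: a video photo-plethysmographic pipeline that converts a short
fundus video (nominally 25 fps, spanning at least three cardiac cycles) and
a file of cardiac beat-onset times into a spatial map of pulsation
amplitude, and a validation framework that compares such maps against
manual observer outlines via threshold-sweep ROC analysis.

## Signal model

Blood absorbs green light strongly, so the transmitted green intensity at a
retinal location falls as the haemoglobin column beneath it thickens. By
the Beer-Lambert law, absorbance is proportional to optical path length, so
we work with

$$ y = 68 \cdot \left(-\log_{10} \frac{I}{I_{\max}}\right), $$

where $I$ is the raw green-channel intensity and $I_{\max}$ the camera's
full-scale value. The factor 68 converts base-10 absorbance to a nominal
half optical path length in microns through haemoglobin (extinction
coefficient at 550 nm, typical haemoglobin concentration, and a factor of
two for the double pass of reflected light); the values remain arbitrary
units — no absolute micron calibration is claimed. Zero intensities are
clamped to half the least count so the transform stays finite.

Frames are affine-registered to a reference frame, cropped to the region
visible in every frame, and tiled into non-overlapping 5×5-pixel clusters
anchored at the top-left corner (trailing remainders dropped). The mean
transformed value of each cluster, tracked across frames, is the cluster's
plethysmographic time series.

Each frame is assigned a cardiac phase $\varphi \in [0, 1)$: a frame at
time $t$ inside the cycle $[o_k, o_{k+1})$ gets
$\varphi = (t - o_k)/(o_{k+1} - o_k)$. Phase is normalized per cycle
because heart rate varies between beats; a single fixed period would smear
the waveform of the longer cycles. Frames before the first or at/after the
last beat onset are excluded from regression rather than extrapolated.

Each cluster series is then fit by ordinary least squares on

$$ y_i = \mu + \sum_{k=1}^{H}\big(a_k \cos 2\pi k\varphi_i
       + b_k \sin 2\pi k \varphi_i\big) + s(t_i) + \varepsilon_i, $$

where $s(t)$ is a continuous piecewise-linear function of absolute time
with knots at the interior beat onsets (one linear segment per cycle). The
spline term absorbs patient movement and slow illumination drift without
touching the periodic component. The pulsation amplitude of the cluster is
the peak-to-trough range of the fitted periodic component
$c(\varphi) = \sum_k a_k \cos 2\pi k\varphi + b_k \sin 2\pi k\varphi$
alone — the intercept and spline model artefact, not pulsation, so they are
excluded from the range. Extrema of $c$ are located on a 1000-point phase
grid and refined by sign changes of the analytic derivative
(`uniroot` on each bracketing interval), so the amplitude does not depend
on grid resolution to within $10^{-6}$.

Because every cluster of a recording shares one design matrix, the map
computation solves all clusters in a single QR decomposition; a 40×40
cluster grid over 75 frames fits in well under a second.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `cluster_size` | 5 px | tile side of the averaging grid (5:1 reduction) |
| `n_harmonics` | 2 (1–4) | harmonics in the regression; two capture the systolic peak and dicrotic shoulder of the pulse wave |
| `scale_factor` | 68 | absorbance-to-paper-units multiplier |
| `phase_grid` | 1000 | phase grid for amplitude extraction |
| `fps` | 25 | nominal video frame rate |

The number of harmonics is the one genuinely open modelling choice. One
harmonic underfits the asymmetric pulse waveform; beyond two, the extra
coefficients mostly fit noise at the 60–100 observations a three-cycle
recording provides. Two is the default; the parameter is exposed.

## Registration

Frames are aligned by intensity-based affine registration on the green
channel: a mean-squared-difference objective over translation, rotation,
shear and scale, minimized by Nelder-Mead with a multi-resolution schedule
(FFT cross-correlation gives the starting translation at coarse scale; the
full affine is refined at half and then native resolution). Warping is
bilinear, and every warped pixel carries an explicit validity flag — pixels
whose source coordinates fall outside the moving frame are flagged rather
than filled — so the subsequent crop to the commonly visible region is
exact: the largest axis-aligned rectangle of the intersected validity
masks. On noise-free synthetic jitter up to ±10 px and ±2° the recovered
translations are accurate to well under 0.1 px and rotations to under 0.1°.

The per-recording movement index is
$\sqrt{\max_{ij}|t_x^{(i)} - t_x^{(j)}|^2 + \max_{ij}|t_y^{(i)} - t_y^{(j)}|^2}$,
the Pythagorean combination of the largest horizontal and vertical
displacement spans between any two frames, computed from the recovered
translation components; rotation and shear contributions are ignored
because translation dominates inter-frame displacement at fundus-video
scales. The illumination variability index is the standard deviation across
frames of the whole-frame mean raw green intensity.

## Observer comparison

Observers outline pulsating regions on a full-resolution frame; the binary
outline is reduced 5:1 onto the cluster grid by OR-pooling (a cluster is
pulsatile if *any* of its 25 pixels is annotated). The amplitude map is
segmented at every integer threshold 0–40 — a range chosen because in
practice it contains essentially all amplitude values; values above 40
still participate as "greater than threshold". Segmentation is strictly
`amplitude > threshold`: a cluster exactly at threshold is non-pulsatile.

Per threshold, the 2×2 confusion table against the observer grid gives
TPR = TP/(TP+FN) and FPR = FP/(FP+TN); a zero denominator yields an
explicit undefined flag, never a silent zero. The empirical AUC is the
trapezoid rule over the swept points anchored with (0,0) and (1,1) and
sorted by (FPR, TPR). Tied-FPR points contribute zero width, which
preserves the standard empirical staircase; collapsing ties (for example
to their mean TPR) would badly understate the area whenever many
thresholds share one FPR — on a perfectly separable map every threshold
has FPR 0 and the collapsed curve would report ≈0.64 instead of 1. This
behaviour is pinned by a test against `pROC` as an independent oracle.

The **ideal threshold** is the integer threshold maximizing
sensitivity × specificity, ties broken toward the lower threshold (the
sensitivity-favouring choice, consistent with the aim that no manually
identified region be missed). The **critical amplitude** of an
observer-outlined region is the maximum amplitude within it: choosing a
detection threshold above that ceiling misses the entire region. Regions
are 8-connected components of the observer cluster grid — hand-drawn
outlines routinely produce diagonal adjacency, which 4-connectivity would
split. The eye-level critical amplitude is the *minimum* over regions: it
is the unique value with the property that thresholds below it miss no
region entirely while thresholds above it miss at least one. Whether a
per-eye summary should instead average region ceilings is not decidable
from the published per-eye table; the minimum is the value that carries
the "no region missed" guarantee, so it is what `roc_sweep` reports.

Inter-observer agreement uses Cohen's kappa with marginal-product expected
agreement over all clusters; two constant graders make the statistic
undefined and are flagged.

## Cohort summaries

AUC values are left-skewed and ideal thresholds right-skewed, so intervals
are computed on transformed scales: $\log(1 - \mathrm{AUC})$ for AUC, and
a natural-log transform for thresholds and critical amplitudes. The
confidence interval is a $t$-interval for the mean of the logs,
back-transformed:
$\exp\!\big(\overline{\ln v} \pm t_{n-1,0.975}\, s_{\ln v}/\sqrt{n}\big)$.
Applied to the bundled 26-eye reference table this reproduces the
published cohort values: median ideal threshold 5 units with 95% CI
4.3–6.0, and median AU-ROC 0.95 at two decimals. The log base is
immaterial after back-transformation.

## The synthetic scene generator

Clinical recordings cannot ship with the package, so every stage is tested
against rendered scenes with known ground truth. A scene is a bright
disc-like background (smooth radial falloff) crossed by curvilinear dark
vessels; each vessel has a baseline absorbance and a cardiac-phase-locked
modulation $a \cdot w(\varphi - \phi_0)$ where $w$ is a unit-peak-to-trough
waveform (sine fundamental plus optional second harmonic, rescaled to range
exactly $[-\tfrac12, \tfrac12]$). The rendering inverts the analysis
transform — intensity $= B(x,y)\,\mathrm{illum}(t)\,10^{-A/68}$ — so a
vessel's `amp` is *exactly* the per-pixel peak-to-trough absorbance the
pipeline should report, making recovery tests self-calibrating. Where
vessels with different phase offsets overlap, their waveforms interfere, so
the ground-truth peak-to-trough there is evaluated numerically on a dense
phase grid rather than by summing amplitudes. Nuisance terms mirror real
recording conditions: multiplicative sinusoidal illumination drift (period
deliberately incommensurate with the cardiac cycle), per-frame
translational/rotational jitter applied analytically (the scene is
evaluated at inverse-transformed coordinates, so there is no interpolation
error in the ground truth), and Gaussian sensor noise added in intensity
space before quantization — a sensor model, not an absorbance model.

Presets fix the study conditions: `clean` (200×200 px, 75 frames at
25 fps, three slightly irregular ~1 s cycles, peak-to-trough 10 units),
`noisy` (sensor noise SD 2 levels), `drift` (illumination SD inside the
0.5–3.5 level range seen across real recordings), `wobble` (jitter up to
±8 px / ±1.5°, displacement indices comparable to real recordings after
scaling to frame size), and `separable` (hard-edged vessels of 12 and 15
units on a non-pulsatile background, so every pulsating cluster outranks
every background cluster and the empirical AUC is exactly 1).

What passing these tests shows — and does not show. The generator
exercises the geometry, the transform algebra, the regression and the ROC
machinery under known truth; it does not emulate specular reflexes, the
optic-disc rim, vessel wall reflexes, saccadic eye movement beyond affine
jitter, or physiological waveform variability. Recovery to within 5% on
`clean` therefore validates the computation, not the biological accuracy
of amplitude in any particular eye.

## Numerical choices and degenerate inputs

- Intensities are normalized to $(0, 1]$ before the log; zeros are clamped
  to half the least count ($1/(2 \cdot I_{\max})$).
- Cluster tiling anchors at pixel (0,0); remainder rows/columns under 5 px
  are dropped.
- Rank-deficient harmonic designs and per-cluster fit failures yield
  amplitude 0 with a flag and a warning; a run errors if more than 10% of
  clusters fail.
- Beat files need at least 4 onsets bounding 3 complete cycles; cycle
  lengths at or below 0.2 s (300 bpm) are rejected as implausible.
- The largest-rectangle crop uses the histogram-stack algorithm, exact for
  arbitrary validity masks (verified against an exhaustive all-rectangles
  scan).
- All randomness in the generator flows from a single stored seed; a fixed
  seed reproduces stacks bit-identically.

Test and validation problem sizes: full-scale presets (200×200×75) for
end-to-end amplitude recovery and ROC checks; 100×100×30 scenes for unit
tests; 6–8 frame stacks for registration recovery; 1000 clusters × 200
permutations for the chance-level AUC null.

## Known limitations

- Amplitude units are nominal; comparing absolute values across cameras or
  illumination levels requires care (illumination variability is known to
  shift the ideal threshold upward).
- The movement index ignores rotational displacement; recordings dominated
  by torsion would understate motion.
- Beat timing arrives as a file; latency between the oximeter pulse and
  the video clock is assumed already corrected upstream.
- Registration assumes a globally affine deformation; it does not model
  non-rigid distortion.
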