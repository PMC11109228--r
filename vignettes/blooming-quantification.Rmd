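---
title: "Quantifying calcification blooming on CT: model, measurement and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying calcification blooming on CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

High-attenuation coronary calcifications appear larger on CT than they are:
system blur and partial-volume averaging smear their edges into the
surrounding lumen (the *blooming artifact*), which makes stenosis look worse
than it is. A recurring clinical suggestion is that raising the X-ray energy
level (tube kVp, or keV of a virtual monochromatic reconstruction from
dual-energy CT) reduces blooming, because the calcification's attenuation —
and hence its visual footprint at a fixed window — drops. `bloomquant`
implements a *quantitative* definition of the artifact so that claim can be
tested on pixels rather than on visual impressions, together with a synthetic
phantom generator that makes every stage reproducible without scanner data.

## The measurement model

All measurement operates on a line profile of attenuation values (HU) along a
cardinal pixel row/column through the centre of the calcification, against a
0 HU background.

* **Actual calcified length** — the full width at third maximum (FW3M): the
  distance between the two outermost sub-pixel crossings of
  $T_{1/3} = \tfrac13\,\mathrm{peak}$, found by walking outward from the peak
  sample and linearly interpolating the first bracketing sample pair. The full
  width at half maximum (FWHM, $T_{1/2}$) is available through the same
  routine.
* **Brightened length / adjacent-affected metric** — in each of the four
  cardinal directions the *halo* is the distance from the FW3M edge to the
  outward crossing of $T_{5\%} = 0.05\,\mathrm{peak}$, clamped at 0. The
  *adjacent pixels affected by calcification* is the mean of the four halos
  (reported in mm and in pixel-spacing units), and the brightened length is
  the actual length plus that mean, so that
  $\text{adjacent} = L_\text{brightened} - L_\text{actual}$ holds by
  construction.

Because both thresholds are *relative* fractions of the peak, the measurement
is exactly invariant under amplitude scaling of the image. This is the
mechanistic heart of the package's headline property: changing the energy
level of an otherwise identical acquisition rescales attenuation but cannot,
by itself, move this metric.

Key conventions, each of which matters in clinical-style images:

* The **peak reference** is the maximum within the calcification's connected
  above-threshold region, not the global image maximum, so a bright contrast
  lumen elsewhere cannot corrupt the thresholds.
* The crossing search starts at the peak and moves outward; the *innermost*
  bracketing pair wins, which makes the estimate robust to distant noise
  bumps. A sample exactly on the threshold is itself the crossing.
* Profiles follow the pixel lattice; no oblique rays, no resampling, no
  smoothing. All sub-pixel precision comes from linear interpolation at the
  crossings.
* **Contrast-agent handling**: when the outward scan toward the 5% threshold
  re-rises from its running minimum by more than 10% of peak while still above
  the threshold, or dwells in a 5%-of-peak band for at least 1 mm (a sustained
  plateau), or reaches the grid edge without crossing, the direction's halo is
  reported as 0 and flagged. The 10%/1 mm/5% defaults separate a genuine
  adjacent structure from the monotone Gaussian-like tail of the
  calcification itself, whose value drops by far more than 5% of peak per
  millimetre near the 5% crossing for any plausible PSF width; they are
  deliberately coarse, and flagged directions should be inspected rather than
  trusted.

## The synthetic phantom

`phantom_spec()` + `render_scene()` generate scenes with known ground truth:

1. rasterize the shape (disc, circular-segment "eccentric" plaque, or annular
   stent) at `supersampling`× the pixel grid (default 16×; partial volume),
2. scale to `peak_hu` (an optional contrast-agent disc adds its amplitude),
3. convolve with an isotropic Gaussian PSF of `psf_sigma_mm`,
4. box-average down to the reconstruction matrix (`fov_mm`/`matrix_size`),
5. add i.i.d. Gaussian noise of `noise_sd_hu`, and
6. clip to `[hu_floor, hu_ceiling]` (defaults −1024 / 3071 HU, the 12-bit
   clinical range).

Defaults emulate the conditions of a bench phantom study: calcification
diameters 4–6 mm; FOV 150 or 300 mm at matrix 512 (0.293 / 0.586 mm pixels);
a five-level virtual-monochromatic energy ladder (40–140 keV) whose peak
attenuations 3071/1404/871/687/654 HU and background noise SDs
15.41/7.33/7.73/8.14/8.23 HU are typical of a dual-source scanner, with the
40 keV peak pinned at the display ceiling; and a four-level polychromatic
ladder (80–140 kVp, peaks 2276–1505 HU). The PSF width is not something a
scene states about itself, so σ defaults to 0.5 mm with 0.3–0.8 mm used in
tests — stand-in values chosen to place the blooming halo (≈0.6–0.7 mm at
σ = 0.5) in the clinically reported range of roughly one pixel.

The generator is a *measurement testbed*, not a CT simulator: there is no
sinogram or filtered backprojection, no beam hardening, no vendor
reconstruction kernel, no correlated or non-Gaussian noise, and energy enters
only as amplitude scaling (plus clipping). Consequences worth spelling out:

* Passing tests demonstrate the measurement pipeline's correctness and its
  scale invariance; they do **not** demonstrate that real scanners show no
  energy dependence — real reconstructions can change the effective PSF with
  energy, which is exactly what this metric would then detect.
* Under a Gaussian PSF the FW3M *overestimates* a plateau-reaching disc's
  diameter by $2 z_{1/3}\sigma$ (with $\Phi(-z_{1/3}) = 1/3$,
  $z_{1/3} \approx 0.431$; ≈0.35 mm at σ = 0.5 mm before curvature
  correction), while the FWHM of a symmetric edge-spread is nearly unbiased.
  Which estimator is more accurate on a given scanner depends on the true
  point-spread profile; the package reports both.

## Numerical choices

* PSF taps are *cell-integrated* Gaussians (differences of the normal CDF
  over each fine sample cell), renormalized to unit sum; blur uses
  zero-padded FFT convolution on a patch around the shapes (background is
  exactly 0 HU). A kernel larger than the grid is rejected.
* The closed form of the blurred disc used by `analytic_profile()` is the
  noncentral-χ² CDF identity: a disc of radius $R$ convolved with an
  isotropic Gaussian at radial distance $r$ equals
  $\mathrm{peak} \cdot P\!\left[\chi^2_2\!\big((r/\sigma)^2\big) \le (R/\sigma)^2\right]$.
  Tests cross-check it against independent brute-force quadrature.
* Rendering fidelity: at 16× supersampling the rendered central row tracks
  the pixel-averaged continuum field to ≈1.2 HU (the residual is the
  O(fine-pixel) binarization of the shape indicator); widths and halos track
  dense continuum root-finding to ≲0.05 mm at 0.293 mm pixels. At 0.586 mm
  pixels the *linear-interpolation chord error* on the convex 5%-of-peak tail
  grows to ≈0.1 mm — an intrinsic floor of lattice profiles with linear
  interpolation, not removable without resampling, and worth remembering when
  comparing absolute halo values across FOVs.
* Study pipelines rank nanometre-rounded medians before the Friedman test:
  pure amplitude scaling reproduces measurements only to ~10⁻¹⁶–10⁻¹⁴ mm
  (floating-point jitter of the interpolation), which must not break exact
  rank ties in the noise-free case.
* Degenerate inputs fail loudly: profiles that never fall below a threshold
  ("unbounded width", with the side named), flat profiles ("no peak"), empty
  masks, zero background SD, constant Friedman tables (statistic 0, p 1 — the
  only silent degeneracy, because it is the correct answer).

## Statistics

Comparisons across energy levels follow a nonparametric repeated-measures
design: per-target medians over repeat scans (five by default), then a
Friedman rank test across energy levels with targets as blocks. The statistic
is implemented from within-block midranks with the tie correction
$\chi^2 = (k-1)\sum_j (R_j - n(k+1)/2)^2 / (A - C)$ and referred to
$\chi^2_{k-1}$; tests verify it against exhaustive within-block permutation
enumeration. Diameter-error comparisons against a fixed reference use a
Wilcoxon signed-rank test whose null distribution is computed exactly by
convolution over (doubled) midranks for n ≤ 25 — valid under ties, unlike the
textbook tables — and by a tie-corrected, continuity-corrected normal
approximation beyond. All tests are two-sided with α = 0.05.

Distortion-angle bookkeeping for physical phantoms combines two orthogonal
view angles as
$\theta = \arctan\!\sqrt{\tan^2\theta_1 + \tan^2\theta_2}$ and converts to a
length error $|1 - 1/\cos\theta| \times 100\%$. Summaries round per-scan
percent errors to two decimals before averaging — the precision such tables
are published at, and (non-obviously) the only convention under which the
published SD of the bundled reference table is reproduced.

## Problem sizes

The test-suite and the acceptance script size their simulations for a
single-core desk run: 200 simulated experiments (3 targets × 5 scans ×
5 energy levels each) for the null-behaviour study, 2000 replicates for the
type-I-error check of the 23-block clinical design, and 12–18 rendered scenes
for the oracle sweeps. These complete in a few minutes; all are plain
function arguments and scale up directly.

## Worked example

```{r example}
library(bloomquant)

spec <- phantom_spec("concentric_disc", diameter_mm = 6, peak_hu = 1404,
                     psf_sigma_mm = 0.5, noise_sd_hu = 7.33, seed = 7)
img <- render_scene(spec, energy_label = "70keV")
measure_bloom(img)

res <- run_phantom_study(study_config(seed = 1))
res$friedman
```

## Known limitations

* Energy dependence enters only through amplitude; vendor-specific PSF or
  kernel changes with energy are out of scope (and are the main candidate
  explanation when real data *do* show energy effects).
* The eccentric shape is a circular segment and the stent a perfect annulus;
  real plaque geometry is messier, and the four-direction cardinal sampling
  under-resolves strongly anisotropic shapes.
* DICOM files are not read or written; images travel as delimited-text
  matrices with a metadata sidecar (`write_image()`/`read_image()`), which
  round-trip exactly.
* At 0.586 mm pixels the halo carries an ≈0.1 mm discretization uncertainty
  (see *Numerical choices*); comparisons *across energy levels at a fixed
  geometry* are unaffected, which is why the pipeline's conclusions are
  phrased as within-design contrasts.
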