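# bloomquant

Quantitative measurement of the blooming artifact that coronary-artery
calcifications produce on CT images.

Calcifications bloom: system blur and partial-volume averaging spread their
high attenuation into neighbouring pixels, making the calcified spot look
larger and the adjacent lumen narrower. Radiologists often expect higher
X-ray energy levels (tube kVp, or keV of virtual monochromatic dual-energy
reconstructions) to reduce the artifact, because the calcification's
attenuation drops. `bloomquant` turns that question into pixel arithmetic,
for imaging scientists and segmentation-algorithm developers who need a
number rather than a visual impression.

## The measurement

On a line profile of attenuation (HU) through the calcification centre,
against a 0 HU background:

* **Actual calcified length** = FW3M, the full width at one *third* of peak:
  sub-pixel crossings of `T = peak/3` found by linear interpolation, walking
  outward from the peak (FWHM, `peak/2`, is computed the same way);
* **per-direction halo** = distance from the FW3M edge to the outward
  crossing of `0.05 × peak`, clamped at ≥ 0, in each of the four cardinal
  directions (directions blocked by an adjacent contrast-agent plateau are
  flagged and contribute 0);
* **adjacent pixels affected by calcification** = mean of the four halos
  (mm and pixel units), equivalently `L_brightened − L_actual`.

Both thresholds are fractions of the peak, so the metric is exactly invariant
under amplitude scaling — which is why changing only the energy level of an
otherwise identical acquisition cannot move it. The package ships a digital
phantom generator (supersampled rasterization → Gaussian PSF blur →
partial-volume downsampling → noise → HU clipping) with known ground truth,
image-quality statistics (`CNR = (HU_ROI − HU_bg)/SD_bg`, `SNR =
HU_ROI/SD_bg`, `noise = SD_bg`), phantom distortion-angle arithmetic
(`θ = arctan√(tan²θ₁ + tan²θ₂)`, error `(1 − 1/cos θ)·100%`), and the
rank-based tests used to compare energy levels (tie-corrected Friedman,
exact Wilcoxon signed-rank).

## Worked example

```r
library(bloomquant)

spec <- phantom_spec("concentric_disc", diameter_mm = 6, peak_hu = 1404,
                     psf_sigma_mm = 0.5, noise_sd_hu = 7.33, seed = 7)
img <- render_scene(spec, energy_label = "70keV")
measure_bloom(img)
#> <bloom_measurement>
#>   actual length (FW3M): 6.326 mm (h 6.330, v 6.323)
#>   brightened length:    6.977 mm
#>   adjacent affected:    0.651 mm (1.111 px)
#>   halos u/d/l/r (mm):   0.685 / 0.631 / 0.651 / 0.636
```

A 6 mm calcification blurred by a 0.5 mm PSF reads as 6.33 mm of "actual"
calcified length (the FW3M threshold bias of a Gaussian edge), surrounded by
a 0.65 mm brightened halo — about 1.1 pixels at the 300 mm FOV — in every
direction, as a symmetric disc should be.

A complete study — 3 calcification sizes × 5 repeat scans × 5 energy levels,
median-reduced and Friedman-tested:

```r
res <- run_phantom_study(study_config(seed = 1))
res
#> <study_result> 75 measurements (3 targets x 5 energies x 5 scans)
#>   Friedman on adjacent-affected medians: chi2 = 2.667 (df 4), p = 0.6151
```

No significant energy effect, as amplitude scaling predicts. Distortion
bookkeeping for a physical phantom:

```r
s <- summarize_angles(phantom_distortion_angles()$angle_deg)
round(c(s$angle$mean, s$angle$sd, s$angle$max), 2)
#> [1] 1.27 0.37 2.06
round(c(s$error_pct$mean, s$error_pct$max), 2)
#> [1] 0.03 0.06
```

A worst-case tilt of ~2° corresponds to a 0.06% length error — negligible
against pixel spacing.

The methods vignette (`vignettes/blooming-quantification.Rmd`) documents the
model, threshold conventions, flagging rules, numerical choices and
limitations. A thin CLI over the same functions is in
`inst/cli/bloomquant.R` (`simulate`, `measure`, `qc`, `distortion`,
`compare`, `run-phantom-study`).

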