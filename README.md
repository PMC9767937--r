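# prfrecon

Population receptive field (pRF) mapping and fMRI-based visual-field
reconstruction for studying how peripheral visual field defects — as occur in
glaucoma — are expressed in visual cortex.

In glaucoma, retinal damage deprives parts of visual cortex of their input.
Whether the adult cortex reorganizes in response (receptive fields shifting or
enlarging) or merely reflects the altered input is impossible to decide
without a control condition that reproduces the deprivation itself. The
experimental device this package implements is the *simulated scotoma* (SS):
a healthy control views the same retinotopy stimulus through a
contrast-attenuation layer built from the patient's perimetry, so that any
patient-vs-control difference beyond the SS condition points to changes in
the cortex rather than in the eye.

The package provides every stage of that analysis as reusable, fully
synthetic-testable code:

- **Perimetry handling** — CSV ingestion of per-eye total-deviation
  sensitivities (dB), binocular integration by the per-point maximum, and
  conversion to contrast masks via the decibel power law
  `m = 10^(dev/10)` (a 3 dB loss halves stimulus contrast).
- **Stimulus generation** — the drifting-bar luminance-contrast retinotopy
  aperture movie (8 directions; full passes of 16 steps interleaved with half
  passes plus blanks; 136 frames = 204 s at TR 1.5 s) and its
  simulated-scotoma variant.
- **Synthetic cohorts** — ground-truth pRF sheets (2-D Gaussians whose size
  grows with eccentricity), forward-simulated BOLD (HRF convolution, cosine
  drift, AR(1) noise), scotoma-linked gain attenuation
  `gain × (10^(dev/10))^κ`, and injectable pRF shifts/enlargements.
- **pRF estimation** — `prf_fit()`, the package's central estimator: per
  voxel, the predicted response is the overlap of the stimulus aperture with
  an isotropic Gaussian receptive field convolved with a double-gamma HRF;
  parameters come from a coarse grid search plus derivative-free local
  refinement, maximizing variance explained (VE). Full-field (FF) and
  scotoma-field (SF) variants, responsiveness thresholding (VE ≥ 0.15,
  eccentricity 0–7°), and a dense micro-probing variant are included.
- **Visual-field reconstruction** — back-projection of the fitted receptive
  fields onto the visual field (sampling density `Σ_v VE_v · G_v(p)`,
  normalized, expressed as `10·log10` dB), and classification of a subject's
  map against a normative control group at the 90/95/98/99/99.5% two-sided
  empirical boundaries.
- **Group statistics** — BOLD modulation (series SD), 1° eccentricity
  binning, normalized pRF-property histograms, pair-vs-baseline
  deviation-rank inference (the rank of a patient–control discrepancy within
  the control–control discrepancy distribution), quadrant summaries,
  Euclidean position displacements, mixed-effects severity slopes
  (`y ~ x + (1 + x | subject)`), and the per-participant median pRF-size
  Welch test.

## Worked example

Simulate a patient with a deep upper-left quadrant scotoma, fit pRFs, and
reconstruct their visual field:

```r
library(prfrecon)

grid  <- archetype_grid("quadrant", depth = -20, quadrant = "UL")
movie <- make_lcr_movie(n_pix = 41)
mask  <- build_contrast_mask(grid, movie)
mask
#> Contrast mask 41x41 px (0.350 deg/px), values in [0.010, 1.000]

spec  <- sim_spec(n_units = 80, seed = 1)
sheet <- apply_damage(sample_sheet(spec), grid, kappa = 1)
ts    <- preprocess(simulate_bold(sheet, movie, spec = spec))
fit   <- prf_fit(ts, effective_aperture(movie, "FF"))
fit
#> pRF fit: 80 units, 128 frames (TR 1.50 s), grid + refine
#>   median VE 0.353; 47/80 units pass VE >= 0.15 & ecc <= 7

mdl <- threshold_models(fit)
quadrant_summary(mdl, bold_modulation(ts)[mdl$unit])[, c(1, 2, 3, 6)]
#>   quadrant  n mean_sigma mean_modulation
#> 1       UL  0         NA              NA
#> 2       UR 14   1.139757       0.1633798
#> 3       LL 21   1.090667       0.1601771
#> 4       LR 12   1.506634       0.1647952

reconstruct_vf(fit, vf_grid(spacing = 0.5))
#> Sensitivity map: 613 positions, range [-20.6, 0.0] dB (floor -40)
```

The -20 dB quadrant loss attenuates the gain of the affected voxels by a
factor 100 (`kappa = 1`), so no voxel with a receptive field in the upper-left
quadrant passes the responsiveness threshold (`n = 0`) and the reconstructed
sensitivity map bottoms out near -20 dB there, while the intact quadrants sit
near 0 dB. `plot(fit)` draws the visual-field coverage;
`normative_deviation()` classifies such a map against a set of control maps;
`make_cohort()` / `run_all()` scale this to matched glaucoma–control cohorts.

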