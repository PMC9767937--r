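---
title: "Simulated scotomas, pRF mapping and visual-field reconstruction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulated scotomas, pRF mapping and visual-field reconstruction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its science: the forward model, the
estimators, the synthetic data that everything is validated on, the numerical
choices behind the defaults, and the limits of what the validation shows.

## The problem

Peripheral visual field defects (scotomas), as caused by glaucoma, deprive
parts of early visual cortex of their input. fMRI population receptive field
(pRF) mapping can chart that deprivation: each voxel's response is modelled
as driven by a restricted region of the visual field, and changes in the
fitted positions and sizes of those regions are candidate signatures of
cortical reorganization. The confound is that an artificial scotoma imposed
on a healthy observer produces similar pRF changes. The analysis implemented
here therefore revolves around a *simulated scotoma* (SS): the patient's
perimetry is turned into a contrast-attenuation mask, the matched control is
"given" the same defect optically, and patient-vs-control differences are
judged against control-vs-control variability.

## From perimetry to contrast masks

Perimetric total-deviation values (dB, one per test point, negative = loss)
are integrated binocularly by the per-point maximum of the two eyes — under
binocular viewing the better eye dominates detectability. Deviations map to
contrast multipliers on the decibel power scale,

$$ m(d) = \min\!\left(10^{d/10},\ 1\right), $$

so a 3 dB loss halves contrast and a 10 dB loss leaves 10%. This is the only
mapping consistent with treating perimetric dB as attenuation of stimulus
power; positive deviations (better than normative) saturate at full contrast.
An optional floor treats deviations below a configurable level (e.g. −15 dB)
as absolute loss; it is off by default because the power law already leaves
only 3% contrast at −15 dB.

Masks are built by interpolating the dB values to pixel resolution and
mapping pointwise. Perimetry layouts are regular lattices (the 10-2 layout, a
2° lattice within 10°, is the natural companion of a 7°-radius stimulus), so
the package interpolates bilinearly on the inferred lattice: exact at the
nodes, linear in between, monotone (no overshoot outside [0, 1]). Cells of
the lattice without a test point are filled from the nearest point; queries
beyond the lattice bounding box clamp to its edge, the lattice analogue of
nearest-point extrapolation. A layout that does not form a lattice falls back
to nearest-point interpolation throughout. How the original analyses
interpolated between test points is not recorded anywhere we know of; linear
interpolation is the conservative choice.

## The stimulus

The luminance-contrast retinotopy run is a bar aperture (width 1.75°)
drifting across a 7°-radius field in 16 equally spaced steps, one per
TR = 1.5 s, in 8 directions. After each full pass the next direction is
truncated: the bar crosses half the field (8 steps) and a blank screen
follows for the same duration. With the four cardinal directions as full
passes interleaved with the four diagonals as truncated passes — the exact
interleaving is a documented configuration default, since only the totals are
constrained — the design is 128 frames; 8 leading dummy frames (discarded
before analysis, emulating scanner saturation) give 136 frames = 204 s. A
block-design localizer preset (17 × 8-frame on/off blocks + 8 dummies = 144
frames = 216 s) is also provided.

The bar's carrier texture (0.5 cycles/°, counterphase flicker) is not
rendered: pRF estimation operates on contrast apertures, so frames store
aperture contrast in [0, 1] and the carrier parameters ride along as
metadata. The default raster is 101 × 101 pixels over ±7° (0.14°/pixel);
validation code mostly uses 41 × 41 (0.35°/pixel), which changes parameter
recovery negligibly while keeping grid searches fast.

Two model apertures derive from a movie: the full-field (FF) aperture — the
pristine binary bar — and the scotoma-field (SF) aperture, the bar multiplied
by the contrast mask, for fitting models that "know" the simulated scotoma.
With an all-ones mask the two are identical by construction, and the fits are
bit-for-bit equal.

## The forward model and the synthetic generator

A unit (voxel) with centre $(x_0, y_0)$ and size $\sigma$ responds to frame
$s(\cdot, t)$ with neural drive

$$ n(t) = \frac{\sum_p s(p, t)\, e^{-\|p - (x_0, y_0)\|^2 / 2\sigma^2}}{2\pi\sigma^2 / a_p}, $$

where $a_p$ is the pixel area: the overlap of the aperture with the receptive
field, normalized by the *analytic* Gaussian mass. (Normalizing by the
in-raster sum instead would rescale the tail of an off-raster receptive field
to full sensitivity, making far-peripheral units spuriously responsive.) The
BOLD signal is $n \ast h$ with $h$ a double-gamma HRF (peak 5 s, undershoot
15 s, peak:undershoot 6:1, sampled at the TR) — the acquisition HRF is not
identifiable from these data, so the same declared kernel is shared verbatim
between simulator and fitter, which keeps noiseless round trips exact to
machine precision.

The synthetic generator defines the study conditions for all validation:

- **Sheets.** Centres uniform over the 7° disc; sizes
  $\sigma = 0.5 + 0.2\,\rho$ degrees (eccentricity $\rho$) with lognormal
  jitter (sdlog 0.15) — a typical early-visual size–eccentricity line;
  gain 1 (percent signal at sustained full-field drive). Uniform sampling is
  used rather than cortical-magnification weighting: binned analyses
  normalize counts anyway, and uniform keeps quadrant counts balanced.
- **Noise.** Slow drift (amplitude 0.5% signal) as a random unit mixture of
  the two lowest cosines of the analysis segment — exactly the structure a
  discrete-cosine high-pass filter targets — plus AR(1) Gaussian noise
  (coefficient 0.3 at TR 1.5 s, a typical fMRI autocorrelation) with
  stationary SD `noise_sd`.
- **Reference noise.** `noise_sd = 0.12` is the package's reference level,
  calibrated once so that the default fitter attains a median variance
  explained of ≈ 0.5 on default sheets — the operating point at which all
  noisy-regime validation is run.
- **Damage.** A perimetry grid attenuates unit gain by $m(d)^\kappa$ with
  $d$ the deviation interpolated at the unit's centre. $\kappa$ is a free
  simulation knob, not an estimate of biology: no quantitative dB-to-BOLD
  link is established for real cortex. $\kappa = 1$ (gain follows stimulus
  contrast) is the default severity used in validation.
- **Plasticity.** Injectable signatures: *enlarge* multiplies in-region
  sizes by $1 + m$; *shift* moves in-region centres $m$ degrees radially away
  from the scotoma centre.
- **Cohorts.** `make_cohort()` mirrors the matched-pairs design (default 19
  pairs): per pair, a scotoma archetype (quadrant loss, superior arcuate,
  nasal step; depth drawn from −30…−10 dB), a damaged "glaucoma" dataset
  under the full-field stimulus, and one healthy control simulated twice —
  once through the SS stimulus, once without. All seeds derive from the
  master seed and are recorded in the manifest.

## Preprocessing

The first 8 frames are discarded; raw-intensity series are converted to
percent signal change about their mean (series already in percent units are
recognized by their scale and only centred); and a discrete-cosine high-pass
filter with cutoff 0.001 Hz is regressed out. One subtlety: for a 192 s run
the lowest nonzero DCT frequency is 0.0026 Hz, so a literal "remove all
components below 0.001 Hz" removes nothing but the mean, while drift slower
than the run fundamental is real and aliases into the low-order terms. The
filter therefore always removes at least the two lowest cosine terms, plus
any term under the cutoff. The orthonormal nuisance basis is stored with the
preprocessed series, and the fitters project their model predictions through
the same residualizer — the standard GLM treatment, and the reason noiseless
recovery is exact rather than merely close.

## pRF estimation

`prf_fit()` fits each unit in two stages. The coarse stage scores every
candidate $(x_0, y_0, \sigma)$ on a lattice (default 0.5° spacing over ±8°,
$\sigma \in \{0.25, 0.5, 1, 1.5, 2, 3, 4\}°$ — the original search space is
unpublished, so the default covers the stimulated field with margin) by the
variance its convolved drive explains; with amplitude and baseline free, VE
is the squared correlation, so the whole stage is one matrix product.
Candidates are pre-sorted by (σ, eccentricity), so ties — including
duplicated candidates — resolve deterministically toward the smaller, more
foveal model. The refine stage runs Nelder–Mead (derivative-free; the
objective is piecewise-smooth in the raster) from the best candidate, bounded
to ±10° and σ ∈ [0.05, 10]°, and is discarded if it fails to improve VE, so
refinement never degrades a fit. Zero-variance series return a flagged
degenerate record rather than an error. Thresholding retains models with
VE ≥ 0.15 and eccentricity within 0–7°.

Micro-probing is the complementary estimator: a dense lattice of small
fixed-σ Gaussian probes (default σ = 0.5°, 1° spacing over ±7°) is regressed
against each series; probe weights are VE signed by the fitted amplitude and
clipped at zero, and each unit is summarized by the weighted centroid and RMS
spread. This is a deliberate simplification of the published micro-probing
technique — probe distribution, acceptance rule and aggregation follow the
description above, not the original implementation, whose update rules are
not reproducible from public text.

### Precision at the reference operating point

Noiseless recovery is exact (coarse stage) and within 0.05° (refined). At
the reference noise level the estimator is close to the information-theoretic
limit but that limit is itself substantial: the Cramér–Rao bound for pRF
position at VE = 0.5, computed from the forward-model Jacobian, is 0.30–0.52°
across the disc (worse peripherally), and the observed median position error
is ≈ 0.3–0.5° with median relative σ error ≈ 25%. Tighter figures sometimes
quoted for pRF mapping assume either higher SNR, multiple averaged runs, or
foveally concentrated voxels. Downstream power calculations should use these
measured figures, not aspirational ones; the acceptance test records the
stricter bounds and their outcome honestly.

## Visual-field reconstruction and normative maps

Back-projection evaluates $\sum_v w_v\, e^{-\|p - c_v\|^2 / 2\sigma_v^2}$ on
a 0.25°-spacing grid within 7°, normalized to maximum 1, with $w_v$ the
model's VE by default (β and count weighting are options; which weighting the
original maps used is not stated). The dB map is $10 \log_{10}$ of the
density, floored at −40 dB.

`normative_deviation()` ranks the subject's value per position within the
empirical control distribution (mid-rank on ties, tail probability
$p = (\#\{c < v\} + \tfrac12 \#\{c = v\})/m$) and labels the outermost
two-sided boundary violated among 90/95/98/99/99.5%. With ~18 controls the
outer boundaries saturate at the sample extremes — a subject below every
control violates all of them and is labelled 99.5% — a documented small-sample
limitation, not a bug. Under exchangeability a held-out control falls outside
the 5–95% band at $2/(m+1) \approx 10.5\%$ of positions for $m = 18$, which
the leave-one-out calibration test confirms.

## Group statistics

- **BOLD modulation** is the SD of the preprocessed percent-signal series.
- **Binning** uses half-open 1° eccentricity bins with bootstrap 95%
  intervals; empty bins are missing, never zero.
- **Histograms** of thresholded-model eccentricity (1° bins over 0–7°),
  polar angle (16 equal bins over [0, 2π); the original bin count is
  unpublished) and size (0.25° bins over 0–5°, Scott's rule at n ≈ 500)
  are normalized to unit mass. The polar angle convention places 0 at the
  upper vertical meridian, increasing counterclockwise, so the upper-left
  quadrant is (0, π/2]; boundary meridians belong to the counterclockwise
  quadrant.
- **Pair deviation** between two histograms is the per-bin signed difference
  with aggregate $\sum |\Delta|$ (range [0, 2]); the aggregate statistic and
  the per-bin ranks are a declared reconstruction, as the original summary
  statistic is described only qualitatively.
- **Deviation rank**: the pair aggregate is ranked among the baseline
  aggregates of the matched control against every *other* control —
  leave-self-out, giving $n - 1 = 18$ baseline values for 19 controls (a
  count of 19 would require the self-pairing, which is identically the SS/NS
  comparison; the count is exposed as an argument). Significance is
  one-sided at the 95th percentile of rank/(n+1); under the null exactly the
  top rank is significant, a 1/19 ≈ 5.3% false-positive rate.
- **Severity slopes** use `lmerTest::lmer(y ~ x + (1 + x | subject))` with
  Satterthwaite p-values, falling back to OLS (with a warning) for degenerate
  designs; r² is reported with the slope's sign attached, matching the
  field's signed-r² reporting convention.
- **Size distributions** are compared by per-participant median σ and a
  Welch two-sample t-test.

## What the synthetic validation does and does not show

The cohort-level rank statistics are validated on ground-truth sheets passed
through an *estimation-noise emulation*: errors (Δx, Δy, log σ-ratio) are
resampled from an empirical table measured by actually fitting
reference-noise simulations, then applied to fresh sheets. This keeps 200-
cohort null calibrations and 50-cohort power runs tractable (refitting
20 × 500 voxels per cohort would be thousands of CPU-hours) while preserving
the fitter's real, heavy-tailed error distribution; the full
simulate–preprocess–fit–reconstruct path is exercised end-to-end at smaller
sizes elsewhere in the suite. Under this emulation the deviation-rank null is
uniform (KS p ≫ 0.01 over 200 cohorts; significance rate ≈ 5%), detection of
a −20 dB quadrant scotoma flags > 90% of the quadrant at 95%-or-worse, and
severity slopes recover the right signs. The power to detect a ×1.5 quadrant
σ enlargement at the reference operating point is ≈ 40–50%, not the ≥ 80%
that would follow from assuming ~15% σ precision — a direct consequence of
the information bound above; detecting such effects reliably requires either
higher SNR, multiple runs, or pooling across properties.

What passing these tests shows about real data is limited in the usual ways:
the generator has isotropic Gaussian receptive fields, a known shared HRF, no
eye movements, attention, or session effects, and damage that follows the
perimetry exactly. Real effects of those factors land mostly in the baseline
control–control variability, which the rank statistic is designed to absorb —
that is precisely why the pair-vs-baseline construction, not a parametric
test, is the primary inference.

## Numerical and interface choices

- Problem sizes in the shipped validation: 41 × 41 rasters, 150–500 units
  per subject, 19-pair cohorts, 200/50 cohort replicates for
  calibration/power — chosen as the smallest sizes at which the monitored
  quantities are stable.
- All randomness flows through explicit integer seeds (`sim_spec$seed`,
  per-pair derived seeds in cohorts, `--seed` in the CLI); generators save
  and restore the caller's RNG state.
- Degenerate inputs never crash the pipeline: constant series, empty
  quadrants, empty histograms and missing bins are flagged records.
- The pipeline surface (`run_simulate()`, `run_fit()`, `run_report()`,
  `run_all()`, YAML `run_config()`) writes plain-text bundles (CSV series
  and tables, JSON sheets/manifests) so cohorts diff and hash cleanly; a thin
  Rscript dispatcher in `inst/cli/` wraps the same functions for shell use.
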