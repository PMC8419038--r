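---
title: "Quantifying intravascular OCT-NIRF pullbacks: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intravascular OCT-NIRF pullbacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octnirf)
```

## The measurement problem

A rotational OCT-NIRF catheter acquires, at each pullback position, a
polar OCT frame (A-lines x depth) and one NIRF value per A-line. The NIRF
channel reports a fluorescent agent bound to plaque macrophages, but the
detected intensity is not directly comparable across A-lines, frames or
animals:

1. light crosses a variable thickness of blood between the catheter
   sheath and the vessel wall, attenuating roughly exponentially with
   distance;
2. injected dose, optical coupling and detector gain differ per animal;
3. serial comparisons require pairing cross-sections of two pullbacks
   acquired days apart with different catheter positions.

`octnirf` addresses (1) with contour-based distance compensation, (2)
with the plaque target-to-background ratio (pTBR), and (3) with
landmark-anchored frame matching. All frame indices are 0-based with
half-open `[start, end)` intervals; A-line 0 sits at angle 0 with angles
increasing counterclockwise. One stated convention avoids off-by-one
drift between modules.

## Lumen segmentation

`segmentLumenFrame()` works per A-line on the polar frame: the depth
profile is median-filtered (window 3), the background level and robust
spread are estimated by the median and MAD of the profile, and the lumen
border is the first depth sample rising above
`background + kMAD * spread`, snapped to the local gradient peak; the
earliest (shallowest) candidate wins because the lumen border is the
first tissue interface. A-lines without a suprathreshold wall — guidewire
shadow, low contrast — are flagged invalid and filled by periodic linear
interpolation; radii are finished with a circular moving median
(`smoothWindow`, default 5). A frame fails with an error when more than
half of its A-lines are undetectable, rather than returning a fabricated
contour.

Parameters: `kMAD` (default 6) trades false walls against missed walls;
at the generator's detector noise (sd 0.02 on a 0-1 scale against a wall
amplitude of 0.85) detection operates at >10 sigma. The MAD floor is
relative to the frame maximum, which keeps the detector exactly invariant
under positive intensity rescaling and equivariant under A-line rotation
— two properties the test suite asserts.

## Distance-decay compensation

The relative detected fraction `c(d)` at sheath-to-lumen distance `d`
(mm) is either parametric monoexponential, `c(d) = exp(-mu (d - dRef))`,
or a tabulated curve with linear interpolation
(`fitCompensationCurve()`). Both are normalised to 1 at the smallest
calibrated distance, so compensation (`raw / c(d)`) only ever amplifies —
a signal measured at calibration conditions is never attenuated. The
monoexponential default matches near-exponential light attenuation in
blood and is identifiable from a handful of phantom points; the tabulated
option admits any measured curve shape, projected onto the
non-increasing cone (a rising calibration trend contradicts distance
decay and triggers a warning). Distances outside the working range are
clamped to the nearest bound and counted in a warning rather than
aborting a pullback: contour noise at the range edge should not kill an
analysis.

## pTBR statistics

The per-animal background is the mean of the **five lowest** per-frame
maxima of the *compensated* signal over normal-looking segments —
computed on the compensated scale so that target and background share
units. Ties among frame maxima are resolved by stable sorting (value,
then frame index), making the statistic deterministic. `map2d =
compensated / background`; pTBR/Frame is the per-frame maximum of the
map; mean pTBR averages pTBR/Frame over the plaque interval. Because
every step is a ratio against a statistic of the same signal, pTBR is
invariant to global rescaling of the raw NIRF — asserted as a property
test.

## Serial analysis

`matchFrames()` anchors a piecewise-linear frame mapping at corresponding
side-branch landmarks, extrapolating outside the landmark span with the
nearest segment's slope (flagged). "Randomly sampled at regular
intervals" is resolved as a regular stride with a seeded random start
phase: the stride honours "regular intervals", the seeded phase honours
"randomly", and the result is reproducible. The default of 30 pairs per
pullback pair matches the study design this package models. Mapped
indices are rounded to the nearest frame and duplicate pairs removed with
the count reported.

Tertile stratification uses the type-1 (inverse-CDF) empirical quantile
at 1/3 and 2/3 of the baseline pTBR/Frame, with ties assigned to the
lower group — a deterministic rule chosen because no published convention
exists for this stratification; with distinct values the three groups
differ in size by at most one.

## Statistics battery

- `groupCompare()`: Kruskal-Wallis omnibus plus all pairwise two-sided
  Mann-Whitney U tests, Bonferroni-adjusted (`min(1, m p)`). Pairwise
  tests are exact when both groups have n <= 8 and no ties; otherwise the
  normal approximation with tie-corrected variance is used (no continuity
  correction — the plain large-sample approximation).
- `pairedCompare()`: Wilcoxon signed-rank (zero differences dropped and
  counted; all-zero differences are a degenerate-input error) or paired
  t. An exact constant shift gives zero-variance differences, where the
  t statistic is undefined; a deterministic jitter at 1e-12 relative
  scale yields the limiting vanishing p-value instead of an error.
- `gatedCorrelation()`: Pearson only when both variables pass
  Shapiro-Wilk at alpha = 0.05 (the analysis-wide significance level),
  Spearman otherwise, with the gate decision recorded.

## Biexponential clearance

`fitBiexponential()` fits `A1 exp(-l1 t) + A2 exp(-l2 t)` by
Levenberg-Marquardt with non-negativity bounds, initialised from a
log-linear fit to the terminal tail followed by curve peeling of the
residual, and a coarse multi-start grid as fallback. Components are
reported fast-first (`lambda1 > lambda2`). When one amplitude collapses,
the series is genuinely monoexponential: the data are refit with a single
exponential, reported as the slow (terminal) component and flagged. A
two-exponential fit yields two half-lives, and a study quoting a single
blood half-life leaves the attribution open; the fit therefore reports
both plus an AUC-weighted effective half-life (weights `A_i / lambda_i`)
and privileges none.

## Ex vivo validation

`friMeanPTBR()` is the plaque/normal ROI mean-intensity ratio on the
en-face FRI image. `samplePairedProfiles()` maps the FRI aorta axis onto
the pullback axis through matched bifurcation landmarks
(piecewise-linear) and samples both modalities on a shared 0.5 mm grid
between the outermost landmarks: in vivo, the maximum pTBR of the nearest
frame; ex vivo, the cross-axis mean of the nearest column.

For histology, `dabIntensityMap()` uses fixed standard optical-density
stain vectors for haematoxylin and DAB (no per-image unmixing — fixed
vectors are deterministic and adequate for single-chromogen sections);
the 0-1 antibody scale is the DAB optical density clipped at 1. The
positive rule is strictly `> 0.1`, and the positive-stained ratio divides
the summed suprathreshold intensities by the tissue pixel count — the
published ratio's denominator is not stated, so the tissue area is the
declared choice here, and `threshold` stays configurable. ORO and PSR
sections are scored by luminance-based tissue segmentation (background =
luminance above 0.9 of the white point for brightfield scans; below 0.05
for polarised dark-field) and stain-specific hue/saturation windows (red
band for ORO, red-magenta for brightfield PSR, red-orange birefringence
for collagen I); the windows are declared defaults, configurable per
image set, not reconstructions of any published parameter values.

## The synthetic-data generator

`generatePullback()` emulates the features the pipeline must handle:

- per-frame elliptical lumen with smooth longitudinal drift — the
  minimal geometry exercising both segmentation and distance variation;
  radii are quantised to the depth grid so the rendered wall and the
  recorded truth agree to the pixel;
- OCT A-lines with a sharp wall interface, exponential attenuation into
  tissue (0.15 mm length), a guidewire shadow sector, additive Gaussian
  noise, 8-bit quantisation (the storage depth of log-compressed OCT
  stacks, and what makes TIFF round trips bit-identical);
- NIRF `raw = source x exp(-mu d) + noise`, with the reference distance
  at the sheath surface (`c(0) = 1`, the smallest calibratable distance);
- plaque frames carry a focal angular source bump with unit peak (so the
  per-frame amplitude *is* the frame maximum), normal frames are
  homogeneous at roughly 1/9 the plaque amplitude;
- the serial model changes per-frame plaque amplitudes by
  `a + b x baseline + noise`, clipped at zero (fluorescence cannot be
  negative). The effect applies to plaque frames only: normal wall
  carries no targetable source, and a change applied uniformly to all
  frames would rescale the background by the same factor and cancel out
  of the pTBR ratio entirely, leaving no baseline-dependent response to
  detect. Landmarks are side-branch frame indices, shifted along with an
  optional longitudinal offset of the follow-up pullback.

All randomness in a generator call flows from one seed; identical
`(config, seed)` reproduce outputs bit for bit.

What the generator does **not** emulate: OCT speckle statistics, catheter
rotation artifacts (NURD), blood-pool attenuation of the OCT channel,
partial-volume mixing at the wall, or motion between cardiac phases.
Passing tests therefore demonstrate the correctness of the quantification
chain on idealised inputs with known truth — not segmentation robustness
on clinical-grade images.

## Numerical choices and degenerate inputs

- Segmentation ties (equal gradient peaks): earliest depth wins.
- Background ties: stable sort keeps frame order.
- Tertile ties: lower group.
- Compensation out-of-range: clamp + warn, never abort; zero raw stays
  zero.
- All-zero frames, empty masks, constant correlation inputs, all-zero
  paired differences, < 3 calibration distances, < 5 normal frames, < 2
  landmarks: explicit errors naming the violated precondition.
- The pipeline logs (rather than fails on) an undefined baseline-delta
  correlation, which arises when two time points are identical.

## Problem sizes

The shipped tests and the acceptance script run the full chain on
pullbacks of 40-150 frames at 64 x 64 to 96 x 96 samples per frame, 20
replicate serial simulations per effect strength, 10,000-replicate null
calibrations, 200 noisy pharmacokinetic refits and 50 synthetic slides —
sizes chosen so the whole suite completes in minutes on one CPU while
every statistic retains enough replication to be meaningful. The
generator's defaults (120 frames, 256 A-lines, 160 depth samples, 10 um
axial pitch, 0.2 mm frame pitch, plaque source 9x normal, decay 1.5/mm)
describe the full-scale study conditions the package models.

## Known limitations

- The monoexponential decay default is a model choice; a measured
  calibration table should be preferred when available (supported via
  `fitCompensationCurve(..., "tabulated")`).
- Segmentation assumes the lumen border is the first bright interface;
  dissections, thrombus or stent struts violate that assumption.
- Histology colour windows assume reasonably calibrated RGB scans; badly
  colour-shifted slides need per-set window overrides.
- Frame matching is longitudinal only; it does not correct rotational
  misalignment between time points (pTBR/Frame, a per-frame maximum, is
  insensitive to rotation).
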