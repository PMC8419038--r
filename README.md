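# octnirf

Quantification of dual-modal intravascular **OCT-NIRF** plaque imaging in R.

Catheter-based optical coherence tomography (OCT) combined with
near-infrared fluorescence (NIRF) images both the structure of an
atherosclerotic vessel wall and the molecular signal of a targeted
fluorescent agent bound to plaque macrophages. Turning the raw per-A-line
fluorescence of a pullback into a comparable inflammation index requires a
chain of corrections and statistics: the detected fluorescence decays with
the distance the light travels through blood, absolute intensities differ
between animals, and serial (baseline vs. follow-up) comparisons require
co-registering two pullbacks of the same artery. `octnirf` implements that
chain for researchers analysing intravascular OCT-NIRF studies, together
with the companion ex vivo validation steps (en-face fluorescence
reflectance imaging, stained-section scoring) and the pharmacokinetic
blood-clearance fit — plus a synthetic-data generator that produces every
input with known ground truth, so the whole pipeline is testable without
animal data.

## The quantities at the core

For a pullback with raw NIRF signal `raw[f, a]` (frame `f`, A-line `a`):

- **Distance compensation.** The lumen contour is segmented automatically
  on each polar OCT frame; the sheath-to-lumen distance `d[f, a]` enters a
  pre-determined calibration curve `c(d)` (monoexponential
  `c(d) = exp(-mu * d)` by default, `c(0) = 1` at the sheath), and
  `comp[f, a] = raw[f, a] / c(d[f, a])`.
- **Background.** Per animal: the mean of the **five lowest** per-frame
  maxima of the compensated signal over normal-looking segments.
- **pTBR map** `= comp / background`; **pTBR/Frame** `= max` of the map
  in each cross-section; **mean pTBR** `=` mean of pTBR/Frame over the
  plaque segment — the inflammatory index of the pullback.
- **Serial change.** Frames are matched between Day 0 and Day 7 through
  side-branch landmarks (30 pairs per animal by default);
  `delta pTBR/Frame = pTBR/Frame(Day 7) − pTBR/Frame(Day 0)`,
  `delta mean pTBR = mean pTBR(Day 7) − mean pTBR(Day 0)`; pairs are
  stratified by baseline tertiles and tested with the study's statistics
  battery (Kruskal-Wallis + Bonferroni-corrected Mann-Whitney, Wilcoxon
  signed-rank / paired t, Shapiro-Wilk-gated Pearson/Spearman).
- **Ex vivo.** FRI mean pTBR `=` plaque-ROI mean / normal-ROI mean;
  in vivo and ex vivo signals are co-registered via bifurcations and
  sampled on a shared 0.5 mm grid. Histology: DAB intensity on a 0–1
  colour-deconvolution scale with a strict `> 0.1` positivity rule
  (positive ratio `=` summed positive intensities / tissue pixels), and
  hue-window segmentation for oil red O and picrosirius red sections.
- **Pharmacokinetics.** Biexponential clearance
  `A1*exp(-l1*t) + A2*exp(-l2*t)` with both half-lives and an
  AUC-weighted effective half-life.

## Worked example

```r
library(octnirf)

cfg <- simConfig(nFrames = 60L, nAlines = 96L, depthSamples = 96L,
                 lumenRadiusMean = 1.05, plaqueRange = c(15L, 45L),
                 normalRanges = list(c(0L, 10L), c(50L, 60L)),
                 landmarkFrames = c(5L, 30L, 55L))
sim <- generatePullback(cfg, seed = 7)
sim$pullback
#> Pullback: 60 frames x 96 A-lines x 96 depth samples
#>   pixel pitch 0.01 mm, frame pitch 0.2 mm, catheter radius 0.45 mm
#>   NIRF range [0, 4.27] a.u.

contour <- segmentLumen(sim$pullback)
curve   <- compensationCurve(mu = 1.5, range = c(0, 3))
comp    <- compensate(nirfRaw(sim$pullback), contourToDistances(contour), curve)
quantifyPTBR(comp, annotationFromTruth(sim$truth))
#> PTBRResult: background = 1.038, mean pTBR = 8.693
#>   pTBR/Frame over 60 frames (plaque [15, 45)), range [0.941, 11.6]
```

The configured plaque source is 9x the normal wall; after segmentation,
compensation and background normalisation the mean pTBR lands at 8.69 —
the raw NIRF range (max 4.3) shows how much signal the distance decay
removes before compensation. The serial pipeline runs the whole analysis
on a baseline/follow-up pair in one call:

```r
rep <- runSerialPipeline(list(seed = 7L, sim = list(
  nFrames = 60L, nAlines = 96L, depthSamples = 96L, lumenRadiusMean = 1.05,
  plaqueRange = c(15L, 45L), normalRanges = list(c(0L, 10L), c(50L, 60L)),
  landmarkFrames = c(5L, 30L, 55L))))
rep$deltaMeanPTBR
#> [1] -3.31522
rep$correlation
#> pearson correlation: r = -0.6507, p = 9.896e-05 (n = 30)
rep$tertiles
#> tertileReport: boundaries at 8.216 / 9.128
#>  tertile  n meanDelta  semDelta
#>        I 10 -2.755255 0.2278803
#>       II 10 -3.284576 0.2190131
#>      III 10 -3.905828 0.4046994
```

With the default treatment-effect model (frames with higher baseline
source lose more signal), the follow-up mean pTBR drops by 3.3, baseline
pTBR/Frame correlates negatively with its change, and the highest
baseline tertile falls the most — the response structure the pTBR
statistics are designed to expose.

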