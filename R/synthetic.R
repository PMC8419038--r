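#' Build a simulation configuration
#'
#' Constructs a validated [SimConfig-class]. Defaults describe a
#' coronary-sized atheromatous vessel imaged with a rotational OCT-NIRF
#' catheter: a 120-frame pullback at 0.2 mm frame pitch, 256 A-lines per
#' frame, 10 um axial sampling, a focal plaque over frames 30-90 flanked by
#' normal-looking reference segments, a plaque NIRF source roughly nine
#' times the normal-wall source, monoexponential distance decay at 1.5 /mm,
#' and a follow-up effect model in which frames with higher baseline source
#' lose more signal (negative `effectB`).
#'
#' @param nFrames,nAlines,depthSamples pullback dimensions.
#' @param pixelPitch,framePitch mm per depth sample / per frame.
#' @param catheterRadius sheath radius, mm.
#' @param lumenRadiusMean,lumenEccentricity,lumenDrift lumen geometry: mean
#'   radius (mm), elliptical eccentricity, relative per-frame drift.
#' @param plaqueRange half-open 0-based frame interval of the plaque.
#' @param normalRanges list of half-open intervals of normal segments.
#' @param plaqueAmp,plaqueAmpSD,normalAmp,normalAmpSD per-frame source
#'   amplitude mean/sd (a.u.) for plaque and normal frames.
#' @param decayMu true distance-decay rate, per mm.
#' @param noiseSD additive NIRF detector noise sd (a.u.).
#' @param octNoiseSD additive OCT noise sd (0-1 intensity scale).
#' @param guidewireAlines width of the guidewire shadow sector, A-lines.
#' @param landmarkFrames 0-based frames of simulated side branches.
#' @param effectA,effectB,effectSD serial effect model on the per-frame
#'   plaque source amplitude: `delta = effectA + effectB * baseline + noise`.
#' @param serialShift longitudinal offset (frames) of the follow-up pullback.
#' @param seed default seed recorded in generated data.
#' @return a [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(nFrames = 40L, plaqueRange = c(10L, 30L),
#'                  normalRanges = list(c(0L, 8L), c(32L, 40L)))
#' cfg
#' @export
simConfig <- function(nFrames = 120L, nAlines = 256L, depthSamples = 160L,
                      pixelPitch = 0.01, framePitch = 0.2,
                      catheterRadius = 0.45,
                      lumenRadiusMean = 1.5, lumenEccentricity = 0.12,
                      lumenDrift = 0.08,
                      plaqueRange = c(30L, 90L),
                      normalRanges = list(c(0L, 20L), c(100L, 120L)),
                      plaqueAmp = 9, plaqueAmpSD = 1.2,
                      normalAmp = 1, normalAmpSD = 0.08,
                      decayMu = 1.5, noiseSD = 0.02, octNoiseSD = 0.02,
                      guidewireAlines = 12L,
                      landmarkFrames = c(5L, 60L, 110L),
                      effectA = 1, effectB = -0.5, effectSD = 0.8,
                      serialShift = 0L, seed = 1L) {
  ## tolerate ranges arriving from parsed YAML/JSON as nested lists/matrices
  plaqueRange <- as.integer(unlist(plaqueRange))
  if (is.matrix(normalRanges)) normalRanges <- asplit(normalRanges, 1L)
  normalRanges <- lapply(normalRanges, function(r) as.integer(unlist(r)))
  lmf <- as.integer(unlist(landmarkFrames))
  if (any(lmf < 0L) || any(lmf >= as.integer(nFrames)))
    stop("landmarkFrames must lie within [0, nFrames)")
  new("SimConfig",
      nFrames = as.integer(nFrames), nAlines = as.integer(nAlines),
      depthSamples = as.integer(depthSamples),
      pixelPitch = pixelPitch, framePitch = framePitch,
      catheterRadius = catheterRadius,
      lumenRadiusMean = lumenRadiusMean,
      lumenEccentricity = lumenEccentricity, lumenDrift = lumenDrift,
      plaqueRange = plaqueRange,
      normalRanges = normalRanges,
      plaqueAmp = plaqueAmp, plaqueAmpSD = plaqueAmpSD,
      normalAmp = normalAmp, normalAmpSD = normalAmpSD,
      decayMu = decayMu, noiseSD = noiseSD, octNoiseSD = octNoiseSD,
      guidewireAlines = as.integer(guidewireAlines),
      landmarkFrames = lmf,
      effectA = effectA, effectB = effectB, effectSD = effectSD,
      serialShift = as.integer(serialShift), seed = as.integer(seed))
}

## 0-based half-open [start, end) -> 1-based R indices
.rangeIdx <- function(r) seq.int(r[1] + 1L, r[2])

.inRange <- function(f, r) f >= r[1] & f < r[2]

## True lumen geometry: per-frame ellipse with smooth longitudinal drift,
## quantised to the depth-sample grid (the wall is rendered at exactly these
## radii, so truth and image agree to the pixel).
.makeGeometry <- function(config) {
  nF <- config@nFrames; nA <- config@nAlines
  theta <- 2 * pi * (seq_len(nA) - 1L) / nA
  f <- seq_len(nF) - 1L
  rBase <- config@lumenRadiusMean *
    (1 + config@lumenDrift * sin(2 * pi * f / nF))
  ecc <- config@lumenEccentricity
  idx <- matrix(0L, nF, nA)
  for (i in seq_len(nF)) {
    aAx <- rBase[i] * (1 + ecc)
    bAx <- rBase[i] * (1 - ecc)
    r <- aAx * bAx / sqrt((bAx * cos(theta))^2 + (aAx * sin(theta))^2)
    k <- round((r - config@catheterRadius) / config@pixelPitch)
    idx[i, ] <- pmin(pmax(as.integer(k), 4L), config@depthSamples - 12L)
  }
  radii <- config@catheterRadius + idx * config@pixelPitch
  list(idx = idx, radii = radii)
}

## Per-frame source amplitudes: plaque frames from N(plaqueAmp, plaqueAmpSD),
## all other frames from N(normalAmp, normalAmpSD), floored at 0.
.drawFrameAmp <- function(config) {
  nF <- config@nFrames
  amp <- pmax(stats::rnorm(nF, config@normalAmp, config@normalAmpSD), 0)
  pidx <- .rangeIdx(config@plaqueRange)
  amp[pidx] <- pmax(stats::rnorm(length(pidx), config@plaqueAmp,
                                 config@plaqueAmpSD), 0)
  amp
}

## Angular source weights: plaque frames carry a focal lesion (Gaussian bump
## with unit peak, centred opposite the guidewire); normal frames are
## angularly homogeneous. The per-frame maximum of the source map therefore
## equals the frame amplitude.
.sourceFromAmp <- function(config, frameAmp) {
  nF <- config@nFrames; nA <- config@nAlines
  centre <- nA %/% 2L
  a <- seq_len(nA) - 1L
  dAng <- pmin(abs(a - centre), nA - abs(a - centre))
  bump <- exp(-0.5 * (dAng / (nA / 8))^2)
  src <- matrix(frameAmp, nF, nA)
  pidx <- .rangeIdx(config@plaqueRange)
  src[pidx, ] <- outer(frameAmp[pidx], bump)
  src
}

## Guidewire shadow A-lines (centred at A-line 0, circular).
.shadowAlines <- function(config) {
  if (config@guidewireAlines <= 0L) return(integer())
  nA <- config@nAlines
  half <- config@guidewireAlines %/% 2L
  offs <- seq.int(-half, half + (config@guidewireAlines %% 2L) - 1L)
  sort(unique((offs %% nA) + 1L))
}

## Render OCT stack + raw NIRF from a geometry/source truth. Consumes RNG.
## OCT A-line model: low baseline, sharp wall interface at the lumen border
## with exponential attenuation into the tissue; the guidewire sector has no
## wall signal. Frames are clipped to [0, 1] and quantised to 8 bits.
.renderPullback <- function(config, geom, src) {
  nF <- config@nFrames; nA <- config@nAlines; nD <- config@depthSamples
  dist <- geom$radii - config@catheterRadius
  nirf <- src * exp(-config@decayMu * dist)
  if (config@noiseSD > 0)
    nirf <- nirf + stats::rnorm(length(nirf), 0, config@noiseSD)
  nirf <- pmax(nirf, 0)

  attLen <- 0.15  # mm, wall attenuation length
  base <- 0.05; wallA <- 0.85
  shadow <- .shadowAlines(config)
  kRow <- matrix(seq_len(nD) - 1L, nA, nD, byrow = TRUE)
  oct <- array(0, dim = c(nF, nA, nD))
  for (i in seq_len(nF)) {
    rel <- (kRow - geom$idx[i, ]) * config@pixelPitch
    fr <- base + wallA * exp(-pmax(rel, 0) / attLen) * (rel >= 0)
    if (length(shadow)) fr[shadow, ] <- base
    if (config@octNoiseSD > 0)
      fr <- fr + stats::rnorm(length(fr), 0, config@octNoiseSD)
    oct[i, , ] <- fr
  }
  oct <- round(pmin(pmax(oct, 0), 1) * 255) / 255
  list(oct = oct, nirf = nirf)
}

.newPullback <- function(config, rendered) {
  new("Pullback", oct = rendered$oct, nirf = rendered$nirf,
      pixelPitch = config@pixelPitch, framePitch = config@framePitch,
      catheterRadius = config@catheterRadius)
}

.newTruth <- function(config, geom, src, frameAmp, seed,
                      plaqueRange = config@plaqueRange,
                      normalRanges = config@normalRanges,
                      landmarks = config@landmarkFrames) {
  new("PullbackTruth", sourceMap = src, lumenRadii = geom$radii,
      frameAmp = frameAmp, decayMu = config@decayMu,
      plaqueRange = plaqueRange, normalRanges = normalRanges,
      landmarkFrames = landmarks, seed = as.integer(seed))
}

#' Generate a synthetic OCT-NIRF pullback with known ground truth
#'
#' Simulates one pullback: an elliptical, slowly drifting lumen rendered as a
#' polar OCT stack (sharp wall interface with exponential attenuation and a
#' guidewire shadow sector), and a raw per-A-line NIRF channel
#' `raw[f, a] = source[f, a] * exp(-decayMu * d[f, a]) + noise`, where
#' `d` is the sheath-to-lumen distance in mm and the detected fraction is 1
#' at the sheath surface (`d = 0`). Plaque frames carry a focal source bump
#' whose peak equals the per-frame amplitude; normal frames are homogeneous.
#' Identical `(config, seed)` reproduce the output bit for bit.
#'
#' @param config a [SimConfig-class].
#' @param seed integer seed for all randomness in this call; defaults to the
#'   seed recorded in `config`.
#' @return list with elements `pullback` ([Pullback-class]) and `truth`
#'   ([PullbackTruth-class]).
#' @examples
#' sim <- generatePullback(simConfig(nFrames = 30L, nAlines = 64L,
#'   depthSamples = 80L, plaqueRange = c(8L, 22L),
#'   normalRanges = list(c(0L, 6L), c(24L, 30L))), seed = 7)
#' sim$pullback
#' @export
generatePullback <- function(config, seed = config@seed) {
  validObject(config)
  set.seed(as.integer(seed))
  geom <- .makeGeometry(config)
  frameAmp <- .drawFrameAmp(config)
  src <- .sourceFromAmp(config, frameAmp)
  rendered <- .renderPullback(config, geom, src)
  list(pullback = .newPullback(config, rendered),
       truth = .newTruth(config, geom, src, frameAmp, seed))
}

#' Generate a serial (baseline / follow-up) pullback pair
#'
#' Simulates two pullbacks of the same artery at baseline (Day 0) and
#' follow-up (Day 7). The follow-up per-frame plaque source amplitude
#' follows the configured treatment-response model
#' `amp7 = max(amp0 + effectA + effectB * amp0 + rnorm(0, effectSD), 0)`;
#' normal-wall frames, which carry no targetable macrophage source, are left
#' unchanged so the background reference is stable across time points. The
#' follow-up pullback may start `serialShift` frames off the baseline start;
#' side-branch landmark frames are emitted for both pullbacks and shift
#' accordingly.
#'
#' @inheritParams generatePullback
#' @return list with elements `day0`, `day7` (each a list `pullback`,
#'   `truth` as from [generatePullback()]) and `effect`, a data.frame of the
#'   true per-frame baseline amplitude and amplitude change over the plaque
#'   (0-based baseline frame indices).
#' @export
generateSerialPair <- function(config, seed = config@seed) {
  validObject(config)
  set.seed(as.integer(seed))
  geom <- .makeGeometry(config)
  amp0 <- .drawFrameAmp(config)
  src0 <- .sourceFromAmp(config, amp0)
  ren0 <- .renderPullback(config, geom, src0)

  pidx <- .rangeIdx(config@plaqueRange)
  eps <- if (config@effectSD > 0)
    stats::rnorm(length(pidx), 0, config@effectSD) else numeric(length(pidx))
  delta <- config@effectA + config@effectB * amp0[pidx] + eps
  ampArtery <- amp0
  ampArtery[pidx] <- pmax(amp0[pidx] + delta, 0)

  ## the day-7 catheter starts `serialShift` frames later along the artery:
  ## day-7 frame f images artery position f - shift (edge-replicated)
  shift <- config@serialShift
  nF <- config@nFrames
  pos <- pmin(pmax(seq_len(nF) - 1L - shift, 0L), nF - 1L) + 1L
  amp7 <- ampArtery[pos]
  geom7 <- list(idx = geom$idx[pos, , drop = FALSE],
                radii = geom$radii[pos, , drop = FALSE])
  shiftRange <- function(r) pmin(pmax(r + shift, 0L), nF)
  plaque7 <- shiftRange(config@plaqueRange)
  normal7 <- lapply(config@normalRanges, shiftRange)
  lm7 <- pmin(pmax(config@landmarkFrames + shift, 0L), nF - 1L)

  src7 <- .sourceFromAmp(config, ampArtery)[pos, , drop = FALSE]
  ren7 <- .renderPullback(config, geom7, src7)

  list(
    day0 = list(pullback = .newPullback(config, ren0),
                truth = .newTruth(config, geom, src0, amp0, seed)),
    day7 = list(pullback = .newPullback(config, ren7),
                truth = .newTruth(config, geom7, src7, amp7, seed,
                                  plaqueRange = plaque7,
                                  normalRanges = normal7, landmarks = lm7)),
    effect = data.frame(frame = pidx - 1L, baseline = amp0[pidx],
                        delta = ampArtery[pidx] - amp0[pidx]))
}

## Standard optical-density unit vectors (per-channel absorbance) for
## haematoxylin counterstain and DAB chromogen.
.stainVectors <- function() {
  hem <- c(0.650, 0.704, 0.286)
  dab <- c(0.269, 0.568, 0.776)
  list(hem = hem / sqrt(sum(hem^2)), dab = dab / sqrt(sum(dab^2)))
}

#' Generate a synthetic stained tissue section
#'
#' Renders an RGB slide image: a circular tissue section on a slide
#' background, with exactly `round(positiveFraction * <tissue pixels>)`
#' pixels stained positive at the stated intensity, and returns the ground
#' truth masks. `"IHC"` renders DAB chromogen over a haematoxylin
#' counterstain using standard optical-density stain vectors, so
#' `positiveIntensity` is the DAB optical density on the 0-1 analysis scale;
#' `"ORO"` (oil red O) and `"PSR_brightfield"` (picrosirius red) blend the
#' stain colour into a pale counterstained tissue on a white slide;
#' `"PSR_polarized"` renders red-orange collagen-I birefringence on a dark
#' polarised-light background.
#'
#' @param kind one of `"IHC"`, `"ORO"`, `"PSR_brightfield"`,
#'   `"PSR_polarized"`.
#' @param width,height image size in pixels.
#' @param positiveFraction fraction of tissue pixels stained positive, 0-1.
#' @param positiveIntensity stain intensity of positive pixels, 0-1.
#' @param noiseSD additive per-channel noise sd.
#' @param seed integer seed.
#' @return list with `rgb` (height x width x 3 array in \[0, 1\]),
#'   `truthMask` and `tissueMask` (logical height x width matrices).
#' @export
generateStainedImage <- function(kind = c("IHC", "ORO", "PSR_brightfield",
                                          "PSR_polarized"),
                                 width = 160L, height = 160L,
                                 positiveFraction, positiveIntensity = 0.8,
                                 noiseSD = 0.008, seed = 1L) {
  kind <- match.arg(kind)
  if (positiveFraction < 0 || positiveFraction > 1)
    stop("positiveFraction must be within [0, 1]")
  if (positiveIntensity < 0 || positiveIntensity > 1)
    stop("positiveIntensity must be within [0, 1]")
  set.seed(as.integer(seed))

  cx <- (width + 1) / 2; cy <- (height + 1) / 2
  rad <- 0.42 * min(width, height)
  xx <- matrix(seq_len(width), height, width, byrow = TRUE)
  yy <- matrix(seq_len(height), height, width)
  tissue <- (xx - cx)^2 + (yy - cy)^2 <= rad^2

  tissueIdx <- which(tissue)
  nPos <- round(positiveFraction * length(tissueIdx))
  posIdx <- if (nPos > 0) sample(tissueIdx, nPos) else integer()
  truthMask <- matrix(FALSE, height, width)
  truthMask[posIdx] <- TRUE

  rgb <- array(0, dim = c(height, width, 3))
  fill <- function(bg, tissueCol, posCol) {
    for (ch in 1:3) {
      plane <- matrix(bg[ch], height, width)
      plane[tissue] <- tissueCol[ch]
      plane[posIdx] <- posCol[ch]
      rgb[, , ch] <<- plane
    }
  }
  if (kind == "IHC") {
    sv <- .stainVectors()
    odT <- 0.35 * sv$hem
    odP <- odT + positiveIntensity * sv$dab
    fill(c(1, 1, 1), 10^(-odT), 10^(-odP))
  } else if (kind == "ORO") {
    mix <- (1 - positiveIntensity) * c(0.93, 0.80, 0.84) +
      positiveIntensity * c(0.72, 0.10, 0.16)
    fill(c(1, 1, 1), c(0.93, 0.80, 0.84), mix)
  } else if (kind == "PSR_brightfield") {
    mix <- (1 - positiveIntensity) * c(0.94, 0.85, 0.75) +
      positiveIntensity * c(0.70, 0.08, 0.25)
    fill(c(1, 1, 1), c(0.94, 0.85, 0.75), mix)
  } else {
    fill(c(0, 0, 0), c(0.12, 0.12, 0.12),
         positiveIntensity * c(0.95, 0.40, 0.05))
  }
  if (noiseSD > 0)
    rgb <- pmin(pmax(rgb + stats::rnorm(length(rgb), 0, noiseSD), 0), 1)
  list(rgb = rgb, truthMask = truthMask, tissueMask = tissue)
}

#' Generate a synthetic blood-clearance time series
#'
#' Biexponential decay sampled at the blood-draw schedule:
#' `intensity(t) = A1 * 2^(-t / thalf1) + A2 * 2^(-t / thalf2) + noise`.
#'
#' @param A1,A2 component amplitudes (a.u.), >= 0.
#' @param thalf1,thalf2 component half-lives in hours, > 0.
#' @param timepoints sampling times in hours.
#' @param noiseSD additive noise sd (a.u.).
#' @param seed integer seed.
#' @return data.frame with columns `time_h`, `intensity`.
#' @examples
#' generatePKSeries(8, 2, 2, 30, noiseSD = 0)
#' @export
generatePKSeries <- function(A1, thalf1, A2, thalf2,
                             timepoints = c(1, 6, 12, 36, 120, 168),
                             noiseSD = 0, seed = 1L) {
  if (A1 < 0 || A2 < 0) stop("amplitudes must be >= 0")
  if (thalf1 <= 0 || thalf2 <= 0) stop("half-lives must be > 0")
  set.seed(as.integer(seed))
  y <- A1 * 2^(-timepoints / thalf1) + A2 * 2^(-timepoints / thalf2)
  if (noiseSD > 0) y <- y + stats::rnorm(length(y), 0, noiseSD)
  data.frame(time_h = timepoints, intensity = y)
}

#' Generate a synthetic en-face FRI scene from pullback truth
#'
#' Renders the ex vivo fluorescence reflectance image of the excised artery
#' that corresponds to a synthetic pullback: the longitudinal profile follows
#' the per-frame source amplitude (linearly interpolated to the pixel grid),
#' modulated by a Gaussian cross-axis vessel profile. Plaque and normal ROI
#' masks cover the respective segments, and bifurcation landmarks are placed
#' at the pullback's side-branch frames.
#'
#' @param truth a [PullbackTruth-class].
#' @param framePitch mm per frame of the originating pullback.
#' @param mmPerPixel FRI pixel size, mm.
#' @param crossWidth image height (cross-axis pixels).
#' @param noiseSD additive intensity noise sd (relative units).
#' @param seed integer seed.
#' @return an [FRIScene-class].
#' @export
generateFRIScene <- function(truth, framePitch = 0.2, mmPerPixel = 0.1,
                             crossWidth = 40L, noiseSD = 0, seed = 1L) {
  set.seed(as.integer(seed))
  nF <- nrow(truth@sourceMap)
  lenMM <- (nF - 1) * framePitch
  nx <- floor(lenMM / mmPerPixel) + 1L
  xMM <- (seq_len(nx) - 1L) * mmPerPixel
  framePos <- (seq_len(nF) - 1L) * framePitch
  long <- stats::approx(framePos, truth@frameAmp, xout = xMM, rule = 2)$y
  prof <- exp(-0.5 * ((seq_len(crossWidth) - (crossWidth + 1) / 2) /
                        (crossWidth / 5))^2)
  img <- outer(prof, long)
  if (noiseSD > 0)
    img <- pmax(img + stats::rnorm(length(img), 0, noiseSD), 0)

  colFrame <- pmin(floor(xMM / framePitch), nF - 1L)  # 0-based frame per col
  inProf <- prof > 0.6
  maskFor <- function(ranges) {
    inCols <- Reduce(`|`, lapply(ranges, function(r) .inRange(colFrame, r)),
                     accumulate = FALSE, init = rep(FALSE, nx))
    outer(inProf, inCols) > 0  # keep masks logical
  }
  plaqueMask <- maskFor(list(truth@plaqueRange))
  normalMask <- maskFor(truth@normalRanges)
  new("FRIScene", image = img, mmPerPixel = mmPerPixel,
      plaqueMask = plaqueMask, normalMask = normalMask & !plaqueMask,
      landmarksPx = truth@landmarkFrames * framePitch / mmPerPixel)
}
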