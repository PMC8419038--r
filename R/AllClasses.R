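#' @import methods
NULL

## Frame indices, plaque ranges and landmark positions are 0-based throughout,
## with half-open intervals [start, end). A-line index 0 sits at angle 0 and
## angles increase counterclockwise. Accessor functions translate to R's
## 1-based arrays internally.

#' Simulation configuration for synthetic OCT-NIRF pullbacks
#'
#' `SimConfig` collects every parameter of the synthetic pullback generator:
#' frame geometry, lumen shape, plaque/normal segment layout, the NIRF source
#' amplitudes, the true distance-decay law, detector noise, and the serial
#' (baseline to follow-up) effect model.
#'
#' @slot nFrames integer, number of cross-sectional frames in the pullback.
#' @slot nAlines integer, A-lines (angular rays) per frame.
#' @slot depthSamples integer, depth samples per A-line.
#' @slot pixelPitch numeric, mm per depth sample.
#' @slot framePitch numeric, mm between consecutive frames along the pullback.
#' @slot catheterRadius numeric, mm from the rotation axis to the sheath
#'   surface (the first depth sample).
#' @slot lumenRadiusMean,lumenEccentricity,lumenDrift numeric; mean lumen
#'   radius (mm), elliptical eccentricity of the cross-section, and relative
#'   amplitude of the smooth per-frame radius drift.
#' @slot plaqueRange integer(2), half-open 0-based frame interval of the
#'   plaque segment.
#' @slot normalRanges list of integer(2) half-open intervals of
#'   normal-looking segments (disjoint from the plaque, >= 5 frames total).
#' @slot plaqueAmp,plaqueAmpSD,normalAmp,normalAmpSD numeric, per-frame NIRF
#'   source amplitude distribution (arbitrary units) for plaque and normal
#'   frames.
#' @slot decayMu numeric, true distance-decay rate (per mm) of detected
#'   fluorescence; the detected fraction is `exp(-decayMu * d)` with `d` the
#'   sheath-to-lumen distance in mm.
#' @slot noiseSD numeric >= 0, additive NIRF detector noise sd.
#' @slot octNoiseSD numeric >= 0, additive OCT intensity noise sd (frames are
#'   rendered on a 0-1 scale).
#' @slot guidewireAlines integer >= 0, width (in A-lines) of the simulated
#'   guidewire shadow sector centred at A-line 0.
#' @slot landmarkFrames integer vector, 0-based frames of simulated side
#'   branches used as co-registration landmarks.
#' @slot effectA,effectB,effectSD numeric, serial change model for the
#'   per-frame plaque source amplitude: `delta = effectA + effectB * baseline
#'   + rnorm(1, 0, effectSD)`.
#' @slot serialShift integer, longitudinal shift (frames) of the follow-up
#'   pullback relative to baseline.
#' @slot seed integer, default seed recorded with generated data.
#'
#' @seealso [simConfig()] for the user-facing constructor with defaults,
#'   [generatePullback()], [generateSerialPair()].
#' @export
setClass("SimConfig", slots = c(
  nFrames = "integer", nAlines = "integer", depthSamples = "integer",
  pixelPitch = "numeric", framePitch = "numeric", catheterRadius = "numeric",
  lumenRadiusMean = "numeric", lumenEccentricity = "numeric",
  lumenDrift = "numeric",
  plaqueRange = "integer", normalRanges = "list",
  plaqueAmp = "numeric", plaqueAmpSD = "numeric",
  normalAmp = "numeric", normalAmpSD = "numeric",
  decayMu = "numeric", noiseSD = "numeric", octNoiseSD = "numeric",
  guidewireAlines = "integer", landmarkFrames = "integer",
  effectA = "numeric", effectB = "numeric", effectSD = "numeric",
  serialShift = "integer", seed = "integer"
))

.checkRange <- function(r, nFrames, what) {
  if (length(r) != 2L || anyNA(r)) return(sprintf("%s must be integer(2)", what))
  if (r[1] < 0L || r[2] > nFrames || r[1] >= r[2])
    return(sprintf("%s [%d,%d) must be non-empty and within [0,%d)",
                   what, r[1], r[2], nFrames))
  NULL
}

setValidity("SimConfig", function(object) {
  msgs <- character()
  for (s in c("nFrames", "nAlines", "depthSamples"))
    if (slot(object, s) <= 0L) msgs <- c(msgs, paste(s, "must be positive"))
  for (s in c("pixelPitch", "framePitch"))
    if (slot(object, s) <= 0) msgs <- c(msgs, paste(s, "must be > 0"))
  if (object@noiseSD < 0 || object@octNoiseSD < 0)
    msgs <- c(msgs, "noise sd must be >= 0")
  m <- .checkRange(object@plaqueRange, object@nFrames, "plaqueRange")
  if (!is.null(m)) msgs <- c(msgs, m)
  covered <- rep(FALSE, object@nFrames)
  pr <- object@plaqueRange
  if (is.null(m)) covered[seq.int(pr[1] + 1L, pr[2])] <- TRUE
  nNormal <- 0L
  for (r in object@normalRanges) {
    m <- .checkRange(r, object@nFrames, "normal range")
    if (!is.null(m)) { msgs <- c(msgs, m); next }
    idx <- seq.int(r[1] + 1L, r[2])
    if (any(covered[idx]))
      msgs <- c(msgs, "plaque and normal ranges must be disjoint")
    covered[idx] <- TRUE
    nNormal <- nNormal + length(idx)
  }
  if (nNormal < 5L)
    msgs <- c(msgs, "normal segments must cover at least 5 frames")
  if (object@lumenRadiusMean <= object@catheterRadius)
    msgs <- c(msgs, "lumenRadiusMean must exceed catheterRadius")
  if (length(msgs)) msgs else TRUE
})

#' Synthetic pullback ground truth
#'
#' Stores everything the generator knows about a synthetic pullback: the true
#' per-A-line fluorophore source map, the true lumen radii, the decay rate of
#' the distance law, the segment labels and the landmark frames.
#'
#' @slot sourceMap numeric matrix (frames x A-lines), true fluorophore signal
#'   in arbitrary units, non-negative.
#' @slot lumenRadii numeric matrix (frames x A-lines), true lumen radius in
#'   mm from the rotation axis (quantised to the depth-sample grid, as
#'   rendered in the OCT stack).
#' @slot frameAmp numeric, per-frame source amplitude (the within-frame
#'   maximum of the source map).
#' @slot decayMu numeric, true decay rate (per mm).
#' @slot plaqueRange integer(2), 0-based half-open plaque frame interval.
#' @slot normalRanges list of integer(2) normal-segment intervals.
#' @slot landmarkFrames integer, 0-based side-branch frames.
#' @slot seed integer, seed the pullback was generated with.
#' @export
setClass("PullbackTruth", slots = c(
  sourceMap = "matrix", lumenRadii = "matrix", frameAmp = "numeric",
  decayMu = "numeric", plaqueRange = "integer", normalRanges = "list",
  landmarkFrames = "integer", seed = "integer"
))

setValidity("PullbackTruth", function(object) {
  msgs <- character()
  if (any(object@sourceMap < 0)) msgs <- c(msgs, "sourceMap must be >= 0")
  if (!identical(dim(object@sourceMap), dim(object@lumenRadii)))
    msgs <- c(msgs, "sourceMap and lumenRadii shapes must match")
  if (length(msgs)) msgs else TRUE
})

#' An intravascular OCT-NIRF pullback
#'
#' Container for one pullback: the polar OCT stack (frames x A-lines x depth,
#' intensities on a 0-1 scale quantised to 8 bits as acquired), the raw
#' per-A-line NIRF channel (frames x A-lines, arbitrary units) and the
#' acquisition geometry.
#'
#' @slot oct numeric 3-d array, frames x A-lines x depth samples.
#' @slot nirf numeric matrix, frames x A-lines.
#' @slot pixelPitch numeric, mm per depth sample.
#' @slot framePitch numeric, mm per frame along the pullback.
#' @slot catheterRadius numeric, mm from rotation axis to sheath surface.
#'
#' @seealso [octStack()], [nirfRaw()], [generatePullback()],
#'   [readPullback()], [writePullback()].
#' @export
setClass("Pullback", slots = c(
  oct = "array", nirf = "matrix",
  pixelPitch = "numeric", framePitch = "numeric", catheterRadius = "numeric"
))

setValidity("Pullback", function(object) {
  d <- dim(object@oct)
  msgs <- character()
  if (length(d) != 3L) msgs <- c(msgs, "oct must be frames x A-lines x depth")
  else if (!identical(dim(object@nirf), d[1:2]))
    msgs <- c(msgs, "nirf must be frames x A-lines, matching the OCT stack")
  if (object@pixelPitch <= 0 || object@framePitch <= 0)
    msgs <- c(msgs, "pitches must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' Lumen contour of a pullback
#'
#' Per-A-line lumen radii (distance from the rotation axis to the lumen
#' border, mm) for one or more frames, with validity flags: A-lines under the
#' guidewire shadow or with insufficient wall contrast are flagged invalid
#' and their radii filled by circular interpolation from valid neighbours.
#'
#' @slot radii numeric matrix, frames x A-lines, radius in mm.
#' @slot valid logical matrix, frames x A-lines; FALSE where the border was
#'   interpolated rather than detected.
#' @slot catheterRadius numeric, mm.
#' @slot frameIndex integer, 0-based frame indices of the rows.
#' @export
setClass("LumenContour", slots = c(
  radii = "matrix", valid = "matrix", catheterRadius = "numeric",
  frameIndex = "integer"
))

setValidity("LumenContour", function(object) {
  msgs <- character()
  if (!identical(dim(object@radii), dim(object@valid)))
    msgs <- c(msgs, "radii and valid shapes must match")
  if (any(object@radii[object@valid] < object@catheterRadius - 1e-9))
    msgs <- c(msgs, "valid radii must be >= catheterRadius")
  if (length(msgs)) msgs else TRUE
})

#' Distance-decay compensation curve
#'
#' The pre-determined calibration curve `c(d)` giving the relative detected
#' fraction of fluorescence as a function of the sheath-to-target distance
#' `d` (mm), normalised so that `c(dRef) = 1` at the smallest calibrated
#' distance. Raw NIRF is compensated by division: `compensated = raw /
#' c(d)`. Either a parametric monoexponential (`model = "exponential"`, slot
#' `mu` per mm) or a tabulated curve with linear interpolation.
#'
#' @slot model character, "exponential" or "tabulated".
#' @slot mu numeric, decay rate per mm (exponential model; NA otherwise).
#' @slot dRef numeric, reference distance in mm where c = 1.
#' @slot grid,values numeric, tabulated distances (mm) and relative detected
#'   fractions (tabulated model; length 0 otherwise).
#' @slot range numeric(2), working distance range [dMin, dMax] in mm;
#'   distances outside are clamped during compensation.
#' @seealso [fitCompensationCurve()], [evalCompensation()], [compensate()].
#' @export
setClass("CompensationCurve", slots = c(
  model = "character", mu = "numeric", dRef = "numeric",
  grid = "numeric", values = "numeric", range = "numeric"
))

setValidity("CompensationCurve", function(object) {
  msgs <- character()
  if (!object@model %in% c("exponential", "tabulated"))
    msgs <- c(msgs, "model must be 'exponential' or 'tabulated'")
  if (object@model == "tabulated") {
    if (length(object@grid) != length(object@values) || length(object@grid) < 2L)
      msgs <- c(msgs, "tabulated curve needs >= 2 (distance, fraction) pairs")
    else {
      if (any(object@values <= 0)) msgs <- c(msgs, "curve values must be > 0")
      if (any(diff(object@values) > 1e-9))
        msgs <- c(msgs, "curve must be non-increasing with distance")
    }
  } else if (object@mu < 0) {
    msgs <- c(msgs, "mu must be >= 0")
  }
  if (length(object@range) != 2L || object@range[1] > object@range[2])
    msgs <- c(msgs, "range must be [dMin, dMax]")
  if (length(msgs)) msgs else TRUE
})

#' Plaque target-to-background ratio result
#'
#' Holds the background value (mean of the five lowest per-frame NIRF maxima
#' over normal-looking segments, on the compensated scale), the pTBR/Frame
#' vector (per-frame maximum pTBR), the mean pTBR over the plaque segment,
#' and the full 2-D longitudinal pTBR map.
#'
#' @slot background positive numeric, compensated NIRF units.
#' @slot ptbrPerFrame numeric, one value per frame (pTBR/Frame).
#' @slot meanPTBR numeric, mean of pTBR/Frame over plaque frames.
#' @slot map2d numeric matrix, frames x A-lines pTBR map.
#' @slot plaqueRange integer(2), 0-based half-open plaque interval used.
#' @seealso [quantifyPTBR()], [computeBackground()], [computePTBRFrames()],
#'   [computeMeanPTBR()].
#' @export
setClass("PTBRResult", slots = c(
  background = "numeric", ptbrPerFrame = "numeric", meanPTBR = "numeric",
  map2d = "matrix", plaqueRange = "integer"
))

setValidity("PTBRResult", function(object) {
  msgs <- character()
  if (object@background <= 0) msgs <- c(msgs, "background must be > 0")
  pr <- object@plaqueRange
  if (length(pr) == 2L && pr[2] > pr[1] && pr[2] <= length(object@ptbrPerFrame)) {
    v <- object@ptbrPerFrame[seq.int(pr[1] + 1L, pr[2])]
    if (object@meanPTBR < min(v) - 1e-9 || object@meanPTBR > max(v) + 1e-9)
      msgs <- c(msgs, "meanPTBR must lie within the range of plaque pTBR/Frame")
  }
  if (length(msgs)) msgs else TRUE
})

#' En-face ex vivo fluorescence reflectance imaging (FRI) scene
#'
#' En-face fluorescence image of the excised artery with manually drawn (or
#' synthetic) plaque and normal ROI masks and bifurcation landmark pixel
#' positions along the aorta axis (image columns).
#'
#' @slot image numeric matrix (rows = cross axis, cols = aorta axis).
#' @slot mmPerPixel numeric, mm per pixel along both axes.
#' @slot plaqueMask,normalMask logical matrices, same shape as `image`,
#'   non-overlapping.
#' @slot landmarksPx numeric, column positions (0-based pixels) of arterial
#'   bifurcations used for co-registration with the in vivo map.
#' @seealso [friMeanPTBR()], [samplePairedProfiles()], [generateFRIScene()].
#' @export
setClass("FRIScene", slots = c(
  image = "matrix", mmPerPixel = "numeric",
  plaqueMask = "matrix", normalMask = "matrix", landmarksPx = "numeric"
))

setValidity("FRIScene", function(object) {
  msgs <- character()
  if (!identical(dim(object@image), dim(object@plaqueMask)) ||
      !identical(dim(object@image), dim(object@normalMask)))
    msgs <- c(msgs, "masks must match the image shape")
  else if (any(object@plaqueMask & object@normalMask))
    msgs <- c(msgs, "plaque and normal masks must not overlap")
  if (object@mmPerPixel <= 0) msgs <- c(msgs, "mmPerPixel must be > 0")
  if (length(msgs)) msgs else TRUE
})
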