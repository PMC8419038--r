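#' Accessors for pullback and result objects
#'
#' @param x a [Pullback-class], [PullbackTruth-class], [LumenContour-class]
#'   or [PTBRResult-class] object.
#' @return `octStack()` the frames x A-lines x depth OCT array; `nirfRaw()`
#'   the frames x A-lines raw NIRF matrix; `nFrames()`/`nAlines()` counts;
#'   `sourceMap()` the true source matrix; `lumenRadii()` the radius matrix
#'   (mm); `validALines()` the logical validity matrix; `ptbrPerFrame()`,
#'   `meanPTBR()`, `background()` and `ptbrMap()` the respective pTBR
#'   quantities.
#' @name accessors
NULL

#' @rdname accessors
#' @export
octStack <- function(x) x@oct

#' @rdname accessors
#' @export
nirfRaw <- function(x) x@nirf

#' @rdname accessors
#' @export
nFrames <- function(x) {
  if (is(x, "Pullback")) dim(x@oct)[1] else nrow(x@sourceMap)
}

#' @rdname accessors
#' @export
nAlines <- function(x) {
  if (is(x, "Pullback")) dim(x@oct)[2] else ncol(x@sourceMap)
}

#' @rdname accessors
#' @export
sourceMap <- function(x) x@sourceMap

#' @rdname accessors
#' @export
lumenRadii <- function(x) {
  if (is(x, "LumenContour")) x@radii else x@lumenRadii
}

#' @rdname accessors
#' @export
validALines <- function(x) x@valid

#' @rdname accessors
#' @export
ptbrPerFrame <- function(x) x@ptbrPerFrame

#' @rdname accessors
#' @export
meanPTBR <- function(x) x@meanPTBR

#' @rdname accessors
#' @export
background <- function(x) x@background

#' @rdname accessors
#' @export
ptbrMap <- function(x) x@map2d

setMethod("show", "Pullback", function(object) {
  d <- dim(object@oct)
  cat(sprintf(paste0(
    "Pullback: %d frames x %d A-lines x %d depth samples\n",
    "  pixel pitch %.4g mm, frame pitch %.4g mm, catheter radius %.4g mm\n",
    "  NIRF range [%.3g, %.3g] a.u.\n"),
    d[1], d[2], d[3], object@pixelPitch, object@framePitch,
    object@catheterRadius, min(object@nirf), max(object@nirf)))
})

setMethod("show", "PullbackTruth", function(object) {
  cat(sprintf(paste0(
    "PullbackTruth: %d frames x %d A-lines, decay mu = %.3g /mm\n",
    "  plaque frames [%d, %d), %d landmark(s), seed %d\n"),
    nrow(object@sourceMap), ncol(object@sourceMap), object@decayMu,
    object@plaqueRange[1], object@plaqueRange[2],
    length(object@landmarkFrames), object@seed))
})

setMethod("show", "LumenContour", function(object) {
  cat(sprintf(paste0(
    "LumenContour: %d frame(s) x %d A-lines\n",
    "  radius %.3g-%.3g mm, %.1f%% A-lines valid\n"),
    nrow(object@radii), ncol(object@radii),
    min(object@radii), max(object@radii), 100 * mean(object@valid)))
})

setMethod("show", "CompensationCurve", function(object) {
  if (object@model == "exponential")
    cat(sprintf(
      "CompensationCurve (exponential): mu = %.4g /mm, dRef = %.3g mm, range [%.3g, %.3g] mm\n",
      object@mu, object@dRef, object@range[1], object@range[2]))
  else
    cat(sprintf(
      "CompensationCurve (tabulated): %d knots, dRef = %.3g mm, range [%.3g, %.3g] mm\n",
      length(object@grid), object@dRef, object@range[1], object@range[2]))
})

setMethod("show", "PTBRResult", function(object) {
  cat(sprintf(paste0(
    "PTBRResult: background = %.4g, mean pTBR = %.4g\n",
    "  pTBR/Frame over %d frames (plaque [%d, %d)), range [%.3g, %.3g]\n"),
    object@background, object@meanPTBR, length(object@ptbrPerFrame),
    object@plaqueRange[1], object@plaqueRange[2],
    min(object@ptbrPerFrame), max(object@ptbrPerFrame)))
})

setMethod("show", "FRIScene", function(object) {
  cat(sprintf(paste0(
    "FRIScene: %d x %d px at %.3g mm/px\n",
    "  plaque ROI %d px, normal ROI %d px, %d landmark(s)\n"),
    nrow(object@image), ncol(object@image), object@mmPerPixel,
    sum(object@plaqueMask), sum(object@normalMask),
    length(object@landmarksPx)))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(paste0(
    "SimConfig: %d frames x %d A-lines x %d depth samples\n",
    "  plaque [%d, %d), decay mu %.3g /mm, NIRF noise sd %.3g\n",
    "  serial effect: delta = %.3g + %.3g * baseline + N(0, %.3g)\n"),
    object@nFrames, object@nAlines, object@depthSamples,
    object@plaqueRange[1], object@plaqueRange[2], object@decayMu,
    object@noiseSD, object@effectA, object@effectB, object@effectSD))
})
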