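#' Build a segment annotation
#'
#' Frame-level annotation of a pullback: the plaque segment, the
#' neighbouring normal-looking segments used for the background value, and
#' ordered side-branch landmark frames used for serial co-registration. All
#' frame indices are 0-based with half-open intervals `[start, end)`.
#'
#' @param plaqueRange integer(2), half-open plaque frame interval.
#' @param normalRanges list of integer(2) half-open normal intervals,
#'   disjoint from the plaque and totalling at least 5 frames.
#' @param landmarks integer vector of 0-based landmark frames.
#' @param nFrames optional total frame count for bounds checking.
#' @return a validated list of class `"segmentAnnotation"`.
#' @export
segmentAnnotation <- function(plaqueRange, normalRanges,
                              landmarks = integer(), nFrames = NULL) {
  plaqueRange <- as.integer(plaqueRange)
  normalRanges <- lapply(normalRanges, as.integer)
  landmarks <- as.integer(landmarks)
  if (length(plaqueRange) != 2L || plaqueRange[1] >= plaqueRange[2])
    stop("plaqueRange must be a non-empty half-open interval")
  nNormal <- 0L
  for (r in normalRanges) {
    if (length(r) != 2L || r[1] >= r[2]) stop("invalid normal range")
    if (r[1] < plaqueRange[2] && plaqueRange[1] < r[2])
      stop("plaque and normal ranges must be disjoint")
    nNormal <- nNormal + (r[2] - r[1])
  }
  if (nNormal < 5L) stop("normal segments must cover at least 5 frames")
  if (!is.null(nFrames)) {
    hi <- max(plaqueRange[2], vapply(normalRanges, max, integer(1)))
    if (hi > nFrames || min(plaqueRange[1], landmarks, 0L) < 0L)
      stop("annotation exceeds the pullback frame range")
  }
  structure(list(plaqueRange = plaqueRange, normalRanges = normalRanges,
                 landmarks = landmarks),
            class = "segmentAnnotation")
}

#' Annotation carried by synthetic ground truth
#'
#' @param truth a [PullbackTruth-class].
#' @return the generator's segment labels as a [segmentAnnotation()].
#' @export
annotationFromTruth <- function(truth) {
  segmentAnnotation(truth@plaqueRange, truth@normalRanges,
                    truth@landmarkFrames, nFrames = nrow(truth@sourceMap))
}

#' Background value: mean of the five lowest normal-segment frame maxima
#'
#' For every frame of the normal-looking segments, takes the per-frame
#' maximum of the compensated NIRF signal over A-lines, sorts these maxima
#' ascending (stable in frame order among ties) and averages the five
#' lowest. This per-animal background puts pullbacks from different animals
#' on a common pTBR scale.
#'
#' @param compensated numeric matrix, frames x A-lines, compensated NIRF.
#' @param annotation a [segmentAnnotation()] (or any list with
#'   `normalRanges`).
#' @return the background value (> 0).
#' @examples
#' comp <- matrix(c(3, 1, 4, 1, 5, 9, 2, 6), ncol = 1)
#' ann <- segmentAnnotation(c(90L, 95L), list(c(0L, 8L)))
#' computeBackground(rbind(comp %*% t(rep(1, 4)),
#'                         matrix(10, 92, 4)), ann)  # mean(1,1,2,3,4) = 2.2
#' @export
computeBackground <- function(compensated, annotation) {
  normalIdx <- unlist(lapply(annotation$normalRanges, .rangeIdx))
  if (length(normalIdx) < 5L)
    stop("need at least 5 normal-looking frames for the background value")
  if (max(normalIdx) > nrow(compensated))
    stop("normal ranges exceed the compensated array")
  frameMax <- apply(compensated[normalIdx, , drop = FALSE], 1L, max)
  lowest5 <- frameMax[order(frameMax)[1:5]]  # stable: ties keep frame order
  bg <- mean(lowest5)
  if (bg <= 0)
    stop("background value must be > 0; check compensation and annotation")
  bg
}

#' Normalise compensated NIRF to pTBR and extract pTBR/Frame
#'
#' Divides the compensated NIRF map by the background value to obtain the
#' 2-D longitudinal pTBR map, and takes the per-frame maximum over A-lines
#' as pTBR/Frame (the maximum pTBR of each cross-section).
#'
#' @param compensated numeric matrix, frames x A-lines.
#' @param background positive background value from [computeBackground()].
#' @return list with `ptbrPerFrame` (numeric, one value per frame) and
#'   `map2d` (frames x A-lines pTBR matrix).
#' @export
computePTBRFrames <- function(compensated, background) {
  if (!is.numeric(background) || length(background) != 1L || background <= 0)
    stop("background must be a single positive value")
  map2d <- compensated / background
  list(ptbrPerFrame = apply(map2d, 1L, max), map2d = map2d)
}

#' Mean pTBR of a plaque segment
#'
#' Arithmetic mean of pTBR/Frame over all cross-sections of the plaque
#' segment: the representative inflammatory index of a pullback.
#'
#' @param ptbrPerFrame numeric pTBR/Frame vector.
#' @param plaqueRange half-open 0-based frame interval of the plaque.
#' @return the mean pTBR.
#' @export
computeMeanPTBR <- function(ptbrPerFrame, plaqueRange) {
  if (plaqueRange[1] >= plaqueRange[2]) stop("plaque range is empty")
  idx <- .rangeIdx(plaqueRange)
  if (max(idx) > length(ptbrPerFrame))
    stop("plaque range exceeds the pTBR/Frame vector")
  mean(ptbrPerFrame[idx])
}

#' Full pTBR quantification of one compensated pullback
#'
#' Convenience wrapper: background, pTBR map, pTBR/Frame and mean pTBR in
#' one [PTBRResult-class].
#'
#' @inheritParams computeBackground
#' @return a [PTBRResult-class].
#' @export
quantifyPTBR <- function(compensated, annotation) {
  bg <- computeBackground(compensated, annotation)
  pf <- computePTBRFrames(compensated, bg)
  new("PTBRResult", background = bg, ptbrPerFrame = pf$ptbrPerFrame,
      meanPTBR = computeMeanPTBR(pf$ptbrPerFrame, annotation$plaqueRange),
      map2d = pf$map2d, plaqueRange = as.integer(annotation$plaqueRange))
}
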