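## Vectorised median-of-3 filter along the depth axis (rows = A-lines).
.med3 <- function(m) {
  nD <- ncol(m)
  l <- m[, c(1L, seq_len(nD - 1L)), drop = FALSE]
  r <- m[, c(seq.int(2L, nD), nD), drop = FALSE]
  l + m + r - pmax(l, m, r) - pmin(l, m, r)
}

## Periodic linear interpolation of invalid entries from valid neighbours.
.circularFill <- function(x, valid) {
  n <- length(x)
  if (all(valid)) return(x)
  v <- which(valid)
  xs <- c(v - n, v, v + n)
  ys <- rep(x[v], 3L)
  x[!valid] <- stats::approx(xs, ys, xout = which(!valid))$y
  x
}

## Circular moving median of odd window w.
.circularMedian <- function(x, w) {
  if (w < 3L) return(x)
  n <- length(x); h <- w %/% 2L
  ext <- c(x[seq.int(n - h + 1L, n)], x, x[seq_len(h)])
  stats::runmed(ext, w, endrule = "keep")[seq.int(h + 1L, h + n)]
}

#' Segment the lumen contour of one polar OCT frame
#'
#' Per A-line, the depth profile is median-filtered and the lumen border is
#' taken as the first depth sample rising above an adaptive threshold
#' (background + `kMAD` robust deviations, estimated per A-line), snapped to
#' the local gradient peak; the earliest (shallowest) candidate wins, since
#' the lumen border is the first tissue interface. A-lines with no
#' suprathreshold wall signal (guidewire shadow, low contrast) are flagged
#' invalid and filled by periodic linear interpolation from valid
#' neighbours; the radii are then smoothed with a circular moving median.
#'
#' The detector is invariant to positive rescaling of the frame intensities
#' and equivariant under circular shifts of the A-lines.
#'
#' @param frame numeric matrix, A-lines x depth samples, intensities >= 0.
#' @param pixelPitch mm per depth sample.
#' @param catheterRadius mm from the rotation axis to the first depth sample.
#' @param params list of tuning parameters: `kMAD` (adaptive threshold
#'   multiplier, default 6), `smoothWindow` (odd circular median window,
#'   default 5), `maxInvalidFrac` (segmentation fails above this fraction of
#'   undetectable A-lines, default 0.5).
#' @param frameIndex 0-based frame index recorded in the result.
#' @return a [LumenContour-class] with one row.
#' @seealso [segmentLumen()] for whole pullbacks, [contourToDistances()].
#' @export
segmentLumenFrame <- function(frame, pixelPitch, catheterRadius,
                              params = list(), frameIndex = 0L) {
  if (!is.matrix(frame) || nrow(frame) < 4L || ncol(frame) < 8L)
    stop("frame must be an A-lines x depth matrix")
  kMAD <- params$kMAD %||% 6
  smoothWindow <- params$smoothWindow %||% 5L
  maxInvalidFrac <- params$maxInvalidFrac %||% 0.5
  nA <- nrow(frame); nD <- ncol(frame)

  frameMax <- max(frame)
  if (frameMax <= 0)
    stop("lumen segmentation failed: frame has no signal")
  mf <- .med3(frame)

  ## per-A-line background level and robust spread
  bgStats <- apply(mf, 1L, function(x) {
    md <- stats::median(x)
    c(md, stats::median(abs(x - md)))
  })
  bg <- bgStats[1L, ]
  spread <- pmax(1.4826 * bgStats[2L, ], 1e-3 * frameMax)
  thr <- bg + kMAD * spread

  above <- mf > thr
  hasWall <- rowSums(above) > 0L
  k0 <- max.col(above, ties.method = "first")  # first suprathreshold sample
  valid <- hasWall & k0 > 1L

  if (mean(!valid) > maxInvalidFrac)
    stop(sprintf(
      "lumen segmentation failed: no detectable wall on %.0f%% of A-lines (frame %d)",
      100 * mean(!valid), frameIndex))

  ## snap to the local gradient peak around the rising edge (earliest wins);
  ## grad[, j] is the rise into sample j + 1, so the border is j + 1
  grad <- mf[, -1L, drop = FALSE] - mf[, -nD, drop = FALSE]
  offs <- -2L:1L
  gWin <- vapply(offs, function(o) {
    j <- pmin(pmax(k0 - 1L + o, 1L), nD - 1L)
    grad[cbind(seq_len(nA), j)]
  }, numeric(nA))
  best <- max.col(gWin, ties.method = "first")
  border <- pmin(pmax(k0 + offs[best], 2L), nD)

  radii <- catheterRadius + (border - 1L) * pixelPitch
  radii[!valid] <- NA_real_
  radii <- .circularFill(radii, valid)
  radii <- .circularMedian(radii, as.integer(smoothWindow))
  radii <- pmax(radii, catheterRadius)

  new("LumenContour", radii = matrix(radii, 1L),
      valid = matrix(valid, 1L), catheterRadius = catheterRadius,
      frameIndex = as.integer(frameIndex))
}

#' Segment the lumen contour of every frame of a pullback
#'
#' Applies [segmentLumenFrame()] to each frame of the OCT stack.
#'
#' @param pullback a [Pullback-class].
#' @param params tuning parameters, see [segmentLumenFrame()].
#' @return a [LumenContour-class] with one row per frame.
#' @export
segmentLumen <- function(pullback, params = list()) {
  stopifnot(is(pullback, "Pullback"))
  d <- dim(pullback@oct)
  radii <- matrix(0, d[1], d[2])
  valid <- matrix(TRUE, d[1], d[2])
  for (f in seq_len(d[1])) {
    ct <- segmentLumenFrame(pullback@oct[f, , ], pullback@pixelPitch,
                            pullback@catheterRadius, params,
                            frameIndex = f - 1L)
    radii[f, ] <- ct@radii
    valid[f, ] <- ct@valid
  }
  new("LumenContour", radii = radii, valid = valid,
      catheterRadius = pullback@catheterRadius,
      frameIndex = seq_len(d[1]) - 1L)
}

#' Convert a lumen contour to sheath-to-lumen distances
#'
#' The distance travelled by excitation/emission light through blood is the
#' lumen radius minus the catheter sheath radius. Negative distances signal
#' inconsistent geometry and raise an error; values within numerical jitter
#' of zero are clamped to 0.
#'
#' @param contour a [LumenContour-class].
#' @return numeric matrix (frames x A-lines) of distances in mm, >= 0.
#' @export
contourToDistances <- function(contour) {
  stopifnot(is(contour, "LumenContour"))
  d <- contour@radii - contour@catheterRadius
  if (any(d < -1e-9))
    stop("inconsistent geometry: lumen radius below catheter radius")
  pmax(d, 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
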