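#' Construct a compensation curve directly
#'
#' Builds a [CompensationCurve-class] from known parameters, e.g. a
#' pre-determined monoexponential decay rate measured on a calibration
#' phantom, without refitting.
#'
#' @param mu decay rate per mm (exponential model); ignored when `grid` is
#'   given.
#' @param dRef reference distance (mm) where the detected fraction is 1.
#' @param range working distance range `c(dMin, dMax)` in mm.
#' @param grid,values optional tabulated curve: distances (mm) and relative
#'   detected fractions; values are renormalised to 1 at the smallest
#'   distance.
#' @return a [CompensationCurve-class].
#' @examples
#' compensationCurve(mu = 1.5, range = c(0, 3))
#' @export
compensationCurve <- function(mu = NULL, dRef = 0, range = c(0, 5),
                              grid = NULL, values = NULL) {
  if (!is.null(grid)) {
    o <- order(grid)
    grid <- grid[o]; values <- values[o]
    values <- values / values[1L]
    new("CompensationCurve", model = "tabulated", mu = NA_real_,
        dRef = grid[1L], grid = grid, values = values,
        range = c(grid[1L], grid[length(grid)]))
  } else {
    new("CompensationCurve", model = "exponential", mu = mu, dRef = dRef,
        grid = numeric(), values = numeric(), range = range)
  }
}

#' Fit the distance-decay compensation curve from calibration data
#'
#' Estimates the relative detected fluorescence fraction `c(d)` from
#' calibration measurements of a fluorescent target at known distances. The
#' exponential model fits `log(intensity)` against distance by least
#' squares and normalises to 1 at the smallest calibrated distance, so the
#' compensation factor `1/c(d)` only ever amplifies. The tabulated model
#' averages replicate intensities per distance, normalises, and projects the
#' table onto the non-increasing cone (monotone regression); a projection
#' that moves any value by more than `tol` triggers a warning, since a
#' rising calibration trend contradicts distance decay.
#'
#' @param calibration data.frame with columns `distance_mm` and `intensity`
#'   (> 0), at least 3 distinct distances.
#' @param model `"exponential"` or `"tabulated"`.
#' @param tol tolerance on a non-monotone (rising) trend before warning.
#' @return a [CompensationCurve-class].
#' @examples
#' cal <- data.frame(distance_mm = c(0, 0.5, 1, 1.5, 2),
#'                   intensity = 10 * exp(-1.5 * c(0, 0.5, 1, 1.5, 2)))
#' fitCompensationCurve(cal)
#' @export
fitCompensationCurve <- function(calibration,
                                 model = c("exponential", "tabulated"),
                                 tol = 1e-6) {
  model <- match.arg(model)
  d <- calibration$distance_mm
  y <- calibration$intensity
  if (is.null(d) || is.null(y))
    stop("calibration needs columns distance_mm and intensity")
  if (any(y <= 0)) stop("calibration intensities must be > 0")
  if (length(unique(d)) < 3L)
    stop("need at least 3 distinct calibration distances")

  if (model == "exponential") {
    fit <- stats::lm(log(y) ~ d)
    mu <- -unname(stats::coef(fit)[2L])
    if (mu < -tol) {
      warning("calibration intensities increase with distance; projecting to mu = 0")
      mu <- 0
    }
    mu <- max(mu, 0)
    compensationCurve(mu = mu, dRef = min(d), range = range(d))
  } else {
    agg <- tapply(y, d, mean)
    grid <- as.numeric(names(agg))
    vals <- as.numeric(agg)
    o <- order(grid); grid <- grid[o]; vals <- vals[o]
    vals <- vals / vals[1L]
    mono <- -stats::isoreg(grid, -vals)$yf  # non-increasing projection
    if (max(abs(mono - vals)) > tol)
      warning("calibration table is not monotone; projected to a non-increasing curve")
    mono <- pmax(mono, min(mono[mono > 0], 1e-6))
    compensationCurve(grid = grid, values = mono)
  }
}

#' Evaluate the relative detected fraction c(d)
#'
#' @param curve a [CompensationCurve-class].
#' @param d numeric vector/matrix of distances (mm); values outside the
#'   working range are clamped to the nearest bound.
#' @return c(d), same shape as `d`, with attribute `nClamped` giving the
#'   number of out-of-range distances.
#' @export
evalCompensation <- function(curve, d) {
  stopifnot(is(curve, "CompensationCurve"))
  dim0 <- dim(d)
  nClamped <- sum(d < curve@range[1L] | d > curve@range[2L])
  dc <- pmin(pmax(d, curve@range[1L]), curve@range[2L])
  v <- if (curve@model == "exponential") {
    exp(-curve@mu * (dc - curve@dRef))
  } else {
    stats::approx(curve@grid, curve@values, xout = as.vector(dc))$y
  }
  dim(v) <- dim0
  attr(v, "nClamped") <- nClamped
  v
}

#' Compensate raw NIRF for distance-dependent decay
#'
#' Divides the raw per-A-line NIRF signal by the relative detected fraction
#' at the light path distance of that A-line:
#' `compensated[f, a] = raw[f, a] / c(distance[f, a])`. Distances outside
#' the curve's working range are clamped to the nearest bound; when that
#' happens, a warning summarises how many values were clamped and the count
#' is attached as attribute `nClamped`.
#'
#' @param raw numeric matrix, frames x A-lines, raw NIRF.
#' @param distances numeric matrix, same shape, sheath-to-lumen distances in
#'   mm (see [contourToDistances()]).
#' @param curve a [CompensationCurve-class].
#' @return compensated NIRF matrix, same shape as `raw`.
#' @examples
#' cur <- compensationCurve(mu = 1.5, range = c(0, 3))
#' raw <- matrix(7 * exp(-1.5 * 0.8), 2, 3)
#' compensate(raw, matrix(0.8, 2, 3), cur)  # recovers 7 everywhere
#' @export
compensate <- function(raw, distances, curve) {
  if (!identical(dim(raw), dim(distances)))
    stop("raw and distances shapes must match")
  cv <- evalCompensation(curve, distances)
  nClamped <- attr(cv, "nClamped")
  if (nClamped > 0)
    warning(sprintf("%d distance(s) outside the curve working range were clamped",
                    nClamped))
  out <- raw / cv
  attr(out, "nClamped") <- nClamped
  out
}
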