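#' Ex vivo mean pTBR from an FRI scene
#'
#' Ratio of the mean NIRF intensity inside the manually drawn plaque ROI to
#' that of the adjacent normal-artery ROI; invariant to global intensity
#' scaling.
#'
#' @param scene an [FRIScene-class].
#' @return the ex vivo mean pTBR.
#' @export
friMeanPTBR <- function(scene) {
  stopifnot(is(scene, "FRIScene"))
  if (!any(scene@plaqueMask)) stop("plaque ROI mask is empty")
  if (!any(scene@normalMask)) stop("normal ROI mask is empty")
  mn <- mean(scene@image[scene@normalMask])
  if (mn == 0) stop("normal ROI mean intensity is zero")
  mean(scene@image[scene@plaqueMask]) / mn
}

#' Sample co-registered in vivo / ex vivo longitudinal profiles
#'
#' Co-registers the in vivo 2-D pTBR map with the en-face ex vivo FRI image
#' through matched bifurcation landmarks (piecewise-linear axis mapping) and
#' samples both signals on a shared longitudinal grid at `interval_mm`
#' spacing between the first and last matched landmark. At each position
#' the in vivo signal is the maximum pTBR of the nearest frame and the ex
#' vivo signal is the cross-axis mean FRI intensity of the nearest column.
#'
#' @param map2d numeric matrix, frames x A-lines in vivo pTBR map.
#' @param framePitch mm per frame of the pullback.
#' @param scene an [FRIScene-class].
#' @param landmarkPairs data.frame with columns `frame` (0-based in vivo
#'   landmark frames) and `px` (0-based FRI column positions); >= 2 rows.
#' @param interval_mm sampling interval, default 0.5 mm.
#' @return data.frame with `position_mm` (along the catheter axis),
#'   `invivo`, `exvivo`.
#' @export
samplePairedProfiles <- function(map2d, framePitch, scene, landmarkPairs,
                                 interval_mm = 0.5) {
  stopifnot(is(scene, "FRIScene"))
  if (nrow(landmarkPairs) < 2L)
    stop("need at least 2 matched landmark pairs")
  lmMM <- landmarkPairs$frame * framePitch
  lmPx <- landmarkPairs$px
  o <- order(lmMM); lmMM <- lmMM[o]; lmPx <- lmPx[o]

  grid <- seq(lmMM[1L], lmMM[length(lmMM)], by = interval_mm)
  nF <- nrow(map2d)
  frames <- pmin(pmax(round(grid / framePitch), 0L), nF - 1L)
  invivo <- apply(map2d[frames + 1L, , drop = FALSE], 1L, max)

  px <- stats::approx(lmMM, lmPx, xout = grid)$y
  cols <- pmin(pmax(round(px), 0L), ncol(scene@image) - 1L)
  exvivo <- colMeans(scene@image)[cols + 1L]
  data.frame(position_mm = grid, invivo = invivo, exvivo = exvivo)
}

#' DAB staining-intensity map of an immunostained section
#'
#' Separates the DAB chromogen from the haematoxylin counterstain by colour
#' deconvolution with the standard optical-density stain vectors and maps
#' the antibody signal onto a 0-1 scale (the DAB optical density along the
#' stain vector, clipped at 1; 0 means no stain). The tissue mask marks
#' non-background pixels by a luminance rule: pixels brighter than 0.9 of
#' the white point belong to the slide background.
#'
#' @param rgb numeric array height x width x 3 with values in \[0, 1\].
#' @param backgroundLuminance luminance threshold for the slide background.
#' @return list with `intensity` (height x width matrix in \[0, 1\]) and
#'   `tissueMask` (logical matrix).
#' @export
dabIntensityMap <- function(rgb, backgroundLuminance = 0.9) {
  if (length(dim(rgb)) != 3L || dim(rgb)[3L] != 3L)
    stop("expected an RGB image (height x width x 3)")
  h <- dim(rgb)[1L]; w <- dim(rgb)[2L]
  od <- -log10(pmax(rgb, 1e-6))
  sv <- .stainVectors()
  third <- c(sv$hem[2L] * sv$dab[3L] - sv$hem[3L] * sv$dab[2L],
             sv$hem[3L] * sv$dab[1L] - sv$hem[1L] * sv$dab[3L],
             sv$hem[1L] * sv$dab[2L] - sv$hem[2L] * sv$dab[1L])
  third <- third / sqrt(sum(third^2))
  M <- rbind(sv$hem, sv$dab, third)
  odFlat <- matrix(od, h * w, 3L)
  conc <- odFlat %*% solve(M)
  intensity <- matrix(pmin(pmax(conc[, 2L], 0), 1), h, w)
  lum <- 0.299 * rgb[, , 1L] + 0.587 * rgb[, , 2L] + 0.114 * rgb[, , 3L]
  list(intensity = intensity, tissueMask = lum <= backgroundLuminance)
}

#' Positive-stained ratio of an intensity map
#'
#' Selects tissue pixels whose staining intensity is strictly greater than
#' `threshold` (default 0.1 on the 0-1 scale) and sums the selected
#' intensities; the positive-stained ratio is that sum divided by the
#' tissue pixel count.
#'
#' @param intensityMap matrix of per-pixel staining intensities in \[0, 1\].
#' @param tissueMask logical matrix marking the tissue section area.
#' @param threshold strict positivity threshold, default 0.1.
#' @param stain label recorded with the result.
#' @return list of class `"stainQuant"` with `tissueAreaPx`,
#'   `positiveRatio`, `nPositive`, `threshold`, `stain`.
#' @export
quantifyPositiveRatio <- function(intensityMap, tissueMask, threshold = 0.1,
                                  stain = "IHC") {
  if (!any(tissueMask)) stop("empty tissue mask")
  sel <- tissueMask & intensityMap > threshold
  structure(list(tissueAreaPx = sum(tissueMask),
                 positiveRatio = sum(intensityMap[sel]) / sum(tissueMask),
                 nPositive = sum(sel), threshold = threshold, stain = stain),
            class = "stainQuant")
}

#' @export
print.stainQuant <- function(x, ...) {
  cat(sprintf("%s: positive ratio %.4g (%d positive px / %d tissue px, threshold %.3g)\n",
              x$stain, x$positiveRatio, x$nPositive, x$tissueAreaPx,
              x$threshold))
  invisible(x)
}

.defaultStainWindows <- list(
  ORO = list(hueLo = 0.93, hueHi = 0.08, satMin = 0.30, valMin = 0.15,
             tissueRule = "bright"),
  PSR_brightfield = list(hueLo = 0.85, hueHi = 0.06, satMin = 0.25,
                         valMin = 0.15, tissueRule = "bright"),
  PSR_polarized = list(hueLo = 0.95, hueHi = 0.12, satMin = 0.30,
                       valMin = 0.30, tissueRule = "dark"))

#' Positive-area fraction of an ORO or PSR stained section
#'
#' Segments the tissue section by luminance (white-slide background for
#' brightfield stains, dark background for polarised light) and the
#' positive-stained area by a stain-specific hue/saturation window: a red
#' band for oil red O lipid, a red-magenta band for brightfield picrosirius
#' red collagen, and a red-orange birefringence band for collagen I under
#' polarised light. The positive ratio is positive pixels over tissue
#' pixels. Window parameters are configurable via `params`.
#'
#' @param rgb numeric array height x width x 3 in \[0, 1\].
#' @param stain `"ORO"`, `"PSR_brightfield"` or `"PSR_polarized"`.
#' @param params optional list overriding the default window (`hueLo`,
#'   `hueHi`, `satMin`, `valMin`; hue is circular, the window spans
#'   `[hueLo, 1] U [0, hueHi]`).
#' @return list of class `"stainQuant"` as in [quantifyPositiveRatio()].
#' @export
segmentStainFraction <- function(rgb,
                                 stain = c("ORO", "PSR_brightfield",
                                           "PSR_polarized"),
                                 params = list()) {
  stain <- match.arg(stain)
  if (length(dim(rgb)) != 3L || dim(rgb)[3L] != 3L)
    stop("expected an RGB image (height x width x 3)")
  win <- utils::modifyList(.defaultStainWindows[[stain]], params)
  r <- rgb[, , 1L]; g <- rgb[, , 2L]; b <- rgb[, , 3L]
  lum <- 0.299 * r + 0.587 * g + 0.114 * b
  tissue <- if (win$tissueRule == "dark") lum > 0.05 else lum <= 0.9
  if (!any(tissue)) {
    warning("no tissue detected on the slide")
    return(structure(list(tissueAreaPx = 0L, positiveRatio = 0,
                          nPositive = 0L, threshold = NA_real_,
                          stain = stain),
                     class = "stainQuant"))
  }
  hsv <- grDevices::rgb2hsv(as.vector(r), as.vector(g), as.vector(b),
                            maxColorValue = 1)
  hue <- hsv[1L, ]; sat <- hsv[2L, ]; val <- hsv[3L, ]
  inHue <- hue >= win$hueLo | hue <= win$hueHi
  pos <- matrix(inHue & sat >= win$satMin & val >= win$valMin,
                nrow(r), ncol(r)) & tissue
  structure(list(tissueAreaPx = sum(tissue),
                 positiveRatio = sum(pos) / sum(tissue),
                 nPositive = sum(pos), threshold = NA_real_, stain = stain),
            class = "stainQuant")
}
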