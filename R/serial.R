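#' Match frames between serial pullbacks by side-branch landmarks
#'
#' Builds a piecewise-linear frame mapping from the baseline (Day 0) to the
#' follow-up (Day 7) pullback, anchored at corresponding side-branch
#' landmark frames; outside the landmark span the mapping extrapolates with
#' the nearest segment's slope and the resulting pairs are flagged. From the
#' baseline plaque frames whose mapped partner falls inside the follow-up
#' plaque, `nPairs` frames are sampled at a regular stride with a seeded
#' random start offset; mapped indices are rounded to the nearest frame and
#' duplicate pairs removed (the count is reported).
#'
#' @param landmarks0,landmarks7 ordered 0-based landmark frames of the two
#'   pullbacks (>= 2 each, equal length).
#' @param plaque0,plaque7 half-open 0-based plaque intervals.
#' @param nPairs number of analysed frame pairs, default 30 per pullback
#'   pair.
#' @param seed integer seed for the sampling phase.
#' @return an object of class `"framePairing"`: list with `pairs`
#'   (data.frame `day0`, `day7`, `extrapolated`), `nPairs`,
#'   `nDuplicatesRemoved`, `seed`.
#' @export
matchFrames <- function(landmarks0, landmarks7, plaque0, plaque7,
                        nPairs = 30L, seed = 1L) {
  landmarks0 <- as.numeric(landmarks0); landmarks7 <- as.numeric(landmarks7)
  if (length(landmarks0) < 2L || length(landmarks7) < 2L)
    stop("need at least 2 corresponding landmarks per pullback")
  if (length(landmarks0) != length(landmarks7))
    stop("landmark sets must correspond pairwise")
  if (is.unsorted(landmarks0, strictly = TRUE) ||
      is.unsorted(landmarks7, strictly = TRUE))
    stop("landmarks must be strictly increasing along the pullback")
  if (nPairs < 1L) stop("nPairs must be >= 1")

  nL <- length(landmarks0)
  mapFrame <- function(f) {
    lo <- landmarks0[1L]; hi <- landmarks0[nL]
    s1 <- (landmarks7[2L] - landmarks7[1L]) / (landmarks0[2L] - landmarks0[1L])
    sn <- (landmarks7[nL] - landmarks7[nL - 1L]) /
      (landmarks0[nL] - landmarks0[nL - 1L])
    out <- numeric(length(f))
    below <- f < lo; above <- f > hi
    mid <- !below & !above
    out[below] <- landmarks7[1L] + s1 * (f[below] - lo)
    out[above] <- landmarks7[nL] + sn * (f[above] - hi)
    if (any(mid))
      out[mid] <- stats::approx(landmarks0, landmarks7, xout = f[mid])$y
    out
  }

  cand <- seq.int(plaque0[1], plaque0[2] - 1L)
  mapped <- round(mapFrame(cand))
  keep <- mapped >= plaque7[1] & mapped < plaque7[2]
  cand <- cand[keep]; mapped <- mapped[keep]
  n <- length(cand)
  if (n < nPairs)
    stop(sprintf("plaque overlap (%d frames) shorter than nPairs = %d",
                 n, nPairs))

  set.seed(as.integer(seed))
  stride <- max(1L, n %/% nPairs)
  maxStart <- n - (nPairs - 1L) * stride
  start <- sample.int(maxStart, 1L)
  sel <- start + (seq_len(nPairs) - 1L) * stride

  pairs <- data.frame(day0 = cand[sel], day7 = as.integer(mapped[sel]),
                      extrapolated = cand[sel] < landmarks0[1L] |
                        cand[sel] > landmarks0[nL])
  dup <- duplicated(pairs[, c("day0", "day7")])
  pairs <- pairs[!dup, , drop = FALSE]
  structure(list(pairs = pairs, nPairs = nrow(pairs),
                 nDuplicatesRemoved = sum(dup), seed = as.integer(seed)),
            class = "framePairing")
}

#' @export
print.framePairing <- function(x, ...) {
  cat(sprintf("framePairing: %d matched pair(s), %d duplicate(s) removed, seed %d\n",
              x$nPairs, x$nDuplicatesRemoved, x$seed))
  invisible(x)
}

#' Change in mean pTBR between serial time points
#'
#' Follow-up minus baseline: `deltaMeanPTBR(8.77, 5.63)` returns -3.14.
#'
#' @param meanDay0,meanDay7 mean pTBR at baseline / follow-up.
#' @return `meanDay7 - meanDay0`.
#' @export
deltaMeanPTBR <- function(meanDay0, meanDay7) {
  if (!is.finite(meanDay0) || !is.finite(meanDay7))
    stop("mean pTBR values must be finite")
  meanDay7 - meanDay0
}

#' Per-pair change in pTBR/Frame
#'
#' Elementwise follow-up minus baseline pTBR/Frame over the matched frame
#' pairs.
#'
#' @param pairing a `"framePairing"` from [matchFrames()].
#' @param ptbr0,ptbr7 pTBR/Frame vectors of the two pullbacks.
#' @return numeric vector of delta pTBR/Frame, one value per pair.
#' @export
deltaPerFrame <- function(pairing, ptbr0, ptbr7) {
  p <- pairing$pairs
  if (any(p$day0 < 0L) || any(p$day0 >= length(ptbr0)) ||
      any(p$day7 < 0L) || any(p$day7 >= length(ptbr7)))
    stop("pair indices out of range of the pTBR/Frame vectors")
  ptbr7[p$day7 + 1L] - ptbr0[p$day0 + 1L]
}

#' Stratify treatment response by baseline tertiles
#'
#' Splits the matched frame pairs into three groups at the 1/3 and 2/3
#' empirical (inverse-CDF, type 1) quantiles of the baseline pTBR/Frame;
#' ties go to the lower group. Reports per-group mean and SEM of the delta
#' pTBR/Frame and, when every group has at least two members, the
#' Kruskal-Wallis omnibus and Bonferroni-corrected pairwise Mann-Whitney
#' tests from [groupCompare()].
#'
#' @param baseline baseline pTBR/Frame values, length >= 3.
#' @param deltas delta pTBR/Frame values, same length.
#' @param alpha significance level passed to [groupCompare()].
#' @return an object of class `"tertileReport"`: list with `boundaries`,
#'   `assignment` (factor I/II/III), `summary` (data.frame n, meanDelta,
#'   semDelta), and `tests`.
#' @export
tertileStratify <- function(baseline, deltas, alpha = 0.05) {
  n <- length(baseline)
  if (n < 3L) stop("need at least 3 frame pairs for tertiles")
  if (length(deltas) != n) stop("baseline and deltas lengths must match")
  q <- stats::quantile(baseline, c(1, 2) / 3, type = 1L, names = FALSE)
  grp <- factor(1L + (baseline > q[1]) + (baseline > q[2]),
                levels = 1:3, labels = c("I", "II", "III"))
  summ <- data.frame(
    tertile = levels(grp),
    n = as.integer(table(grp)),
    meanDelta = as.numeric(tapply(deltas, grp, mean)),
    semDelta = as.numeric(tapply(deltas, grp,
                                 function(x) stats::sd(x) / sqrt(length(x)))))
  tests <- NULL
  if (all(summ$n >= 2L))
    tests <- groupCompare(split(deltas, grp), alpha = alpha)
  structure(list(boundaries = q, assignment = grp, summary = summ,
                 tests = tests),
            class = "tertileReport")
}

#' @export
print.tertileReport <- function(x, ...) {
  cat(sprintf("tertileReport: boundaries at %.4g / %.4g\n",
              x$boundaries[1], x$boundaries[2]))
  print(x$summary, row.names = FALSE)
  if (!is.null(x$tests))
    cat(sprintf("Kruskal-Wallis p = %.3g\n", x$tests$omnibus$p.value))
  invisible(x)
}
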