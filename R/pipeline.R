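.runConfigSchema <- list(
  seed = "integer",
  sim = "list",          # simConfig() arguments for synthetic input
  inputs = "list",       # day0 / day7 directories of saved pullbacks
  curve = "list",        # mu + dRef + range, or calibration table/path
  segmentation = "list", # kMAD, smoothWindow, maxInvalidFrac
  matching = "list",     # nPairs
  alpha = "numeric",
  outDir = "character"
)

.validateRunConfig <- function(config) {
  unknown <- setdiff(names(config), names(.runConfigSchema))
  if (length(unknown))
    stop("unknown run-config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(config$sim) && is.null(config$inputs))
    stop("run config needs either 'sim' (synthetic) or 'inputs' (saved pullbacks)")
  if (!is.null(config$inputs) &&
      (is.null(config$inputs$day0) || is.null(config$inputs$day7)))
    stop("'inputs' needs 'day0' and 'day7' directories")
  config$seed <- as.integer(config$seed %||% 1L)
  config$alpha <- config$alpha %||% 0.05
  config$matching <- utils::modifyList(list(nPairs = 30L),
                                       config$matching %||% list())
  config
}

.loadRunConfig <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("missing config file: ", config)
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
    else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  .validateRunConfig(config)
}

.curveFromConfig <- function(cfg, maxDist) {
  cfg <- cfg %||% list()
  if (!is.null(cfg$calibration)) {
    cal <- cfg$calibration
    if (is.character(cal)) cal <- utils::read.csv(cal)
    fitCompensationCurve(cal, model = cfg$model %||% "exponential")
  } else {
    compensationCurve(mu = cfg$mu %||% 1.5, dRef = cfg$dRef %||% 0,
                      range = c(0, cfg$dMax %||% (maxDist + 0.1)))
  }
}

.stageTry <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE))
}

#' Run the serial OCT-NIRF quantification pipeline end to end
#'
#' Orchestrates the full analysis on a baseline/follow-up pullback pair:
#' lumen segmentation, distance compensation against the configured
#' pre-determined curve, background and pTBR quantification per pullback,
#' landmark-based frame matching, delta statistics (delta mean pTBR, per-pair
#' delta pTBR/Frame with a paired t-test and a Wilcoxon signed-rank test),
#' the normality-gated correlation between baseline pTBR/Frame and delta
#' pTBR/Frame, and tertile stratification of the response. Inputs are
#' either generated synthetically (`config$sim`, arguments to
#' [simConfig()]) or loaded from saved pullbacks (`config$inputs$day0/7`).
#'
#' The run configuration (an R list, or the path of a YAML/JSON file) is
#' validated against the known schema before any computation; unknown keys
#' are rejected. Every result carries the seed and an MD5 hash of the
#' canonicalised configuration, so identical `(config, seed)` reruns are
#' reproducible; stage errors propagate with the stage name.
#'
#' @param config run configuration: list or YAML/JSON path with optional
#'   keys `seed`, `sim`, `inputs`, `curve` (`mu`, `dRef`, `dMax` or
#'   `calibration`), `segmentation`, `matching` (`nPairs`), `alpha`,
#'   `outDir`.
#' @param outDir output directory for the JSON report, CSV tables and
#'   rendered pTBR map PNGs; overrides `config$outDir`; NULL writes nothing.
#' @return the report: list with per-day [PTBRResult-class]s, the frame
#'   pairing, `deltaMeanPTBR`, `deltaPerFrame`, test results, the
#'   baseline-delta correlation, the tertile report, `seed`, `paramHash`
#'   and a `warnings` log (clamped distances, removed duplicate pairs).
#' @export
runSerialPipeline <- function(config, outDir = NULL) {
  config <- .loadRunConfig(config)
  outDir <- outDir %||% config$outDir
  seed <- config$seed
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  paramHash <- unname(tools::md5sum(tmp))
  log <- character()

  if (!is.null(config$sim)) {
    simCfg <- .stageTry("simulate", do.call(simConfig, config$sim))
    pair <- .stageTry("simulate", generateSerialPair(simCfg, seed = seed))
    pb0 <- pair$day0$pullback; pb7 <- pair$day7$pullback
    ann0 <- annotationFromTruth(pair$day0$truth)
    ann7 <- annotationFromTruth(pair$day7$truth)
  } else {
    in0 <- .stageTry("load", readPullback(config$inputs$day0))
    in7 <- .stageTry("load", readPullback(config$inputs$day7))
    pb0 <- in0$pullback; pb7 <- in7$pullback
    ann0 <- in0$annotation; ann7 <- in7$annotation
    if (is.null(ann0) || is.null(ann7))
      stop("[load] saved pullbacks must include annotation.json")
  }

  quantify <- function(pb, ann, day) {
    ct <- .stageTry(paste0("segment:", day),
                    segmentLumen(pb, config$segmentation %||% list()))
    dist <- .stageTry(paste0("segment:", day), contourToDistances(ct))
    curve <- .curveFromConfig(config$curve, max(dist))
    comp <- withCallingHandlers(
      .stageTry(paste0("compensate:", day),
                compensate(nirfRaw(pb), dist, curve)),
      warning = function(w) {
        log <<- c(log, sprintf("compensate:%s: %s", day, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    res <- .stageTry(paste0("quantify:", day), quantifyPTBR(comp, ann))
    list(contour = ct, compensated = comp, ptbr = res)
  }
  q0 <- quantify(pb0, ann0, "day0")
  q7 <- quantify(pb7, ann7, "day7")

  pairing <- .stageTry("serial", matchFrames(
    ann0$landmarks, ann7$landmarks, ann0$plaqueRange, ann7$plaqueRange,
    nPairs = config$matching$nPairs, seed = seed))
  if (pairing$nDuplicatesRemoved > 0)
    log <- c(log, sprintf("serial: %d duplicate frame pair(s) removed",
                          pairing$nDuplicatesRemoved))

  dMean <- deltaMeanPTBR(meanPTBR(q0$ptbr), meanPTBR(q7$ptbr))
  dFrame <- deltaPerFrame(pairing, ptbrPerFrame(q0$ptbr),
                          ptbrPerFrame(q7$ptbr))
  base <- ptbrPerFrame(q0$ptbr)[pairing$pairs$day0 + 1L]
  pairedT <- .stageTry("stats",
                       pairedCompare(base, base + dFrame, "paired_t"))
  wilcox <- tryCatch(pairedCompare(base, base + dFrame, "wilcoxon"),
                     error = function(e) NULL)
  corr <- tryCatch(gatedCorrelation(base, dFrame, alpha = config$alpha),
                   error = function(e) {
                     log <<- c(log, sprintf("stats: correlation skipped (%s)",
                                            conditionMessage(e)))
                     NULL
                   })
  tert <- .stageTry("stats", tertileStratify(base, dFrame,
                                             alpha = config$alpha))

  report <- list(day0 = q0$ptbr, day7 = q7$ptbr, pairing = pairing,
                 deltaMeanPTBR = dMean, deltaPerFrame = dFrame,
                 baselinePTBRFrame = base, pairedT = pairedT,
                 wilcoxon = wilcox, correlation = corr, tertiles = tert,
                 seed = seed, paramHash = paramHash, warnings = log)
  if (!is.null(outDir)) .writeSerialReport(report, outDir)
  report
}

.writeSerialReport <- function(report, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  js <- list(
    seed = report$seed, paramHash = report$paramHash,
    background = c(day0 = background(report$day0),
                   day7 = background(report$day7)),
    meanPTBR = c(day0 = meanPTBR(report$day0),
                 day7 = meanPTBR(report$day7)),
    deltaMeanPTBR = report$deltaMeanPTBR,
    pairedT = report$pairedT[c("statistic", "p", "n")],
    correlation = if (!is.null(report$correlation))
      report$correlation[c("method", "r", "p")],
    tertiles = report$tertiles$summary,
    kruskalP = if (!is.null(report$tertiles$tests))
      report$tertiles$tests$omnibus$p.value,
    warnings = report$warnings)
  jsonlite::write_json(js, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  utils::write.csv(
    data.frame(frame0 = report$pairing$pairs$day0,
               frame7 = report$pairing$pairs$day7,
               baseline = report$baselinePTBRFrame,
               delta = report$deltaPerFrame),
    file.path(outDir, "pairs.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(frame = seq_along(ptbrPerFrame(report$day0)) - 1L,
               ptbr_day0 = ptbrPerFrame(report$day0),
               ptbr_day7 = ptbrPerFrame(report$day7)),
    file.path(outDir, "ptbr_frames.csv"), row.names = FALSE)
  for (day in c("day0", "day7")) {
    m <- ptbrMap(report[[day]])
    png::writePNG(m / max(m, 1e-12),
                  file.path(outDir, sprintf("ptbr_map_%s.png", day)))
  }
  invisible(outDir)
}
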