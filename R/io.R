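## Full-precision CSV for numeric matrices: %.17g round-trips doubles
## exactly through write/parse.
.writeMatrixCSV <- function(m, path) {
  lines <- apply(m, 1L, function(r) paste(sprintf("%.17g", r),
                                          collapse = ","))
  writeLines(lines, path)
}

.readMatrixCSV <- function(path) {
  lines <- readLines(path)
  do.call(rbind, lapply(strsplit(lines, ",", fixed = TRUE), as.numeric))
}

#' Write a pullback to disk
#'
#' Writes the OCT stack as a multi-page TIFF (one 8-bit page per frame,
#' rows = A-lines, cols = depth samples), the raw NIRF array as a
#' full-precision CSV (frames x A-lines), a JSON manifest recording the
#' geometry, and optionally the segment annotation as JSON. A saved
#' pullback reloads bit-identically with [readPullback()].
#'
#' @param pullback a [Pullback-class].
#' @param dir output directory (created if needed).
#' @param annotation optional [segmentAnnotation()].
#' @param seed optional integer recorded in the manifest.
#' @return `dir`, invisibly.
#' @export
writePullback <- function(pullback, dir, annotation = NULL, seed = NULL) {
  stopifnot(is(pullback, "Pullback"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(pullback@oct)
  pages <- lapply(seq_len(d[1L]), function(f) pullback@oct[f, , ])
  tiff::writeTIFF(pages, file.path(dir, "oct.tif"), bits.per.sample = 8L)
  .writeMatrixCSV(pullback@nirf, file.path(dir, "nirf.csv"))
  manifest <- list(nFrames = d[1L], nAlines = d[2L], depthSamples = d[3L],
                   pixelPitch = pullback@pixelPitch,
                   framePitch = pullback@framePitch,
                   catheterRadius = pullback@catheterRadius,
                   seed = seed)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(annotation))
    jsonlite::write_json(unclass(annotation),
                         file.path(dir, "annotation.json"),
                         auto_unbox = FALSE, digits = NA)
  invisible(dir)
}

#' Read a pullback from disk
#'
#' Loads a pullback written by [writePullback()], checking every array
#' shape against the manifest; a missing file or a mismatch between the
#' manifest frame count and the TIFF page count is an error naming the
#' offending path.
#'
#' @param dir directory containing `oct.tif`, `nirf.csv`, `manifest.json`
#'   and optionally `annotation.json`.
#' @return list with `pullback` ([Pullback-class]), `annotation`
#'   ([segmentAnnotation()] or NULL) and `seed`.
#' @export
readPullback <- function(dir) {
  need <- file.path(dir, c("manifest.json", "oct.tif", "nirf.csv"))
  for (p in need) if (!file.exists(p)) stop("missing file: ", p)
  manifest <- jsonlite::read_json(need[1L], simplifyVector = TRUE)
  pages <- tiff::readTIFF(need[2L], all = TRUE)
  if (length(pages) != manifest$nFrames)
    stop(sprintf("%s has %d page(s) but manifest declares %d frames",
                 need[2L], length(pages), manifest$nFrames))
  if (!all(dim(pages[[1L]]) == c(manifest$nAlines, manifest$depthSamples)))
    stop(sprintf("%s page shape does not match the manifest", need[2L]))
  oct <- array(0, dim = c(manifest$nFrames, manifest$nAlines,
                          manifest$depthSamples))
  for (f in seq_along(pages)) oct[f, , ] <- pages[[f]]
  nirf <- .readMatrixCSV(need[3L])
  if (!all(dim(nirf) == c(manifest$nFrames, manifest$nAlines)))
    stop(sprintf("%s shape does not match the manifest", need[3L]))
  pb <- new("Pullback", oct = oct, nirf = nirf,
            pixelPitch = manifest$pixelPitch,
            framePitch = manifest$framePitch,
            catheterRadius = manifest$catheterRadius)
  annPath <- file.path(dir, "annotation.json")
  ann <- NULL
  if (file.exists(annPath)) {
    a <- jsonlite::read_json(annPath, simplifyVector = TRUE)
    ann <- segmentAnnotation(a$plaqueRange,
                             if (is.matrix(a$normalRanges))
                               asplit(a$normalRanges, 1L) else a$normalRanges,
                             a$landmarks %||% integer())
  }
  list(pullback = pb, annotation = ann,
       seed = if (is.null(manifest$seed)) NA_integer_ else manifest$seed)
}
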