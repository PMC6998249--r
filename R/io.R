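# Plain-text and PNG interfaces: survival tables, interval grids, curves,
# predictions, slice manifests and cohort directories.

#' Read a survival table
#'
#' CSV with header `subject_id,time_days,event`; `event` must be 0/1.
#'
#' @param path CSV path.
#' @return Data frame with columns `subject_id`, `time`, `event`.
#' @export
readSurvivalTable <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "time_days", "event")
  if (!all(need %in% names(df)))
    stop("survival table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  out <- data.frame(subject_id = as.character(df$subject_id),
                    time = as.numeric(df$time_days),
                    event = as.integer(df$event),
                    stringsAsFactors = FALSE)
  .checkRecords(out)
}

#' Write a survival table
#'
#' @param records Data frame with columns `subject_id`, `time`, `event`.
#' @param path Output CSV path.
#' @export
writeSurvivalTable <- function(records, path) {
  .checkRecords(records)
  write.csv(data.frame(subject_id = records$subject_id,
                       time_days = records$time,
                       event = records$event),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write survival curves in long format
#'
#' One row per subject and interval endpoint: `subject_id,t,probability`.
#'
#' @param curves A [SurvivalCurves-class].
#' @param path Output CSV path.
#' @export
writeSurvivalCurves <- function(curves, path) {
  stopifnot(is(curves, "SurvivalCurves"))
  tt <- curves@boundaries[-1L]
  df <- data.frame(
    subject_id = rep(curves@subjectIds, each = length(tt)),
    t = rep(tt, times = length(curves@subjectIds)),
    probability = as.vector(t(curves@probabilities)))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize / restore an interval grid as JSON
#'
#' @param grid An [IntervalGrid-class].
#' @param path JSON path.
#' @return `readGridJSON` returns an [IntervalGrid-class].
#' @export
writeGridJSON <- function(grid, path) {
  stopifnot(is(grid, "IntervalGrid"))
  jsonlite::write_json(grid@boundaries, path, digits = NA)
  invisible(path)
}

#' @rdname writeGridJSON
#' @export
readGridJSON <- function(path) {
  intervalGrid(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Write / read a predictions table
#'
#' CSV with header `subject_id,score,surv_at_horizon`: a ranking score
#' (larger = longer predicted survival) and the predicted survival
#' probability at the evaluation horizon.
#'
#' @param predictions Data frame with those three columns.
#' @param path CSV path.
#' @export
writePredictions <- function(predictions, path) {
  need <- c("subject_id", "score", "surv_at_horizon")
  stopifnot(all(need %in% names(predictions)))
  write.csv(predictions[need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writePredictions
#' @export
readPredictions <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "score", "surv_at_horizon")
  if (!all(need %in% names(df)))
    stop("predictions must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  df
}

#' Write an evaluation report as JSON
#'
#' @param report List as returned by [evaluationReport()].
#' @param path JSON path.
#' @export
writeEvaluationReport <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a slice and its mask as 8-bit grayscale PNGs
#'
#' @param sample An [ImageSample-class].
#' @param slicePath,maskPath Output PNG paths.
#' @export
writeSlicePNG <- function(sample, slicePath, maskPath) {
  stopifnot(is(sample, "ImageSample"))
  png::writePNG(sample@pixels / 255, slicePath)
  png::writePNG(sample@mask, maskPath)
  invisible(slicePath)
}

#' Read a slice and its mask from PNGs
#'
#' Masks may be stored as {0, 1} or {0, 255}; any value above one half of
#' the maximum is treated as inside the contour.
#'
#' @param slicePath,maskPath PNG paths.
#' @param subjectId Subject identifier.
#' @param sliceIndex Integer slice index.
#' @return An [ImageSample-class].
#' @export
readSlicePNG <- function(slicePath, maskPath, subjectId = "s1",
                         sliceIndex = 1L) {
  px <- png::readPNG(slicePath)
  mk <- png::readPNG(maskPath)
  if (length(dim(px)) == 3L) px <- px[, , 1L]
  if (length(dim(mk)) == 3L) mk <- mk[, , 1L]
  mk <- (mk > max(mk) / 2) * 1
  imageSample(px * 255, mk, subjectId = subjectId,
              sliceIndex = sliceIndex)
}

#' Read a slice manifest and load its cohort
#'
#' The manifest is a CSV with header
#' `subject_id,slice_path,mask_path,slice_index`; paths are resolved
#' relative to the manifest location.
#'
#' @param path Manifest CSV path.
#' @return List of [ImageSample-class] objects.
#' @export
readCohortManifest <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "slice_path", "mask_path", "slice_index")
  if (!all(need %in% names(df)))
    stop("manifest must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  base <- dirname(path)
  lapply(seq_len(nrow(df)), function(i)
    readSlicePNG(file.path(base, df$slice_path[i]),
                 file.path(base, df$mask_path[i]),
                 subjectId = df$subject_id[i],
                 sliceIndex = df$slice_index[i]))
}

# write a simulated cohort (slices, records, truth) into a directory
.writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "slices"), showWarnings = FALSE)
  rows <- lapply(cohort$slices, function(s) {
    sp <- file.path("slices",
                    sprintf("%s_s%02d.png", s@subjectId, s@sliceIndex))
    mp <- file.path("slices",
                    sprintf("%s_s%02d_mask.png", s@subjectId,
                            s@sliceIndex))
    writeSlicePNG(s, file.path(dir, sp), file.path(dir, mp))
    data.frame(subject_id = s@subjectId, slice_path = sp,
               mask_path = mp, slice_index = s@sliceIndex,
               stringsAsFactors = FALSE)
  })
  write.csv(do.call(rbind, rows), file.path(dir, "manifest.csv"),
            row.names = FALSE, quote = FALSE)
  writeSurvivalTable(cohort$records, file.path(dir, "survival.csv"))
  write.csv(cohort$truth, file.path(dir, "truth.csv"),
            row.names = FALSE, quote = FALSE)
  invisible(dir)
}
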