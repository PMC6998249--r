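# ROI-based slice preprocessing: contour masking, ROI size filtering,
# slice ranking/selection, and standardization to the fixed model input.

#' @rdname imgsurv-accessors
#' @export
setMethod("roiSize", "ImageSample", function(x) sum(x@mask == 1))

#' @rdname imgsurv-accessors
#' @export
setMethod("roiMeanIntensity", "ImageSample", function(x) {
  n <- sum(x@mask == 1)
  if (n == 0L) return(0)
  sum(x@pixels[x@mask == 1]) / n
})

#' Zero out pixels outside the contour
#'
#' Multiplies the pixel matrix elementwise by the binary mask, so every
#' pixel outside the contoured region is 0 on the 0-255 grayscale.
#' Idempotent.
#'
#' @param sample An [ImageSample-class].
#' @return The masked [ImageSample-class].
#' @export
applyMask <- function(sample) {
  stopifnot(is(sample, "ImageSample"))
  sample@pixels <- sample@pixels * sample@mask
  sample
}

#' Filter and rank slices by ROI size and intensity
#'
#' Drops slices whose ROI is smaller than `minRoi` pixels, ranks the
#' remainder by ROI pixel count (descending) with mean ROI intensity as
#' the descending tiebreak, and returns the top `k` (or all survivors if
#' fewer). The default threshold of 250 pixels excludes ROIs too small to
#' carry usable texture.
#'
#' @param slices List of [ImageSample-class] objects.
#' @param k Number of slices to keep (>= 1).
#' @param minRoi Minimum ROI pixel count (default 250).
#' @return List of selected slices, ranked.
#' @export
rankAndSelect <- function(slices, k, minRoi = 250) {
  stopifnot(is.list(slices), k >= 1)
  sizes <- vapply(slices, roiSize, numeric(1))
  keep <- which(sizes >= minRoi)
  if (length(keep) == 0L) {
    warning("no slices with ROI >= ", minRoi, " pixels", call. = FALSE)
    return(list())
  }
  means <- vapply(slices[keep], roiMeanIntensity, numeric(1))
  ord <- order(-sizes[keep], -means)
  slices[keep][ord][seq_len(min(k, length(keep)))]
}

#' Standardize a masked slice to the model input size
#'
#' Crops a `side x side` window centered on the ROI centroid (zero-padded
#' where the window extends past the image), then rescales intensities to
#' `[0, 255]` by min-max over ROI pixels only; background stays 0. A
#' constant-intensity ROI maps to 255 everywhere (max-normalization
#' convention for the degenerate min-max). No interpolation is performed,
#' so texture scale is preserved. Idempotent at a fixed `side`.
#'
#' @param sample An [ImageSample-class]; the mask is applied first.
#' @param side Output side in pixels (default 140).
#' @return A standardized `side x side` [ImageSample-class].
#' @export
standardizeSlice <- function(sample, side = 140L) {
  stopifnot(is(sample, "ImageSample"), side >= 1)
  side <- as.integer(side)
  sample <- applyMask(sample)
  m <- sample@mask
  if (sum(m) == 0L) stop("empty ROI: cannot standardize", call. = FALSE)
  idx <- which(m == 1, arr.ind = TRUE)
  # round-half-up centroid so a re-standardized image crops to itself
  cr <- floor(mean(idx[, 1L]) + 0.5)
  cc <- floor(mean(idx[, 2L]) + 0.5)
  half <- (side - 1L) %/% 2L
  rows <- seq.int(cr - half, length.out = side)
  cols <- seq.int(cc - half, length.out = side)
  px <- matrix(0, side, side)
  mk <- matrix(0, side, side)
  rIn <- rows >= 1L & rows <= nrow(m)
  cIn <- cols >= 1L & cols <= ncol(m)
  px[rIn, cIn] <- sample@pixels[rows[rIn], cols[cIn]]
  mk[rIn, cIn] <- m[rows[rIn], cols[cIn]]
  roi <- mk == 1
  if (any(roi)) {
    lo <- min(px[roi]); hi <- max(px[roi])
    px[roi] <- if (hi > lo) (px[roi] - lo) / (hi - lo) * 255 else 255
  }
  px[!roi] <- 0
  new("ImageSample", pixels = px, mask = mk,
      subjectId = sample@subjectId, sliceIndex = sample@sliceIndex)
}

#' Aggregate per-slice hazards to one row per patient
#'
#' `"largest_slice"` (default) takes the hazards of the top-ranked slice
#' (largest ROI, mean intensity as tiebreak); `"mean"` averages hazards
#' across the patient's slices per interval.
#'
#' @param slices List of one patient's selected [ImageSample-class]
#'   objects, aligned with the rows of `hazards`.
#' @param hazards Numeric matrix, one row per slice.
#' @param mode `"largest_slice"` or `"mean"`.
#' @return One-row numeric matrix of aggregated hazards.
#' @export
aggregatePatient <- function(slices, hazards,
                             mode = c("largest_slice", "mean")) {
  mode <- match.arg(mode)
  stopifnot(is.list(slices), length(slices) >= 1L,
            is.matrix(hazards), nrow(hazards) == length(slices))
  ids <- unique(vapply(slices, function(s) s@subjectId, character(1)))
  if (length(ids) != 1L)
    stop("aggregatePatient expects slices of a single subject",
         call. = FALSE)
  row <- switch(mode,
    largest_slice = {
      sizes <- vapply(slices, roiSize, numeric(1))
      means <- vapply(slices, roiMeanIntensity, numeric(1))
      hazards[order(-sizes, -means)[1L], , drop = FALSE]
    },
    mean = matrix(colMeans(hazards), nrow = 1L))
  rownames(row) <- ids
  row
}

#' Stack standardized slices into a model input array
#'
#' @param samples List of [ImageSample-class] objects, all of one size.
#' @return Numeric array `side x side x n` of masked pixel intensities.
#' @export
imageArray <- function(samples) {
  stopifnot(is.list(samples), length(samples) >= 1L)
  dims <- vapply(samples, function(s) dim(s@pixels), integer(2))
  if (length(unique(dims[1L, ])) != 1L ||
      length(unique(dims[2L, ])) != 1L)
    stop("all samples must share one image size", call. = FALSE)
  arr <- array(0, c(dims[1L, 1L], dims[2L, 1L], length(samples)))
  for (i in seq_along(samples))
    arr[, , i] <- samples[[i]]@pixels * samples[[i]]@mask
  dimnames(arr) <- list(NULL, NULL,
                        vapply(samples, function(s) s@subjectId,
                               character(1)))
  arr
}
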