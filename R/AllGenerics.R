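#' @name imgsurv-accessors
#' @title Accessors for imgsurv S4 objects
#' @description Small accessor generics: interval boundaries, interval
#'   count, subject identifiers, ROI pixel count and mean ROI intensity.
#' @param x An imgsurv S4 object.
#' @return `boundaries()` a numeric vector; `nIntervals()` an integer;
#'   `subjectIds()` a character vector; `roiSize()` an integer pixel
#'   count; `roiMeanIntensity()` a numeric scalar.
NULL

#' @rdname imgsurv-accessors
#' @export
setGeneric("boundaries", function(x) standardGeneric("boundaries"))

#' @rdname imgsurv-accessors
#' @export
setGeneric("nIntervals", function(x) standardGeneric("nIntervals"))

#' @rdname imgsurv-accessors
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' @rdname imgsurv-accessors
#' @export
setGeneric("roiSize", function(x) standardGeneric("roiSize"))

#' @rdname imgsurv-accessors
#' @export
setGeneric("roiMeanIntensity",
           function(x) standardGeneric("roiMeanIntensity"))

#' @rdname imgsurv-accessors
#' @export
setMethod("boundaries", "IntervalGrid", function(x) x@boundaries)

#' @rdname imgsurv-accessors
#' @export
setMethod("boundaries", "DiscreteTargets", function(x) x@grid@boundaries)

#' @rdname imgsurv-accessors
#' @export
setMethod("boundaries", "SurvivalCurves", function(x) x@boundaries)

#' @rdname imgsurv-accessors
#' @export
setMethod("boundaries", "CNNSurvModel", function(x) x@boundaries)

#' @rdname imgsurv-accessors
#' @export
setMethod("nIntervals", "IntervalGrid",
          function(x) length(x@boundaries) - 1L)

#' @rdname imgsurv-accessors
#' @export
setMethod("nIntervals", "DiscreteTargets", function(x) ncol(x@events))

#' @rdname imgsurv-accessors
#' @export
setMethod("nIntervals", "SurvivalCurves",
          function(x) ncol(x@probabilities))

#' @rdname imgsurv-accessors
#' @export
setMethod("nIntervals", "CNNSurvModel", function(x) x@spec@nIntervals)

#' @rdname imgsurv-accessors
#' @export
setMethod("subjectIds", "DiscreteTargets", function(x) x@subjectIds)

#' @rdname imgsurv-accessors
#' @export
setMethod("subjectIds", "SurvivalCurves", function(x) x@subjectIds)

#' @rdname imgsurv-accessors
#' @export
setMethod("subjectIds", "ImageSample", function(x) x@subjectId)

setMethod("show", "IntervalGrid", function(object) {
  b <- object@boundaries
  cat("IntervalGrid with", length(b) - 1L, "intervals over [0,",
      format(b[length(b)]), "] days\n")
})

setMethod("show", "DiscreteTargets", function(object) {
  cat("DiscreteTargets:", nrow(object@events), "subjects x",
      ncol(object@events), "intervals;",
      sum(object@events), "events\n")
})

setMethod("show", "SurvivalCurves", function(object) {
  cat("SurvivalCurves:", nrow(object@probabilities), "subjects x",
      ncol(object@probabilities), "intervals, horizon",
      format(max(object@boundaries)), "days\n")
})

setMethod("show", "ImageSample", function(object) {
  cat("ImageSample", object@subjectId, "slice", object@sliceIndex, ":",
      nrow(object@pixels), "x", ncol(object@pixels), "px, ROI size",
      sum(object@mask), "\n")
})

setMethod("show", "ModelSpec", function(object) {
  cat("ModelSpec:", object@inputSide, "x", object@inputSide,
      "input, 6 conv layers (", object@nFilters, "filters ), pools [",
      paste(object@poolSizes, collapse = ", "), "], dropout",
      object@dropoutRate, ",", object@featureDim, "features ->",
      object@nIntervals, "hazard units\n")
})

setMethod("show", "CNNSurvModel", function(object) {
  cat("CNNSurvModel (", object@stage, ")\n", sep = "")
  show(object@spec)
  if (nrow(object@lossHistory))
    cat("trained epochs:", nrow(object@lossHistory), "; last loss",
        format(object@lossHistory$loss[nrow(object@lossHistory)],
               digits = 5), "\n")
})

setMethod("show", "CoxSurvFit", function(object) {
  cat("CoxSurvFit: ", length(object@coefficients), " features, ",
      length(object@selected), " selected, lambda = ",
      format(object@lambda), ", logPL = ",
      format(object@logPartialLik, digits = 6),
      if (!object@converged) " (NOT converged)" else "", "\n", sep = "")
})

setMethod("show", "SyntheticConfig", function(object) {
  cat("SyntheticConfig:", object@nSubjects, "subjects x",
      object@slicesPerSubject, "slices,", object@imageSide, "px, beta =",
      object@betaSignal, ", seed", object@seed, "\n")
})
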