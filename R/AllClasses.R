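#' Interval grid for discrete-time survival
#'
#' A strictly increasing sequence of boundaries `t_0 < t_1 < ... < t_J`
#' with `t_0 = 0`, defining `J` half-open intervals `[t_{j-1}, t_j)` in
#' days. Hazards, targets and survival curves are all indexed by these
#' intervals.
#'
#' @slot boundaries Numeric vector of interval boundaries in days,
#'   starting at 0, strictly increasing, length `J + 1`.
#' @seealso [makeIntervalGrid()]
#' @export
setClass("IntervalGrid", representation(boundaries = "numeric"))

setValidity("IntervalGrid", function(object) {
  b <- object@boundaries
  if (length(b) < 2L) return("need at least one interval (2 boundaries)")
  if (any(!is.finite(b))) return("boundaries must be finite")
  if (b[1L] != 0) return("first boundary must be 0")
  if (any(diff(b) <= 0)) return("boundaries must be strictly increasing")
  TRUE
})

#' Construct an IntervalGrid from explicit boundaries
#'
#' @param boundaries Numeric vector `c(0, t_1, ..., t_J)`, strictly
#'   increasing.
#' @return An [IntervalGrid-class] object.
#' @examples
#' intervalGrid(c(0, 180, 360, 540))
#' @export
intervalGrid <- function(boundaries) {
  new("IntervalGrid", boundaries = as.numeric(boundaries))
}

#' Discrete-time survival targets
#'
#' Per-subject binary matrices `d` (event) and `r` (at risk / "in view")
#' over the intervals of a grid: `d[i, j] = 1` iff subject `i` failed in
#' interval `j`; `r[i, j] = 1` iff the subject was under observation and
#' event-free at the start of interval `j` (and, for censored subjects,
#' remained so through the whole interval under the default encoding
#' rule). These are exactly the quantities consumed by
#' [discreteSurvivalLoss()].
#'
#' @slot events Binary matrix `n x J` of event indicators `d`.
#' @slot atRisk Binary matrix `n x J` of at-risk indicators `r`.
#' @slot subjectIds Character vector of subject identifiers (row order).
#' @slot grid The [IntervalGrid-class] the encoding was made on.
#' @seealso [encodeTargets()]
#' @export
setClass("DiscreteTargets",
  representation(events = "matrix", atRisk = "matrix",
                 subjectIds = "character", grid = "IntervalGrid"))

setValidity("DiscreteTargets", function(object) {
  d <- object@events; r <- object@atRisk
  if (!all(dim(d) == dim(r))) return("events and atRisk dims differ")
  if (nrow(d) != length(object@subjectIds))
    return("subjectIds length must match rows")
  if (ncol(d) != length(object@grid@boundaries) - 1L)
    return("column count must equal number of grid intervals")
  if (!all(d %in% c(0, 1)) || !all(r %in% c(0, 1)))
    return("events and atRisk must be binary")
  if (any(d > r)) return("d <= r violated (event outside at-risk set)")
  if (any(rowSums(d) > 1)) return("a subject may fail at most once")
  # r must be a prefix pattern: once 0, always 0
  if (ncol(r) > 1L && any(r[, -1L, drop = FALSE] >
                          r[, -ncol(r), drop = FALSE]))
    return("atRisk must be a prefix pattern (no re-entry)")
  # after an event, never at risk again
  if (ncol(r) > 1L) {
    cd <- t(apply(d, 1L, cumsum))
    if (any(r[, -1L, drop = FALSE] == 1 &
            cd[, -ncol(d), drop = FALSE] >= 1))
      return("subject at risk after its event interval")
  }
  TRUE
})

#' Per-subject survival curves on an interval grid
#'
#' Survival probabilities `S_j = prod_{k <= j} (1 - h_k)` evaluated at the
#' right endpoints of the grid intervals; each row is one subject's curve,
#' monotone non-increasing in `[0, 1]`.
#'
#' @slot probabilities Numeric matrix `n x J`; row `i` is subject `i`'s
#'   survival probability at `t_1, ..., t_J`.
#' @slot boundaries Numeric vector `c(0, t_1, ..., t_J)`.
#' @slot subjectIds Character vector of subject identifiers.
#' @seealso [hazardsToSurvival()], [survivalAt()], [kaplanMeier()]
#' @export
setClass("SurvivalCurves",
  representation(probabilities = "matrix", boundaries = "numeric",
                 subjectIds = "character"))

setValidity("SurvivalCurves", function(object) {
  p <- object@probabilities
  if (ncol(p) != length(object@boundaries) - 1L)
    return("probability columns must match grid intervals")
  if (nrow(p) != length(object@subjectIds))
    return("subjectIds length must match rows")
  if (any(p < -1e-12 | p > 1 + 1e-12)) return("probabilities outside [0, 1]")
  if (ncol(p) > 1L &&
      any(p[, -1L, drop = FALSE] > p[, -ncol(p), drop = FALSE] + 1e-10))
    return("curves must be monotone non-increasing")
  TRUE
})

#' A masked grayscale tumor slice
#'
#' One 2-D grayscale slice (intensities in `[0, 255]`) with a binary
#' region-of-interest mask of identical shape; pixels outside the contour
#' are set to zero by [applyMask()].
#'
#' @slot pixels Numeric matrix of intensities in `[0, 255]`.
#' @slot mask Binary matrix (1 = tumor) of the same shape.
#' @slot subjectId Subject identifier.
#' @slot sliceIndex Integer slice index within the subject's series.
#' @export
setClass("ImageSample",
  representation(pixels = "matrix", mask = "matrix",
                 subjectId = "character", sliceIndex = "integer"))

setValidity("ImageSample", function(object) {
  if (!all(dim(object@pixels) == dim(object@mask)))
    return("pixels and mask shapes differ")
  if (!all(object@mask %in% c(0, 1))) return("mask must be binary")
  if (any(!is.finite(object@pixels))) return("pixels must be finite")
  if (any(object@pixels < -1e-9 | object@pixels > 255 + 1e-9))
    return("pixel intensities must lie in [0, 255]")
  TRUE
})

#' Construct an ImageSample
#'
#' @param pixels Numeric matrix of grayscale intensities in `[0, 255]`.
#' @param mask Binary matrix of the same shape (1 = inside the contour).
#' @param subjectId Subject identifier.
#' @param sliceIndex Integer slice index (default 1).
#' @return An [ImageSample-class].
#' @export
imageSample <- function(pixels, mask, subjectId = "s1", sliceIndex = 1L) {
  new("ImageSample", pixels = pixels, mask = mask,
      subjectId = as.character(subjectId),
      sliceIndex = as.integer(sliceIndex))
}

#' Network architecture specification
#'
#' The fixed backbone: three blocks of two 3x3 convolutions (32 filters
#' each, batch-normalized, ReLU), a max-pool after each block with pool
#' sizes 2, 3, 3, dropout 0.5 after each block, global average pooling over
#' the 32 channels, a 19-unit feature dense layer (`32 * 19 + 19 = 627`
#' parameters) and a sigmoid output with one hazard unit per interval.
#'
#' @slot inputSide Input image side in pixels (square input).
#' @slot nFilters Convolution filters per layer.
#' @slot poolSizes Integer vector of the three pool sizes.
#' @slot dropoutRate Dropout rate applied after each block.
#' @slot featureDim Width of the feature dense layer.
#' @slot nIntervals Number of output hazard units `J`.
#' @seealso [modelSpec()], [buildModel()]
#' @export
setClass("ModelSpec",
  representation(inputSide = "integer", nFilters = "integer",
                 poolSizes = "integer", dropoutRate = "numeric",
                 featureDim = "integer", nIntervals = "integer"))

setValidity("ModelSpec", function(object) {
  if (object@inputSide < 1L) return("inputSide must be positive")
  if (object@nFilters < 1L) return("nFilters must be positive")
  if (length(object@poolSizes) != 3L || any(object@poolSizes < 1L))
    return("poolSizes must be three positive integers")
  if (object@dropoutRate < 0 || object@dropoutRate >= 1)
    return("dropoutRate must be in [0, 1)")
  if (object@featureDim < 1L) return("featureDim must be positive")
  if (object@nIntervals < 1L) return("nIntervals must be positive")
  # the input must survive the pooling chain with at least a 1x1 map
  s <- object@inputSide
  for (p in object@poolSizes) s <- s %/% p
  if (s < 1L) return("inputSide too small for the pooling chain")
  TRUE
})

#' Training schedule configuration
#'
#' Defaults follow the two-stage transfer-learning schedule: Adam at
#' learning rate 1e-4, 50 pretraining epochs, 20 finetuning epochs, no
#' augmentation. During finetuning all convolution and batch-normalization
#' parameters are frozen; the `"head"` policy (default) updates the 19-unit
#' feature dense layer and the output layer, `"feature_only"` updates the
#' feature dense layer alone.
#'
#' @slot learningRate Adam learning rate.
#' @slot pretrainEpochs Epochs for the pretraining stage.
#' @slot finetuneEpochs Epochs for the finetuning stage.
#' @slot batchSize Minibatch size (default 8: at the fixed learning
#'   rate, smaller batches supply the optimizer with enough update steps
#'   on compact cohorts).
#' @slot seed Integer seed driving shuffling and dropout.
#' @slot augmentation Must be `FALSE` (augmentation is not part of the
#'   training procedure).
#' @slot freezePolicy `"head"` or `"feature_only"`.
#' @seealso [trainConfig()], [pretrain()], [finetune()]
#' @export
setClass("TrainConfig",
  representation(learningRate = "numeric", pretrainEpochs = "integer",
                 finetuneEpochs = "integer", batchSize = "integer",
                 seed = "integer", augmentation = "logical",
                 freezePolicy = "character"))

setValidity("TrainConfig", function(object) {
  if (object@learningRate < 0) return("learningRate must be >= 0")
  if (object@pretrainEpochs < 0L || object@finetuneEpochs < 0L)
    return("epoch counts must be >= 0")
  if (object@batchSize < 1L) return("batchSize must be positive")
  if (isTRUE(object@augmentation))
    return("augmentation is not supported; it must stay FALSE")
  if (!object@freezePolicy %in% c("head", "feature_only"))
    return("freezePolicy must be 'head' or 'feature_only'")
  TRUE
})

#' A CNN survival model
#'
#' Holds the architecture specification, the parameter list (convolution
#' kernels, batch-normalization scale/shift and running statistics, the
#' feature dense layer and the hazard output layer), the optimizer state,
#' the per-epoch loss history and the interval grid the model was trained
#' on.
#'
#' @slot spec A [ModelSpec-class].
#' @slot params Named list of layer parameters.
#' @slot optState Adam optimizer state (moments and step counter).
#' @slot lossHistory Data frame with columns `stage`, `epoch`, `loss`
#'   (mean per-sample training loss).
#' @slot stage `"initialized"`, `"pretrained"` or `"finetuned"`.
#' @slot boundaries Interval boundaries the hazard outputs refer to
#'   (length `J + 1`, or empty before training).
#' @seealso [buildModel()], [pretrain()], [finetune()],
#'   [predictHazards()], [extractFeatures()]
#' @export
setClass("CNNSurvModel",
  representation(spec = "ModelSpec", params = "list", optState = "list",
                 lossHistory = "data.frame", stage = "character",
                 boundaries = "numeric"))

#' A fitted Cox proportional-hazards baseline
#'
#' @slot coefficients Named numeric vector of log hazard ratios.
#' @slot converged Logical convergence flag.
#' @slot logPartialLik Breslow log partial likelihood at the estimate.
#' @slot selected Names of features with nonzero coefficients.
#' @slot lambda L1 penalty used (0 for the unpenalized fit).
#' @seealso [coxFit()], [coxRiskScore()], [lassoPathSelect()]
#' @export
setClass("CoxSurvFit",
  representation(coefficients = "numeric", converged = "logical",
                 logPartialLik = "numeric", selected = "character",
                 lambda = "numeric"))

#' Synthetic cohort configuration
#'
#' Parameters of the image-and-survival generator: each subject carries a
#' latent standard-normal score `z`; the rendered slices encode `z` in
#' their mean ROI intensity and bright-blob coverage, and the event time is
#' exponential with rate `baselineRate * exp(betaSignal * z)`, censored by
#' an independent uniform draw on `[0, censorHorizon]`.
#'
#' @slot nSubjects Number of subjects.
#' @slot imageSide Image side in pixels.
#' @slot slicesPerSubject Rendered slices per subject.
#' @slot betaSignal True log-hazard coefficient on `z`.
#' @slot baselineRate Baseline event rate per day.
#' @slot censorHorizon Upper bound of the uniform censoring time in days
#'   (`Inf` disables censoring).
#' @slot blobScale Spatial scale (pixels) of the texture blobs.
#' @slot intensityRange Background-to-peak intensity range of the ROI.
#' @slot roiRadiusRange Ellipse semi-axis range in pixels.
#' @slot seed Mandatory integer seed.
#' @seealso [syntheticConfig()], [simulateCohort()]
#' @export
setClass("SyntheticConfig",
  representation(nSubjects = "integer", imageSide = "integer",
                 slicesPerSubject = "integer", betaSignal = "numeric",
                 baselineRate = "numeric", censorHorizon = "numeric",
                 blobScale = "numeric", intensityRange = "numeric",
                 roiRadiusRange = "numeric", seed = "integer"))

setValidity("SyntheticConfig", function(object) {
  if (object@nSubjects < 1L) return("nSubjects must be positive")
  if (object@imageSide < 8L) return("imageSide must be at least 8")
  if (object@slicesPerSubject < 1L)
    return("slicesPerSubject must be positive")
  if (object@baselineRate <= 0) return("baselineRate must be positive")
  if (object@censorHorizon <= 0) return("censorHorizon must be positive")
  if (object@blobScale <= 0) return("blobScale must be positive")
  if (length(object@intensityRange) != 2L ||
      any(object@intensityRange < 0) || any(object@intensityRange > 255) ||
      diff(object@intensityRange) <= 0)
    return("intensityRange must be an increasing pair within [0, 255]")
  if (length(object@roiRadiusRange) != 2L ||
      any(object@roiRadiusRange < 1) || diff(object@roiRadiusRange) < 0)
    return("roiRadiusRange must be a non-decreasing pair >= 1 pixel")
  if (object@roiRadiusRange[2L] >= object@imageSide / 2)
    return("roiRadiusRange too large for imageSide (zero-area ROI margin)")
  if (length(object@seed) != 1L || is.na(object@seed))
    return("seed is mandatory")
  TRUE
})
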