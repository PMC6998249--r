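# The CNN survival model: construction, two-stage training with layer
# freezing, hazard prediction and feature extraction.

#' Construct a network architecture specification
#'
#' @param inputSide Input side in pixels (default 140).
#' @param nIntervals Number of hazard output units `J`.
#' @param nFilters Convolution filters per layer (default 32).
#' @param poolSizes The three max-pool sizes (default `c(2, 3, 3)`).
#' @param dropoutRate Dropout after each block (default 0.5).
#' @param featureDim Width of the feature dense layer (default 19, giving
#'   `32 * 19 + 19 = 627` parameters in that layer).
#' @return A [ModelSpec-class].
#' @examples
#' modelSpec(nIntervals = 12)
#' @export
modelSpec <- function(inputSide = 140L, nIntervals = 12L, nFilters = 32L,
                      poolSizes = c(2L, 3L, 3L), dropoutRate = 0.5,
                      featureDim = 19L) {
  new("ModelSpec", inputSide = as.integer(inputSide),
      nFilters = as.integer(nFilters),
      poolSizes = as.integer(poolSizes),
      dropoutRate = as.numeric(dropoutRate),
      featureDim = as.integer(featureDim),
      nIntervals = as.integer(nIntervals))
}

#' Construct a training schedule configuration
#'
#' @param learningRate Adam learning rate (default 1e-4).
#' @param pretrainEpochs Pretraining epochs (default 50).
#' @param finetuneEpochs Finetuning epochs (default 20).
#' @param batchSize Minibatch size (default 8; small batches give the optimizer enough update steps at the fixed learning rate even on compact cohorts).
#' @param seed Integer seed for shuffling and dropout (default 1).
#' @param freezePolicy `"head"` (feature dense + output layer trainable
#'   during finetuning, default) or `"feature_only"`.
#' @return A [TrainConfig-class].
#' @export
trainConfig <- function(learningRate = 1e-4, pretrainEpochs = 50L,
                        finetuneEpochs = 20L, batchSize = 8L, seed = 1L,
                        freezePolicy = c("head", "feature_only")) {
  new("TrainConfig", learningRate = as.numeric(learningRate),
      pretrainEpochs = as.integer(pretrainEpochs),
      finetuneEpochs = as.integer(finetuneEpochs),
      batchSize = as.integer(batchSize), seed = as.integer(seed),
      augmentation = FALSE, freezePolicy = match.arg(freezePolicy))
}

#' Build an untrained CNN survival model
#'
#' Initializes the six convolution layers and the 19-unit feature dense
#' layer with He-normal weights, batch-normalization scale 1 / shift 0,
#' and the hazard output layer at exactly zero (its bias is calibrated to
#' the marginal interval event rates when training starts). Zero
#' initialization of the head makes the untrained model predict the base
#' rate and lets early updates move the ranking immediately.
#'
#' @param spec A [ModelSpec-class].
#' @param seed Integer seed for the weight draws.
#' @return A [CNNSurvModel-class] with stage `"initialized"`.
#' @export
buildModel <- function(spec, seed = 1L) {
  stopifnot(is(spec, "ModelSpec"))
  validObject(spec)
  set.seed(as.integer(seed))
  Fn <- spec@nFilters
  params <- list()
  Cin <- 1L
  for (li in 1:6) {
    fanin <- 9L * Cin
    params[[paste0("conv", li)]] <- list(
      W = matrix(rnorm(Fn * fanin, sd = sqrt(2 / fanin)), Fn, fanin),
      b = numeric(Fn))
    params[[paste0("bn", li)]] <- list(
      gamma = rep(1, Fn), beta = numeric(Fn),
      mean = numeric(Fn), var = rep(1, Fn))
    Cin <- Fn
  }
  params$fc <- list(
    W = matrix(rnorm(spec@featureDim * Fn, sd = sqrt(1 / Fn)),
               spec@featureDim, Fn),
    b = numeric(spec@featureDim))
  params$out <- list(
    W = matrix(0, spec@nIntervals, spec@featureDim),
    b = numeric(spec@nIntervals))
  new("CNNSurvModel", spec = spec, params = params, optState = list(),
      lossHistory = data.frame(stage = character(), epoch = integer(),
                               loss = numeric()),
      stage = "initialized", boundaries = numeric(0))
}

#' Parameter counts per layer group
#'
#' @param model A [CNNSurvModel-class].
#' @return Named numeric vector with elements `conv`, `bn` (trainable
#'   scale/shift only), `feature_dense`, `output` and `total`. With the
#'   default specification `feature_dense` is `32 * 19 + 19 = 627`.
#' @examples
#' m <- buildModel(modelSpec(nIntervals = 3))
#' parameterCounts(m)[["feature_dense"]]  # 627
#' @export
parameterCounts <- function(model) {
  stopifnot(is(model, "CNNSurvModel"))
  p <- model@params
  conv <- sum(vapply(1:6, function(i)
    length(p[[paste0("conv", i)]]$W) + length(p[[paste0("conv", i)]]$b),
    numeric(1)))
  bn <- sum(vapply(1:6, function(i)
    length(p[[paste0("bn", i)]]$gamma) + length(p[[paste0("bn", i)]]$beta),
    numeric(1)))
  fc <- length(p$fc$W) + length(p$fc$b)
  out <- length(p$out$W) + length(p$out$b)
  c(conv = conv, bn = bn, feature_dense = fc, output = out,
    total = conv + bn + fc + out)
}

#' Trainable parameter count under a finetuning freeze policy
#'
#' @param model A [CNNSurvModel-class].
#' @param freezePolicy `"head"` or `"feature_only"`.
#' @return Number of parameters updated during finetuning.
#' @export
finetuneTrainableCount <- function(model,
                                   freezePolicy = c("head",
                                                    "feature_only")) {
  pc <- parameterCounts(model)
  switch(match.arg(freezePolicy),
         head = unname(pc["feature_dense"] + pc["output"]),
         feature_only = unname(pc["feature_dense"]))
}

.checkImages <- function(images, spec) {
  if (!is.array(images) || length(dim(images)) != 3L)
    stop("images must be a (side, side, n) array", call. = FALSE)
  if (dim(images)[1L] != spec@inputSide ||
      dim(images)[2L] != spec@inputSide)
    stop("image side ", dim(images)[1L], " does not match the model's ",
         spec@inputSide, call. = FALSE)
  invisible(images)
}

.checkTargetsForModel <- function(targets, spec, n) {
  stopifnot(is(targets, "DiscreteTargets"))
  if (ncol(targets@events) != spec@nIntervals)
    stop("targets have ", ncol(targets@events), " intervals; the model ",
         "outputs ", spec@nIntervals, call. = FALSE)
  if (nrow(targets@events) != n)
    stop("targets rows must match the number of images", call. = FALSE)
  invisible(targets)
}

#' Pretrain the full network
#'
#' Optimizes the discrete-time hazard likelihood loss over all layers with
#' Adam at the configured learning rate, minibatched and shuffled per
#' epoch, dropout active and batch-normalization in batch-statistics mode.
#' On a freshly built model the output bias is first calibrated to the
#' logit of the marginal per-interval event rate. A zero-epoch call
#' returns the model unchanged. Runs are reproducible for a fixed
#' configuration seed.
#'
#' @param model A [CNNSurvModel-class].
#' @param images Array `(side, side, n)` of standardized masked slices.
#' @param targets A [DiscreteTargets-class], rows aligned with the image
#'   slabs.
#' @param cfg A [TrainConfig-class].
#' @return The trained model, stage `"pretrained"`, with per-epoch loss
#'   history appended.
#' @export
pretrain <- function(model, images, targets, cfg = trainConfig()) {
  stopifnot(is(model, "CNNSurvModel"), is(cfg, "TrainConfig"))
  validObject(cfg)
  .checkImages(images, model@spec)
  .checkTargetsForModel(targets, model@spec, dim(images)[3L])
  if (cfg@pretrainEpochs == 0L) return(model)
  if (model@stage == "initialized") {
    d <- targets@events; r <- targets@atRisk
    rate <- colSums(d) / pmax(colSums(r), 1)
    model@params$out$b <- qlogis(pmin(pmax(rate, 1e-3), 1 - 1e-3))
  }
  model@boundaries <- targets@grid@boundaries
  model <- .trainFull(model, images, targets, cfg,
                      epochs = cfg@pretrainEpochs, stage = "pretrained")
  model
}

.trainFull <- function(model, images, targets, cfg, epochs, stage) {
  spec <- model@spec
  n <- dim(images)[3L]
  trainable <- .layerNames()
  params <- model@params
  state <- .adamInit(params, trainable)
  set.seed(cfg@seed)
  hist <- model@lossHistory
  ws <- .makeWorkspace(spec, min(cfg@batchSize, n), training = TRUE)
  for (ep in seq_len(epochs)) {
    perm <- sample.int(n)
    epLoss <- 0
    for (start in seq(1L, n, by = cfg@batchSize)) {
      idx <- perm[start:min(start + cfg@batchSize - 1L, n)]
      st <- .trainStep(params, spec, ws,
                       images[, , idx, drop = FALSE],
                       t(targets@events[idx, , drop = FALSE]),
                       t(targets@atRisk[idx, , drop = FALSE]))
      if (!is.finite(st$loss))
        stop("non-finite training loss at stage ", stage, ", epoch ", ep,
             " (batch starting at ", start, "); inspect the inputs or ",
             "lower the learning rate", call. = FALSE)
      epLoss <- epLoss + st$loss
      upd <- .adamStep(st$params, st$grads, state, trainable,
                       cfg@learningRate)
      params <- upd$params
      state <- upd$state
    }
    hist <- rbind(hist, data.frame(stage = stage, epoch = ep,
                                   loss = epLoss / n))
  }
  model@params <- params
  model@optState <- state
  model@lossHistory <- hist
  model@stage <- stage
  model
}

#' Finetune the dense head on a new cohort
#'
#' All convolution and batch-normalization parameters are frozen
#' (bit-identical before and after); the frozen trunk runs in inference
#' mode (no dropout, running batch-norm statistics), so its per-image
#' features are computed once and the head is optimized on them. Under
#' the default `"head"` policy the 627-parameter feature dense layer and
#' the hazard output layer are updated; `"feature_only"` restricts
#' updates to the feature dense layer.
#'
#' @inheritParams pretrain
#' @return The finetuned model, stage `"finetuned"`.
#' @export
finetune <- function(model, images, targets, cfg = trainConfig()) {
  stopifnot(is(model, "CNNSurvModel"), is(cfg, "TrainConfig"))
  validObject(cfg)
  if (model@stage == "initialized")
    stop("finetune requires a pretrained model", call. = FALSE)
  .checkImages(images, model@spec)
  .checkTargetsForModel(targets, model@spec, dim(images)[3L])
  if (cfg@finetuneEpochs == 0L) return(model)
  spec <- model@spec
  trainable <- switch(cfg@freezePolicy, head = c("fc", "out"),
                      feature_only = "fc")
  if (length(trainable) == 0L)
    stop("freeze policy leaves no trainable parameters", call. = FALSE)
  params <- model@params
  n <- dim(images)[3L]
  # frozen trunk: compute GAP features once, in inference mode
  G <- .predictTrunk(params, spec, images)
  d0 <- targets@events
  r0 <- targets@atRisk
  state <- .adamInit(params, trainable)
  set.seed(cfg@seed)
  hist <- model@lossHistory
  for (ep in seq_len(cfg@finetuneEpochs)) {
    perm <- sample.int(n)
    epLoss <- 0
    for (start in seq(1L, n, by = cfg@batchSize)) {
      idx <- perm[start:min(start + cfg@batchSize - 1L, n)]
      Gb <- G[, idx, drop = FALSE]
      d <- t(d0[idx, , drop = FALSE])
      r <- t(r0[idx, , drop = FALSE])
      hd <- .nnForwardHead(params, Gb)
      h <- .clipHazards(hd$hazards)
      loss <- -sum(d * log(h)) - sum((r - d) * log1p(-h))
      if (!is.finite(loss))
        stop("non-finite finetuning loss at epoch ", ep, call. = FALSE)
      epLoss <- epLoss + loss
      dLogits <- (hd$hazards - d) * r
      grads <- list()
      ob <- .denseBwd(dLogits, hd$features, params$out)
      grads$out <- list(W = ob$dW, b = ob$db)
      fb <- .denseBwd(ob$dX, Gb, params$fc)
      grads$fc <- list(W = fb$dW, b = fb$db)
      upd <- .adamStep(params, grads, state, trainable, cfg@learningRate)
      params <- upd$params
      state <- upd$state
    }
    hist <- rbind(hist, data.frame(stage = "finetuned", epoch = ep,
                                   loss = epLoss / n))
  }
  model@params <- params
  model@optState <- state
  model@lossHistory <- hist
  model@stage <- "finetuned"
  model@boundaries <- targets@grid@boundaries
  model
}

# inference-mode GAP features in memory-bounded chunks
.predictTrunk <- function(params, spec, images, chunk = 32L) {
  n <- dim(images)[3L]
  chunk <- min(chunk, n)
  ws <- .makeWorkspace(spec, chunk, training = FALSE)
  G <- matrix(0, spec@nFilters, n)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    G[, idx] <- .inferTrunk(params, spec, ws,
                            images[, , idx, drop = FALSE])
  }
  G
}

#' Predict per-interval hazards
#'
#' Inference mode: dropout off, batch normalization on running
#' statistics. Deterministic for fixed inputs.
#'
#' @param model A trained [CNNSurvModel-class].
#' @param images Array `(side, side, n)` of standardized masked slices.
#' @return Numeric matrix `n x J` of hazards in (0, 1); rownames taken
#'   from the third `dimnames` of `images` when present.
#' @export
predictHazards <- function(model, images) {
  stopifnot(is(model, "CNNSurvModel"))
  .checkImages(images, model@spec)
  G <- .predictTrunk(model@params, model@spec, images)
  hd <- .nnForwardHead(model@params, G)
  h <- t(.clipHazards(hd$hazards))
  rownames(h) <- dimnames(images)[[3L]]
  h
}

#' Extract the 19 dense-layer features
#'
#' Activations of the feature dense layer in inference mode, the inputs
#' of the Cox baseline built on transfer-learning features.
#'
#' @inheritParams predictHazards
#' @return Numeric matrix `n x featureDim` (default width 19).
#' @export
extractFeatures <- function(model, images) {
  stopifnot(is(model, "CNNSurvModel"))
  .checkImages(images, model@spec)
  G <- .predictTrunk(model@params, model@spec, images)
  Fv <- t(.denseFwd(G, model@params$fc))
  rownames(Fv) <- dimnames(images)[[3L]]
  colnames(Fv) <- paste0("tf", seq_len(ncol(Fv)))
  Fv
}

#' Predict survival curves for images
#'
#' Convenience wrapper: [predictHazards()] followed by
#' [hazardsToSurvival()] on the interval grid the model was trained on.
#'
#' @inheritParams predictHazards
#' @return A [SurvivalCurves-class].
#' @export
predictSurvival <- function(model, images) {
  if (length(model@boundaries) == 0L)
    stop("model has no interval grid yet; train it first", call. = FALSE)
  h <- predictHazards(model, images)
  hazardsToSurvival(h, intervalGrid(model@boundaries),
                    subjectIds = rownames(h))
}
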