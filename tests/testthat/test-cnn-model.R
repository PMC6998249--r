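# A reduced input side (36: 36 -> 18 -> 6 -> 2 through the pooling
# chain) keeps these training tests fast; the architecture itself is
# unchanged (6 convolutions, pools 2/3/3, 19-unit feature layer).

smallSpec <- function(J = 3L, dropout = 0.5) {
  modelSpec(inputSide = 36L, nIntervals = J, dropoutRate = dropout)
}

smallCohort <- function(n, beta = 1.5, seed = 1, J = 3L) {
  sim <- simulateCohort(syntheticConfig(n, imageSide = 36,
                                        slicesPerSubject = 1L,
                                        betaSignal = beta, seed = seed))
  X <- imageArray(lapply(sim$slices, standardizeSlice, side = 36))
  grid <- makeIntervalGrid(sim$records, J)
  list(X = X, targets = encodeTargets(sim$records, grid), grid = grid,
       records = sim$records)
}

test_that("the feature dense layer has 19 units and 627 parameters", {
  pc <- parameterCounts(buildModel(modelSpec(nIntervals = 12L)))
  expect_equal(unname(pc["feature_dense"]), 627)
  # single-interval head: 19 weights + 1 bias
  pc1 <- parameterCounts(buildModel(modelSpec(nIntervals = 1L)))
  expect_equal(unname(pc1["output"]), 20)
  # an input too small for the pooling chain is rejected
  expect_error(modelSpec(inputSide = 12L, nIntervals = 3L),
               "pooling chain")
})

test_that("backpropagation matches central-difference gradients", {
  sp <- modelSpec(inputSide = 18L, nIntervals = 2L, dropoutRate = 0)
  m <- buildModel(sp, seed = 5)
  set.seed(9)
  m@params$out$W[] <- rnorm(length(m@params$out$W), sd = 0.3)
  X <- array(runif(18 * 18 * 4) * 255, c(18, 18, 4))
  rec <- data.frame(subject_id = as.character(1:4),
                    time = c(50, 150, 180, 200),
                    event = c(1, 1, 0, 0))
  tg <- encodeTargets(rec, intervalGrid(c(0, 100, 200)))
  d <- t(tg@events); r <- t(tg@atRisk)
  ws <- imgsurv:::.makeWorkspace(sp, 4L, training = TRUE)
  lossAt <- function(p) imgsurv:::.trainStep(p, sp, ws, X, d, r)$loss
  st <- imgsurv:::.trainStep(m@params, sp, ws, X, d, r)
  eps <- 1e-5
  set.seed(4)
  for (nm in c("conv1", "conv3", "conv6", "bn2", "bn5", "fc", "out")) {
    for (sl in imgsurv:::.trainSlots(nm)) {
      p <- m@params
      for (i in sample(length(p[[nm]][[sl]]),
                       min(3, length(p[[nm]][[sl]])))) {
        p1 <- p; p1[[nm]][[sl]][i] <- p1[[nm]][[sl]][i] + eps
        p2 <- p; p2[[nm]][[sl]][i] <- p2[[nm]][[sl]][i] - eps
        num <- (lossAt(p1) - lossAt(p2)) / (2 * eps)
        expect_equal(st$grads[[nm]][[sl]][i], num, tolerance = 1e-5)
      }
    }
  }
})

test_that("the training loop loss equals the module-level loss", {
  set.seed(41)
  co <- smallCohort(8, seed = 41)
  sp <- modelSpec(inputSide = 36L, nIntervals = nIntervals(co$grid),
                  dropoutRate = 0)
  m <- buildModel(sp, seed = 2)
  ws <- imgsurv:::.makeWorkspace(sp, 8L, training = TRUE)
  st <- imgsurv:::.trainStep(m@params, sp, ws, co$X,
                             t(co$targets@events), t(co$targets@atRisk))
  expect_equal(st$loss, discreteSurvivalLoss(st$hazards, co$targets),
               tolerance = 1e-5)
})

test_that("training runs are seeded, monotone in smoke conditions, and inert at zero epochs", {
  co <- smallCohort(50, seed = 42)
  sp <- smallSpec(J = nIntervals(co$grid))
  m <- buildModel(sp, seed = 2)
  cfg <- trainConfig(pretrainEpochs = 5L, seed = 3L)
  m1 <- pretrain(m, co$X, co$targets, cfg)
  expect_equal(m1@stage, "pretrained")
  expect_equal(nrow(m1@lossHistory), 5L)
  expect_lte(m1@lossHistory$loss[5], m1@lossHistory$loss[1])
  # reproducibility under the same seed
  m1b <- pretrain(m, co$X, co$targets, cfg)
  expect_identical(m1@params, m1b@params)
  # zero epochs: strict no-op
  expect_identical(pretrain(m, co$X, co$targets,
                            trainConfig(pretrainEpochs = 0L)), m)
  # zero learning rate freezes the dynamics (single batch, no dropout:
  # the per-epoch loss is then exactly constant)
  sp0 <- smallSpec(J = nIntervals(co$grid), dropout = 0)
  m0 <- buildModel(sp0, seed = 2)
  mlr <- pretrain(m0, co$X, co$targets,
                  trainConfig(pretrainEpochs = 3L, learningRate = 0,
                              batchSize = 64L))
  expect_equal(diff(range(mlr@lossHistory$loss)), 0, tolerance = 1e-12)
})

test_that("finetuning freezes the trunk and updates only the head", {
  co <- smallCohort(40, seed = 43)
  sp <- smallSpec(J = nIntervals(co$grid))
  m <- buildModel(sp, seed = 7)
  m1 <- pretrain(m, co$X, co$targets,
                 trainConfig(pretrainEpochs = 2L, seed = 5L))
  m2 <- finetune(m1, co$X, co$targets,
                 trainConfig(finetuneEpochs = 3L, seed = 6L))
  for (nm in c(paste0("conv", 1:6), paste0("bn", 1:6)))
    expect_identical(m2@params[[nm]], m1@params[[nm]])
  expect_false(identical(m2@params$fc, m1@params$fc))
  expect_false(identical(m2@params$out, m1@params$out))
  expect_equal(m2@stage, "finetuned")

  # strict policy: only the 627-parameter feature layer moves
  m3 <- finetune(m1, co$X, co$targets,
                 trainConfig(finetuneEpochs = 3L, seed = 6L,
                             freezePolicy = "feature_only"))
  expect_identical(m3@params$out, m1@params$out)
  expect_false(identical(m3@params$fc, m1@params$fc))

  expect_equal(finetuneTrainableCount(m1, "head"),
               627 + unname(parameterCounts(m1)["output"]))
  expect_equal(finetuneTrainableCount(m1, "feature_only"), 627)
  # finetuning an untrained model is refused
  expect_error(finetune(buildModel(sp), co$X, co$targets),
               "pretrained")
})

test_that("inference is deterministic with hazards in (0, 1)", {
  co <- smallCohort(20, seed = 44)
  sp <- smallSpec(J = nIntervals(co$grid))
  m <- pretrain(buildModel(sp, seed = 3), co$X, co$targets,
                trainConfig(pretrainEpochs = 2L, seed = 4L))
  h <- predictHazards(m, co$X)
  expect_equal(dim(h), c(20L, nIntervals(co$grid)))
  expect_true(all(h > 0 & h < 1))
  expect_identical(predictHazards(m, co$X), h)
  # duplicated inputs give identical rows
  Xdup <- co$X[, , c(1, 1, 2), drop = FALSE]
  hd <- predictHazards(m, Xdup)
  expect_equal(hd[1, ], hd[2, ])
  # hazards compose into monotone survival curves
  curves <- predictSurvival(m, co$X)
  expect_true(validObject(curves))
  expect_true(all(diff(t(curves@probabilities)) <= 1e-12))
  # features: width 19, deterministic, equal for equal images
  f <- extractFeatures(m, Xdup)
  expect_equal(ncol(f), 19L)
  expect_equal(f[1, ], f[2, ])
  expect_identical(extractFeatures(m, Xdup), f)
  # shape guard
  expect_error(predictHazards(m, array(0, c(18, 18, 2))), "side")
})
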