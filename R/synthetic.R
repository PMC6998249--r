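# Synthetic cohort generator: masked grayscale tumor-like slices whose
# texture and intensity carry a known log-hazard signal, with exponential
# event times and independent uniform censoring. The latent score z is
# emitted so downstream metrics can be checked against the ground truth.

#' Construct a synthetic cohort configuration
#'
#' The latent per-subject score `z ~ N(0, 1)` drives both the image
#' appearance and the hazard: the event time is
#' `Exponential(baselineRate * exp(betaSignal * z))`, and each rendered
#' slice encodes `z` through its mean ROI intensity level and the
#' coverage fraction of bright texture blobs, so the signal survives
#' per-slice min-max intensity standardization.
#'
#' @param nSubjects Number of subjects.
#' @param imageSide Image side in pixels (default 140; reduce for fast
#'   tests).
#' @param slicesPerSubject Slices rendered per subject (default 3, echoing the multi-slice pretraining cohorts this generator emulates).
#' @param betaSignal True log-hazard coefficient on `z` (default 1).
#' @param baselineRate Baseline event rate per day (default 1/365: median
#'   survival about 8.4 months at `z = 0`).
#' @param censorHorizon Uniform censoring upper bound in days (default
#'   1095, i.e. 3 years; `Inf` disables censoring).
#' @param blobScale Blob texture scale in pixels (default 4).
#' @param intensityRange ROI intensity range on the 0-255 scale
#'   (default `c(60, 200)`).
#' @param roiRadiusRange Ellipse semi-axis range in pixels (default
#'   `c(0.12, 0.30) * imageSide`).
#' @param seed Mandatory integer seed.
#' @return A [SyntheticConfig-class].
#' @export
syntheticConfig <- function(nSubjects, imageSide = 140L,
                            slicesPerSubject = 3L, betaSignal = 1,
                            baselineRate = 1 / 365,
                            censorHorizon = 1095,
                            blobScale = 4, intensityRange = c(60, 200),
                            roiRadiusRange = NULL, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (is.null(roiRadiusRange))
    roiRadiusRange <- c(0.12, 0.30) * imageSide
  new("SyntheticConfig", nSubjects = as.integer(nSubjects),
      imageSide = as.integer(imageSide),
      slicesPerSubject = as.integer(slicesPerSubject),
      betaSignal = as.numeric(betaSignal),
      baselineRate = as.numeric(baselineRate),
      censorHorizon = as.numeric(censorHorizon),
      blobScale = as.numeric(blobScale),
      intensityRange = as.numeric(intensityRange),
      roiRadiusRange = as.numeric(roiRadiusRange),
      seed = as.integer(seed))
}

# bilinear upsampling of a coarse square field to side x side
.bilinearUpsample <- function(z, side) {
  m <- nrow(z)
  x <- seq(1, m, length.out = side)
  i0 <- pmin(floor(x), m - 1L)
  f <- x - i0
  zr <- z[i0, , drop = FALSE] * (1 - f) + z[i0 + 1L, , drop = FALSE] * f
  zr[, i0, drop = FALSE] * rep(1 - f, each = side) +
    zr[, i0 + 1L, drop = FALSE] * rep(f, each = side)
}

.renderSlice <- function(cfg, z, subjectId, sliceIndex) {
  s <- cfg@imageSide
  rr <- cfg@roiRadiusRange
  a <- runif(1, rr[1L], rr[2L])
  b <- runif(1, rr[1L], rr[2L])
  th <- runif(1, 0, pi)
  jit <- s / 10
  cx <- s / 2 + runif(1, -jit, jit)
  cy <- s / 2 + runif(1, -jit, jit)
  xs <- matrix(seq_len(s) - cx, s, s)
  ys <- matrix(seq_len(s) - cy, s, s, byrow = TRUE)
  xr <- xs * cos(th) + ys * sin(th)
  yr <- -xs * sin(th) + ys * cos(th)
  mask <- ((xr / a)^2 + (yr / b)^2 <= 1) * 1
  if (sum(mask) == 0)
    stop("degenerate configuration: zero-area ROI", call. = FALSE)
  m <- max(2L, ceiling(s / cfg@blobScale) + 1L)
  u <- .bilinearUpsample(matrix(rnorm(m * m), m, m), s)
  i0 <- cfg@intensityRange[1L]
  w <- diff(cfg@intensityRange)
  # both cues are monotone in z: base level and bright-blob coverage
  level <- i0 + (0.20 + 0.10 * tanh(z / 2)) * w
  coverage <- 0.15 + 0.45 * plogis(0.9 * z)
  thr <- quantile(u[mask == 1], 1 - coverage, names = FALSE)
  px <- level + 0.55 * w * (u > thr) + 0.05 * w * rnorm(s * s)
  px <- pmin(pmax(px, 0), 255) * mask
  imageSample(px, mask, subjectId = subjectId, sliceIndex = sliceIndex)
}

#' Simulate an imaging cohort with survival outcomes
#'
#' Draws one latent score per subject, renders `slicesPerSubject` masked
#' slices encoding it, draws the exponential event time and the uniform
#' censoring time, and returns slices, survival records and the
#' ground-truth latent table. With `dir` set, also writes the cohort to
#' disk in the formats the training tools consume: 8-bit grayscale PNG
#' slices and masks, `manifest.csv`, `survival.csv` and `truth.csv`.
#'
#' @param cfg A [SyntheticConfig-class].
#' @param dir Optional output directory.
#' @return A list with `slices` (list of [ImageSample-class]), `records`
#'   (data frame `subject_id`, `time`, `event`) and `truth` (data frame
#'   `subject_id`, `z`).
#' @examples
#' sim <- simulateCohort(syntheticConfig(4, imageSide = 32, seed = 7))
#' sim$records
#' @export
simulateCohort <- function(cfg, dir = NULL) {
  stopifnot(is(cfg, "SyntheticConfig"))
  validObject(cfg)
  set.seed(cfg@seed)
  n <- cfg@nSubjects
  ids <- sprintf("sub%04d", seq_len(n))
  z <- rnorm(n)
  rate <- cfg@baselineRate * exp(cfg@betaSignal * z)
  etime <- rexp(n, rate = rate)
  ctime <- if (is.finite(cfg@censorHorizon))
    runif(n, 0, cfg@censorHorizon) else rep(Inf, n)
  time <- pmin(etime, ctime)
  event <- as.integer(etime <= ctime)
  slices <- vector("list", n * cfg@slicesPerSubject)
  k <- 0L
  for (i in seq_len(n)) {
    for (sl in seq_len(cfg@slicesPerSubject)) {
      k <- k + 1L
      slices[[k]] <- .renderSlice(cfg, z[i], ids[i], sl)
    }
  }
  records <- data.frame(subject_id = ids, time = time, event = event,
                        stringsAsFactors = FALSE)
  truth <- data.frame(subject_id = ids, z = z, stringsAsFactors = FALSE)
  out <- list(slices = slices, records = records, truth = truth)
  if (!is.null(dir)) .writeCohort(out, dir)
  out
}

#' Simulate a tabular feature cohort
#'
#' Standard-normal features, exponential event times with rate
#' `baselineRate * exp(x' beta)` and independent uniform censoring on
#' `[0, censorHorizon]` (`Inf` disables censoring). Drives the Cox
#' baseline without images.
#'
#' @param n Number of subjects.
#' @param p Number of features.
#' @param beta True coefficient vector (recycled to length `p`).
#' @param baselineRate Baseline event rate per day.
#' @param censorHorizon Uniform censoring upper bound in days.
#' @param seed Mandatory integer seed.
#' @return A list with `features` (matrix `n x p`) and `records`.
#' @examples
#' sim <- simulateFeatureCohort(50, 2, beta = c(1, 0), seed = 3)
#' head(sim$records)
#' @export
simulateFeatureCohort <- function(n, p, beta, baselineRate = 1 / 365,
                                  censorHorizon = 1095, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(n >= 1, p >= 1, baselineRate > 0, censorHorizon > 0)
  set.seed(as.integer(seed))
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("x", seq_len(p))))
  beta <- rep_len(beta, p)
  rate <- baselineRate * exp(drop(X %*% beta))
  etime <- rexp(n, rate = rate)
  ctime <- if (is.finite(censorHorizon)) runif(n, 0, censorHorizon)
           else rep(Inf, n)
  records <- data.frame(subject_id = sprintf("sub%04d", seq_len(n)),
                        time = pmin(etime, ctime),
                        event = as.integer(etime <= ctime),
                        stringsAsFactors = FALSE)
  list(features = X, records = records)
}
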