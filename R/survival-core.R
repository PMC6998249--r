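# Core discrete-time survival machinery: interval grids, (d, r) target
# encoding, the hazard likelihood loss and its gradient, hazard-to-survival
# conversion and Kaplan-Meier estimation.

# hazards are clipped into [EPS, 1 - EPS] before any log
.EPS <- 1e-7

.checkRecords <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("records must be a nonempty data.frame", call. = FALSE)
  need <- c("subject_id", "time", "event")
  if (!all(need %in% names(records)))
    stop("records must have columns subject_id, time, event",
         call. = FALSE)
  if (any(!is.finite(records$time)) || any(records$time <= 0))
    stop("all follow-up times must be positive and finite", call. = FALSE)
  if (!all(records$event %in% c(0, 1)))
    stop("event must be 0 (censored) or 1 (failure)", call. = FALSE)
  invisible(records)
}

#' Build an interval grid from observed event times
#'
#' Boundaries are placed at the empirical quantiles (levels `k/J`,
#' `k = 1, ..., J`, type-7 rule) of the uncensored event times, with
#' `t_0 = 0` and the last boundary extended to the maximum follow-up time
#' over all records. Duplicate quantile values are collapsed, reducing `J`.
#' Quantile placement balances the number of events per interval, which
#' keeps every hazard output unit supplied with failures during training.
#'
#' @param records Data frame with columns `subject_id`, `time` (days,
#'   positive) and `event` (0/1).
#' @param nIntervals Requested number of intervals `J` (>= 1); the result
#'   may have fewer after collapsing duplicated quantiles.
#' @return An [IntervalGrid-class].
#' @examples
#' rec <- data.frame(subject_id = as.character(1:4),
#'                   time = c(100, 200, 300, 400), event = 1)
#' boundaries(makeIntervalGrid(rec, 2))
#' @export
makeIntervalGrid <- function(records, nIntervals = 12L) {
  .checkRecords(records)
  if (nIntervals < 1L) stop("nIntervals must be >= 1", call. = FALSE)
  etimes <- records$time[records$event == 1]
  if (length(etimes) == 0L)
    stop("cannot build a grid: no uncensored events in records",
         call. = FALSE)
  J <- as.integer(nIntervals)
  qs <- unname(quantile(etimes, probs = seq_len(J) / J, type = 7))
  # collapse duplicated quantiles first, then extend the last boundary to
  # the maximum follow-up (so fully tied event times give one interval)
  b <- unique(c(0, qs))
  b[length(b)] <- max(b[length(b)], max(records$time))
  intervalGrid(b)
}

#' Encode survival records as discrete (event, at-risk) targets
#'
#' For an event at time `T` falling in interval `j*`: `d[j*] = 1`,
#' `r[j] = 1` for `j <= j*` and 0 after. For censoring at `T` in interval
#' `j*`: all `d = 0` and, under the default `"exclude"` rule, `r[j] = 1`
#' only for fully survived intervals `j < j*` (the subject is not counted
#' at risk in the interval it was censored in). The `"midpoint"` rule
#' additionally counts the censoring interval as at-risk when `T` lies at
#' or past its midpoint. Follow-up beyond the last boundary is clamped to
#' it and treated as event-free through all intervals.
#'
#' @param records Data frame with columns `subject_id`, `time`, `event`.
#' @param grid An [IntervalGrid-class].
#' @param censorRule `"exclude"` (default) or `"midpoint"`.
#' @return A [DiscreteTargets-class].
#' @examples
#' g <- intervalGrid(c(0, 180, 360, 540))
#' rec <- data.frame(subject_id = "p1", time = 316, event = 1)
#' tg <- encodeTargets(rec, g)
#' tg@events  # 0 1 0
#' tg@atRisk  # 1 1 0
#' @export
encodeTargets <- function(records, grid,
                          censorRule = c("exclude", "midpoint")) {
  .checkRecords(records)
  stopifnot(is(grid, "IntervalGrid"))
  censorRule <- match.arg(censorRule)
  b <- grid@boundaries
  J <- length(b) - 1L
  n <- nrow(records)
  time <- pmin(records$time, b[J + 1L])
  # clamped subjects are event-free through the whole grid
  event <- ifelse(records$time > b[J + 1L], 0, records$event)
  d <- matrix(0, n, J)
  r <- matrix(0, n, J)
  # interval containing t: largest j with t_{j-1} <= t; J + 1 means t = t_J
  jstar <- findInterval(time, b)
  mid <- (b[-1L] + b[-(J + 1L)]) / 2
  for (i in seq_len(n)) {
    js <- jstar[i]
    if (event[i] == 1) {
      js <- min(js, J)  # an event at exactly t_J belongs to interval J
      d[i, js] <- 1
      r[i, seq_len(js)] <- 1
    } else if (js > J) {
      r[i, ] <- 1       # censored at (or clamped to) the last boundary
    } else {
      if (js > 1L) r[i, seq_len(js - 1L)] <- 1
      if (censorRule == "midpoint" && time[i] >= mid[js]) r[i, js] <- 1
    }
  }
  new("DiscreteTargets", events = d, atRisk = r,
      subjectIds = as.character(records$subject_id), grid = grid)
}

.clipHazards <- function(h, eps = .EPS) pmin(pmax(h, eps), 1 - eps)

.checkHazards <- function(hazards, targets = NULL) {
  if (!is.matrix(hazards) || !is.numeric(hazards))
    stop("hazards must be a numeric matrix", call. = FALSE)
  if (any(!is.finite(hazards)) || any(hazards <= 0) || any(hazards >= 1))
    stop("hazards must lie strictly in (0, 1)", call. = FALSE)
  if (!is.null(targets) && !all(dim(hazards) == dim(targets@events)))
    stop("hazards and targets are not conformable", call. = FALSE)
  invisible(hazards)
}

#' Discrete-time hazard likelihood loss
#'
#' The negative log likelihood of the discrete hazards given the targets,
#' summed over subjects and intervals: at-risk cells contribute
#' `-ln(h)` when the subject failed in the interval and `-ln(1 - h)` when
#' it survived it; cells outside the at-risk set contribute nothing. The
#' total is the sum of the per-interval losses. Hazards are clipped to
#' `[1e-7, 1 - 1e-7]` before the logarithm.
#'
#' @param hazards Numeric matrix `n x J` of hazards strictly in (0, 1).
#' @param targets A [DiscreteTargets-class] of matching shape.
#' @return Nonnegative scalar loss.
#' @examples
#' g <- intervalGrid(c(0, 100))
#' tg <- encodeTargets(data.frame(subject_id = "a", time = 50, event = 1), g)
#' discreteSurvivalLoss(matrix(0.5), tg)  # -log(0.5)
#' @export
discreteSurvivalLoss <- function(hazards, targets) {
  stopifnot(is(targets, "DiscreteTargets"))
  .checkHazards(hazards, targets)
  h <- .clipHazards(hazards)
  d <- targets@events
  r <- targets@atRisk
  -sum(d * log(h)) - sum((r - d) * log1p(-h))
}

#' Gradient of the discrete hazard loss with respect to the hazards
#'
#' `dL/dh = -d/h + (r - d)/(1 - h)` elementwise (zero off the at-risk
#' set), evaluated on the clipped hazards.
#'
#' @inheritParams discreteSurvivalLoss
#' @return Numeric matrix of the same shape as `hazards`.
#' @export
discreteSurvivalLossGradient <- function(hazards, targets) {
  stopifnot(is(targets, "DiscreteTargets"))
  .checkHazards(hazards, targets)
  h <- .clipHazards(hazards)
  d <- targets@events
  r <- targets@atRisk
  -d / h + (r - d) / (1 - h)
}

#' Convert per-interval hazards to survival curves
#'
#' `S_j = prod_{k <= j} (1 - h_k)` per subject, evaluated at the right
#' endpoints of the grid intervals.
#'
#' @param hazards Numeric matrix `n x J` of hazards in (0, 1).
#' @param grid An [IntervalGrid-class] with `J` intervals.
#' @param subjectIds Optional subject identifiers (default rownames or
#'   `s1, s2, ...`).
#' @return A [SurvivalCurves-class].
#' @examples
#' g <- intervalGrid(c(0, 180, 360))
#' hazardsToSurvival(matrix(c(0.1, 0.2), 1), g)@probabilities  # 0.9 0.72
#' @export
hazardsToSurvival <- function(hazards, grid, subjectIds = NULL) {
  stopifnot(is(grid, "IntervalGrid"))
  .checkHazards(hazards)
  if (ncol(hazards) != length(grid@boundaries) - 1L)
    stop("hazards columns must match grid intervals", call. = FALSE)
  S <- if (ncol(hazards) == 1L) 1 - hazards
       else t(apply(1 - hazards, 1L, cumprod))
  if (is.null(subjectIds))
    subjectIds <- rownames(hazards) %||% paste0("s", seq_len(nrow(hazards)))
  new("SurvivalCurves", probabilities = S,
      boundaries = grid@boundaries, subjectIds = as.character(subjectIds))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate survival curves at a time point
#'
#' Right-continuous step-function convention: `S(t) = S_j` for the largest
#' `j` with `t_j <= t`, and `S(t) = 1` anywhere inside the first interval
#' (before its right endpoint `t_1`). No extrapolation beyond the last
#' boundary.
#'
#' @param curves A [SurvivalCurves-class].
#' @param t Evaluation time in days, `0 <= t <= t_J`.
#' @return Named numeric vector, one probability per subject.
#' @examples
#' g <- intervalGrid(c(0, 180, 360))
#' sc <- hazardsToSurvival(matrix(c(0.1, 0.2), 1), g)
#' survivalAt(sc, 200)  # 0.9: t_1 = 180 passed, t_2 = 360 not yet
#' @export
survivalAt <- function(curves, t) {
  stopifnot(is(curves, "SurvivalCurves"), length(t) == 1L, is.finite(t))
  b <- curves@boundaries
  if (t < 0 || t > b[length(b)])
    stop("t outside [0, ", b[length(b)], "]: no extrapolation",
         call. = FALSE)
  j <- findInterval(t, b[-1L])  # number of right endpoints passed
  out <- if (j == 0L) rep(1, nrow(curves@probabilities))
         else curves@probabilities[, j]
  setNames(out, curves@subjectIds)
}

#' Kaplan-Meier product-limit estimator
#'
#' Fits the product-limit estimator via [survival::survfit()] and returns
#' the curve on the grid of distinct uncensored event times.
#'
#' @param records Data frame with columns `subject_id`, `time`, `event`.
#' @return A single-row [SurvivalCurves-class] (subject id `"KM"`) whose
#'   boundaries are `c(0, distinct event times)`, extended to the maximum
#'   follow-up time (at an unchanged probability) when censored subjects
#'   outlive the last event.
#' @examples
#' rec <- data.frame(subject_id = c("a", "b"), time = c(100, 200), event = 1)
#' sf <- kaplanMeier(rec)
#' survivalAt(sf, 100)  # 0.5
#' @export
kaplanMeier <- function(records) {
  .checkRecords(records)
  fit <- survival::survfit(
    survival::Surv(records$time, records$event) ~ 1)
  keep <- fit$n.event > 0
  if (!any(keep))
    stop("no uncensored events: Kaplan-Meier curve is identically 1",
         call. = FALSE)
  surv <- fit$surv[keep]
  b <- c(0, fit$time[keep])
  maxFollow <- max(records$time)
  if (maxFollow > b[length(b)]) {
    b <- c(b, maxFollow)
    surv <- c(surv, surv[length(surv)])
  }
  new("SurvivalCurves", probabilities = matrix(surv, nrow = 1L),
      boundaries = b, subjectIds = "KM")
}

# Right-continuous Kaplan-Meier step function of `records` (or of the
# censoring distribution when flip = TRUE), returned as
# function(t, left = FALSE); left = TRUE gives the left limit S(t-).
# Defined for t up to the maximum follow-up time.
.kmStepFun <- function(records, flip = FALSE) {
  ev <- if (flip) 1 - records$event else records$event
  fit <- survival::survfit(survival::Surv(records$time, ev) ~ 1)
  times <- fit$time
  surv <- fit$surv
  maxT <- max(records$time)
  function(t, left = FALSE) {
    if (any(t > maxT + 1e-9))
      stop("time beyond maximum follow-up in KM step function",
           call. = FALSE)
    idx <- if (left) findInterval(t - 1e-9, times)
           else findInterval(t, times)
    ifelse(idx == 0L, 1, surv[pmax(idx, 1L)])
  }
}
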