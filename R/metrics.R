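# Prognostic performance metrics: concordance index over the order graph,
# IPCW Brier score, and the index of prediction accuracy (IPA).

.alignScores <- function(scores, records) {
  if (!is.null(names(scores))) {
    miss <- setdiff(records$subject_id, names(scores))
    if (length(miss))
      stop("scores missing for subjects: ",
           paste(head(miss, 5L), collapse = ", "), call. = FALSE)
    scores <- scores[as.character(records$subject_id)]
  }
  if (length(scores) != nrow(records))
    stop("scores and records have different lengths", call. = FALSE)
  as.numeric(scores)
}

#' Concordance index over the order graph
#'
#' Evaluable pairs (the edges of the order graph) are pairs `(i, j)` with
#' `T_i` uncensored and `T_j > T_i`. The index is the fraction of those
#' pairs in which the subject that lived longer was also predicted to live
#' longer, `f(x_i) < f(x_j)`. Under the default `"strict"` tie rule a tied
#' prediction earns no credit (the literal indicator definition); the
#' `"half"` rule awards 0.5 per tie (Harrell convention, as used by the
#' usual R survival-comparison packages).
#'
#' @param scores Numeric vector oriented so that larger means longer
#'   predicted survival; optionally named by subject id.
#' @param records Data frame with columns `subject_id`, `time`, `event`.
#' @param ties `"strict"` (default) or `"half"`.
#' @return Concordance in `[0, 1]`, with attribute `nPairs` (the number of
#'   evaluable pairs).
#' @examples
#' rec <- data.frame(subject_id = letters[1:5], time = 1:5 * 100, event = 1)
#' concordanceIndex(1:5, rec)  # perfectly ordered: 1
#' @export
concordanceIndex <- function(scores, records,
                             ties = c("strict", "half")) {
  .checkRecords(records)
  ties <- match.arg(ties)
  f <- .alignScores(scores, records)
  tm <- records$time
  ev <- records$event
  unc <- which(ev == 1)
  nPairs <- 0L
  credit <- 0
  for (i in unc) {
    later <- tm > tm[i]
    nPairs <- nPairs + sum(later)
    credit <- credit + sum(f[i] < f[later])
    if (ties == "half") credit <- credit + 0.5 * sum(f[i] == f[later])
  }
  if (nPairs == 0L)
    stop("no evaluable pairs in the order graph (need an uncensored ",
         "subject with a longer-lived comparator)", call. = FALSE)
  structure(credit / nPairs, nPairs = nPairs)
}

#' IPCW Brier score at a horizon
#'
#' The inverse-probability-of-censoring-weighted Brier score at `tStar`:
#' \deqn{BS(t^*) = \frac{1}{n}\sum_i \left[
#'   \frac{\hat S_i(t^*)^2\, 1\{T_i \le t^*, \delta_i = 1\}}{G(T_i^-)} +
#'   \frac{(1-\hat S_i(t^*))^2\, 1\{T_i > t^*\}}{G(t^*)} \right]}
#' with `G` the Kaplan-Meier estimator of the censoring distribution
#' (event flags inverted). Subjects censored before `tStar` contribute
#' zero. With no censoring this reduces exactly to the mean squared error
#' between the survival indicator and the predicted probability.
#'
#' @param survProb Predicted survival probabilities at `tStar`, one per
#'   record (optionally named by subject id).
#' @param records Data frame with columns `subject_id`, `time`, `event`;
#'   also used to estimate the censoring distribution.
#' @param tStar Evaluation horizon in days.
#' @return Nonnegative scalar Brier score.
#' @export
ipcwBrier <- function(survProb, records, tStar) {
  .checkRecords(records)
  s <- .alignScores(survProb, records)
  if (any(s < 0 | s > 1))
    stop("survProb must be probabilities in [0, 1]", call. = FALSE)
  if (tStar > max(records$time))
    stop("tStar beyond maximum follow-up: censoring distribution not ",
         "estimable there", call. = FALSE)
  G <- .kmStepFun(records, flip = TRUE)
  tm <- records$time
  ev <- records$event
  w <- numeric(nrow(records))
  isEvent <- ev == 1 & tm <= tStar
  isAlive <- tm > tStar
  if (any(isEvent)) {
    g <- G(tm[isEvent], left = TRUE)
    if (any(g <= 0))
      stop("censoring survival G(T-) is 0 for subject(s) ",
           paste(records$subject_id[isEvent][g <= 0], collapse = ", "),
           call. = FALSE)
    w[isEvent] <- s[isEvent]^2 / g
  }
  if (any(isAlive)) {
    gstar <- G(tStar)
    if (gstar <= 0)
      stop("censoring survival G(tStar) is 0: horizon not evaluable",
           call. = FALSE)
    w[isAlive] <- (1 - s[isAlive])^2 / gstar
  }
  mean(w)
}

#' Index of prediction accuracy (IPA)
#'
#' `IPA = (1 - BS_model(tStar) / BS_null(tStar)) * 100`, in percent. The
#' null model predicts, for every subject, the (training-set)
#' Kaplan-Meier survival probability at `tStar`. 100 indicates a perfect
#' (zero-Brier) model, 0 a model no better than the marginal
#' Kaplan-Meier, and negative values a harmful model.
#'
#' @inheritParams ipcwBrier
#' @param trainRecords Records used for the null Kaplan-Meier curve
#'   (defaults to `records`).
#' @return IPA in percent (may be negative), with attributes `brier` and
#'   `brierNull`.
#' @export
ipa <- function(survProb, records, tStar, trainRecords = records) {
  bs <- ipcwBrier(survProb, records, tStar)
  kmNull <- .kmStepFun(trainRecords, flip = FALSE)
  s0 <- kmNull(min(tStar, max(trainRecords$time)))
  bs0 <- ipcwBrier(rep(s0, nrow(records)), records, tStar)
  if (bs0 <= 0)
    stop("null-model Brier score is 0: degenerate sample", call. = FALSE)
  structure((1 - bs / bs0) * 100, brier = bs, brierNull = bs0)
}

#' Full evaluation report at a horizon
#'
#' Bundles the concordance index, IPCW Brier score, null Brier score and
#' IPA for one set of predictions.
#'
#' @param scores Ranking scores, larger = longer predicted survival.
#' @param survProb Predicted survival probabilities at `tStar`.
#' @inheritParams ipa
#' @param ties Tie rule forwarded to [concordanceIndex()].
#' @return A list with elements `ci`, `brier`, `brier_null`,
#'   `ipa_percent` and `n_pairs`.
#' @export
evaluationReport <- function(scores, survProb, records, tStar,
                             trainRecords = records,
                             ties = c("strict", "half")) {
  ci <- concordanceIndex(scores, records, ties = match.arg(ties))
  ip <- ipa(survProb, records, tStar, trainRecords = trainRecords)
  list(ci = as.numeric(ci),
       brier = as.numeric(attr(ip, "brier")),
       brier_null = as.numeric(attr(ip, "brierNull")),
       ipa_percent = as.numeric(ip),
       n_pairs = attr(ci, "nPairs"))
}
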