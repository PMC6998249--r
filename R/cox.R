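# Cox proportional-hazards baseline over feature tables: unpenalized fits
# via survival::coxph (Breslow ties), L1 path via glmnet's Cox family,
# plus a hand-written Breslow log partial likelihood used as the
# independent evaluation of any coefficient vector.

.featureMatrix <- function(features) {
  if (is.data.frame(features)) {
    if ("subject_id" %in% names(features))
      features <- features[setdiff(names(features), "subject_id")]
    features <- as.matrix(features)
  }
  if (!is.numeric(features))
    stop("features must be numeric", call. = FALSE)
  if (is.null(colnames(features)))
    colnames(features) <- paste0("x", seq_len(ncol(features)))
  features
}

#' Breslow log partial likelihood
#'
#' Direct evaluation of the Breslow-ties Cox log partial likelihood at a
#' given coefficient vector:
#' `sum over event times of [sum of eta over tied events - d * log(sum of
#' exp(eta) over the risk set)]`.
#'
#' @param beta Coefficient vector.
#' @param features Numeric matrix or data frame `n x p`.
#' @param records Data frame with columns `subject_id`, `time`, `event`.
#' @return Scalar log partial likelihood.
#' @export
breslowLogLik <- function(beta, features, records) {
  .checkRecords(records)
  X <- .featureMatrix(features)
  eta <- drop(X %*% beta)
  ll <- 0
  for (t in unique(records$time[records$event == 1])) {
    ev <- records$event == 1 & records$time == t
    atRisk <- records$time >= t
    ll <- ll + sum(eta[ev]) - sum(ev) * log(sum(exp(eta[atRisk])))
  }
  ll
}

#' Fit a Cox proportional-hazards baseline
#'
#' With `l1Penalty = 0` the Breslow-ties partial likelihood is maximized
#' by [survival::coxph()]; with a positive penalty the coefficients come
#' from [glmnet::glmnet()]'s Cox family at that penalty (features
#' standardized internally, coefficients reported on the original scale).
#' Nonzero coefficients are recorded as the selected features.
#' Non-convergence and monotone-likelihood (perfect-separation) warnings
#' are captured and flagged, not silenced.
#'
#' @param features Numeric matrix or data frame `n x p` (a `subject_id`
#'   column, if present, is dropped); rows aligned with `records`.
#' @param records Data frame with columns `subject_id`, `time`, `event`.
#' @param l1Penalty Nonnegative L1 penalty (glmnet's lambda scale).
#' @return A [CoxSurvFit-class].
#' @examples
#' set.seed(1)
#' sim <- simulateFeatureCohort(100, 1, beta = 1, seed = 1)
#' coxFit(sim$features, sim$records)
#' @export
coxFit <- function(features, records, l1Penalty = 0) {
  .checkRecords(records)
  X <- .featureMatrix(features)
  if (nrow(X) != nrow(records))
    stop("features and records have different row counts", call. = FALSE)
  stopifnot(l1Penalty >= 0)
  if (l1Penalty == 0) {
    if (any(apply(X, 2L, function(x) diff(range(x)) == 0)))
      stop("constant feature column: unpenalized fit is unidentifiable",
           call. = FALSE)
    converged <- TRUE
    fit <- withCallingHandlers(
      survival::coxph(
        survival::Surv(records$time, records$event) ~ X,
        ties = "breslow",
        control = survival::coxph.control(eps = 1e-9, iter.max = 50)),
      warning = function(w) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      })
    beta <- setNames(as.numeric(stats::coef(fit)), colnames(X))
    ll <- fit$loglik[2L]
    converged <- converged && all(is.finite(beta))
  } else {
    fit <- glmnet::glmnet(
      X, survival::Surv(records$time, records$event),
      family = "cox", alpha = 1, lambda = l1Penalty,
      standardize = TRUE)
    beta <- setNames(as.numeric(stats::coef(fit)), colnames(X))
    ll <- breslowLogLik(beta, X, records)
    converged <- TRUE
  }
  new("CoxSurvFit", coefficients = beta, converged = converged,
      logPartialLik = as.numeric(ll),
      selected = colnames(X)[beta != 0],
      lambda = as.numeric(l1Penalty))
}

#' Linear risk score of a Cox fit
#'
#' The linear predictor `x' beta` per subject. Higher values mean higher
#' hazard, i.e. shorter predicted survival; negate before passing to
#' [concordanceIndex()], which expects larger = longer survival.
#'
#' @param fit A [CoxSurvFit-class].
#' @param features Feature matrix or data frame with the fit's columns.
#' @return Numeric vector of risk scores.
#' @export
coxRiskScore <- function(fit, features) {
  stopifnot(is(fit, "CoxSurvFit"))
  X <- .featureMatrix(features)
  if (ncol(X) != length(fit@coefficients))
    stop("feature dimension does not match the fit", call. = FALSE)
  drop(X %*% fit@coefficients)
}

#' Cross-validated L1 feature selection (LASSO-Cox)
#'
#' Runs [glmnet::cv.glmnet()] on the Cox family over a log-spaced lambda
#' path (50 points spanning two decades below the all-zero lambda, unless
#' an explicit grid is given), picks lambda by cross-validated partial
#' likelihood under the chosen rule, refits at that lambda, and returns
#' the nonzero-coefficient features. The default `"1se"` rule takes the
#' sparsest model within one standard error of the best, the usual
#' parsimonious choice; `"min"` takes the best-scoring lambda.
#'
#' @inheritParams coxFit
#' @param lambdas Optional explicit lambda grid; a single value skips
#'   cross-validation and fits at that value.
#' @param nFolds Number of CV folds (>= 2, default 5).
#' @param seed Integer seed for the fold assignment.
#' @param rule `"1se"` (default) or `"min"`.
#' @return A list with `selected` (character), `lambda` (numeric) and
#'   `fit` (the [CoxSurvFit-class] refit at the chosen lambda). An
#'   all-zero solution returns an empty selection with a warning.
#' @export
lassoPathSelect <- function(features, records, lambdas = NULL,
                            nFolds = 5L, seed = 1L,
                            rule = c("1se", "min")) {
  .checkRecords(records)
  rule <- match.arg(rule)
  X <- .featureMatrix(features)
  y <- survival::Surv(records$time, records$event)
  if (!is.null(lambdas) && length(lambdas) == 1L) {
    fit <- coxFit(X, records, l1Penalty = lambdas)
    return(list(selected = fit@selected, lambda = as.numeric(lambdas),
                fit = fit))
  }
  if (nFolds < 2L) stop("need at least 2 folds", call. = FALSE)
  set.seed(as.integer(seed))
  foldid <- sample(rep_len(seq_len(nFolds), nrow(X)))
  cv <- if (is.null(lambdas))
    glmnet::cv.glmnet(X, y, family = "cox", alpha = 1, foldid = foldid,
                      nlambda = 50L, lambda.min.ratio = 0.01)
  else
    glmnet::cv.glmnet(X, y, family = "cox", alpha = 1, foldid = foldid,
                      lambda = sort(lambdas, decreasing = TRUE))
  lam <- if (rule == "1se") cv$lambda.1se else cv$lambda.min
  fit <- coxFit(X, records, l1Penalty = lam)
  if (length(fit@selected) == 0L)
    warning("L1 path selected no features (all-zero solution)",
            call. = FALSE)
  list(selected = fit@selected, lambda = as.numeric(lam), fit = fit)
}
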