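test_that("concordance index handles perfect, reversed and degenerate orderings", {
  rec <- data.frame(subject_id = letters[1:5], time = 1:5 * 100,
                    event = 1)
  expect_equal(as.numeric(concordanceIndex(1:5, rec)), 1)
  expect_equal(as.numeric(concordanceIndex(5:1, rec)), 0)
  expect_equal(attr(concordanceIndex(1:5, rec), "nPairs"), 10L)

  # all-censored data has no evaluable pairs: explicit error, not 0
  recC <- transform(rec, event = 0)
  expect_error(concordanceIndex(1:5, recC), "pairs")

  # all-tied scores earn nothing under the strict rule, half under half
  expect_equal(as.numeric(concordanceIndex(rep(1, 5), rec)), 0)
  expect_equal(as.numeric(concordanceIndex(rep(1, 5), rec,
                                           ties = "half")), 0.5)
})

test_that("concordance index equals the pair-enumeration oracle", {
  set.seed(21)
  for (rep in 1:100) {
    n <- sample(5:30, 1)
    rec <- randomRecords(n)
    if (sum(rec$event) == 0) rec$event[1] <- 1
    # integer scores force ties into the comparison
    sc <- sample(1:8, n, replace = TRUE)
    for (rule in c("strict", "half")) {
      expect_equal(as.numeric(concordanceIndex(sc, rec, ties = rule)),
                   ciOracle(sc, rec, rule), tolerance = 1e-12)
    }
  }
})

test_that("concordance index is a proper rank statistic", {
  set.seed(22)
  rec <- randomRecords(40)
  sc <- rnorm(40)
  ci <- as.numeric(concordanceIndex(sc, rec))
  # invariant under strictly increasing transforms
  expect_equal(as.numeric(concordanceIndex(exp(2 * sc), rec)), ci)
  expect_equal(as.numeric(concordanceIndex(rank(sc), rec)), ci)
  # complementarity without ties
  expect_equal(ci + as.numeric(concordanceIndex(-sc, rec)), 1)
  # agreement with the survival package's Harrell estimator (half rule)
  cf <- survival::concordance(
    survival::Surv(rec$time, rec$event) ~ sc)
  expect_equal(as.numeric(concordanceIndex(sc, rec, ties = "half")),
               as.numeric(cf$concordance), tolerance = 1e-12)
})

test_that("random scores concentrate at concordance one half", {
  cis <- vapply(1:200, function(s) {
    set.seed(4000 + s)
    rec <- randomRecords(30)
    if (sum(rec$event) == 0) rec$event[1] <- 1
    as.numeric(concordanceIndex(rnorm(30), rec))
  }, numeric(1))
  expect_lt(abs(mean(cis) - 0.5), 0.05)
})

test_that("IPCW Brier score has its analytic values without censoring", {
  rec <- data.frame(subject_id = letters[1:6], time = 1:6 * 100,
                    event = 1)
  tStar <- 350
  # perfectly calibrated indicator predictions give 0
  expect_equal(ipcwBrier(as.numeric(rec$time > tStar), rec, tStar), 0)
  # a constant 0.5 gives 0.25
  expect_equal(ipcwBrier(rep(0.5, 6), rec, tStar), 0.25)
  # reduction to the plain mean squared error
  set.seed(23)
  s <- runif(6)
  expect_equal(ipcwBrier(s, rec, tStar),
               mean((as.numeric(rec$time > tStar) - s)^2),
               tolerance = 1e-12)
})

test_that("IPCW Brier score equals the weighted-sum oracle under censoring", {
  set.seed(24)
  for (rep in 1:20) {
    rec <- randomRecords(50, censorFrac = 0.3)
    if (sum(rec$event) == 0) rec$event[1] <- 1
    tStar <- unname(quantile(rec$time, 0.5))
    s <- runif(50)
    expect_equal(ipcwBrier(s, rec, tStar), brierOracle(s, rec, tStar),
                 tolerance = 1e-12)
  }
})

test_that("IPA is 0 for the null, 100 for perfect, negative for harmful", {
  set.seed(25)
  rec <- randomRecords(60, censorFrac = 0)
  rec$event <- 1
  tStar <- unname(quantile(rec$time, 0.3))
  s0 <- as.numeric(survivalAt(kaplanMeier(rec),
                              min(tStar, max(rec$time))))
  expect_equal(as.numeric(ipa(rep(s0, 60), rec, tStar)), 0,
               tolerance = 1e-9)
  expect_equal(as.numeric(ipa(as.numeric(rec$time > tStar), rec,
                              tStar)), 100)
  # predicting the complement of the null on a balanced sample is harmful
  expect_lt(as.numeric(ipa(rep(1 - s0, 60), rec, tStar)), 0)
})

test_that("IPA decreases as the model Brier score grows", {
  set.seed(26)
  rec <- randomRecords(80, censorFrac = 0.2)
  if (sum(rec$event) == 0) rec$event[1] <- 1
  tStar <- unname(quantile(rec$time, 0.5))
  truth <- as.numeric(rec$time > tStar)
  noise <- runif(80)
  mix <- function(w) pmin(pmax((1 - w) * truth + w * noise, 0), 1)
  ipas <- vapply(c(0, 0.3, 0.6, 1), function(w)
    as.numeric(ipa(mix(w), rec, tStar)), numeric(1))
  expect_true(all(diff(ipas) < 0))
})

test_that("evaluation report bundles the metrics consistently", {
  set.seed(27)
  rec <- randomRecords(50, censorFrac = 0.2)
  if (sum(rec$event) == 0) rec$event[1] <- 1
  tStar <- unname(quantile(rec$time, 0.4))
  s <- runif(50)
  rep <- evaluationReport(scores = s, survProb = s, records = rec,
                          tStar = tStar)
  expect_named(rep, c("ci", "brier", "brier_null", "ipa_percent",
                      "n_pairs"))
  expect_equal(rep$ci, as.numeric(concordanceIndex(s, rec)))
  expect_equal(rep$brier, ipcwBrier(s, rec, tStar))
  expect_equal(rep$ipa_percent,
               (1 - rep$brier / rep$brier_null) * 100)
})
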