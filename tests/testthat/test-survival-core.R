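test_that("interval grid places boundaries at event-time quantiles", {
  rec <- data.frame(subject_id = as.character(1:5),
                    time = c(100, 200, 300, 400, 500),
                    event = c(1, 1, 1, 1, 0))
  g <- makeIntervalGrid(rec, 2)
  # median of {100, 200, 300, 400} (type-7) is 250; last boundary is the
  # maximum follow-up, here the censored 500
  expect_equal(boundaries(g), c(0, 250, 500))

  # fully tied event times collapse to a single extended interval
  rec2 <- data.frame(subject_id = as.character(1:4),
                     time = c(180, 180, 180, 400),
                     event = c(1, 1, 1, 0))
  g2 <- makeIntervalGrid(rec2, 3)
  expect_equal(boundaries(g2), c(0, 400))
  expect_equal(nIntervals(g2), 1L)

  expect_error(makeIntervalGrid(
    data.frame(subject_id = "a", time = 100, event = 0), 3),
    "no uncensored")
  expect_error(makeIntervalGrid(rec, 0), "nIntervals")
})

test_that("quantile grid balances event counts across intervals", {
  set.seed(71)
  n <- 1000
  rec <- data.frame(subject_id = as.character(1:n),
                    time = rexp(n, 1 / 365), event = 1)
  g <- makeIntervalGrid(rec, 4)
  b <- boundaries(g)
  counts <- table(cut(rec$time, b, right = FALSE))
  expect_equal(nIntervals(g), 4L)
  expect_true(all(abs(as.numeric(counts) - 250) <= 2))
})

test_that("target encoding follows the event and censoring rules", {
  g <- intervalGrid(c(0, 180, 360, 540))
  # death at day 316 falls in the second interval
  tg <- encodeTargets(
    data.frame(subject_id = "p1", time = 316, event = 1), g)
  expect_equal(as.numeric(tg@events), c(0, 1, 0))
  expect_equal(as.numeric(tg@atRisk), c(1, 1, 0))
  # censored exactly at the last boundary survives all intervals
  tg2 <- encodeTargets(
    data.frame(subject_id = "p2", time = 540, event = 0), g)
  expect_equal(as.numeric(tg2@events), c(0, 0, 0))
  expect_equal(as.numeric(tg2@atRisk), c(1, 1, 1))
  # censored mid-interval: not at risk for the censoring interval
  tg3 <- encodeTargets(
    data.frame(subject_id = "p3", time = 200, event = 0), g)
  expect_equal(as.numeric(tg3@atRisk), c(1, 0, 0))
  # midpoint rule counts the censoring interval when past its middle
  tg4 <- encodeTargets(
    data.frame(subject_id = "p4", time = 300, event = 0), g,
    censorRule = "midpoint")
  expect_equal(as.numeric(tg4@atRisk), c(1, 1, 0))
  # follow-up beyond the grid is clamped, event-free
  tg5 <- encodeTargets(
    data.frame(subject_id = "p5", time = 900, event = 1), g)
  expect_equal(as.numeric(tg5@events), c(0, 0, 0))
  expect_equal(as.numeric(tg5@atRisk), c(1, 1, 1))

  expect_error(encodeTargets(
    data.frame(subject_id = "x", time = 0, event = 1), g), "positive")
})

test_that("target encoding invariants hold on random inputs", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(3:40, 1)
    J <- sample(2:8, 1)
    tg <- randomTargets(n, J)
    expect_true(validObject(tg))
    d <- tg@events; r <- tg@atRisk
    expect_true(all(rowSums(d) <= 1))
    expect_true(all(d <= r))
    # prefix property: r never rises again after a zero
    for (i in seq_len(n))
      expect_true(all(diff(which(r[i, ] == 1)) == 1) ||
                  sum(r[i, ]) <= 1)
  }
})

test_that("discrete hazard loss matches its analytic and brute-force values", {
  g <- intervalGrid(c(0, 100))
  tg <- encodeTargets(
    data.frame(subject_id = "a", time = 50, event = 1), g)
  expect_equal(discreteSurvivalLoss(matrix(0.5), tg), -log(0.5),
               tolerance = 1e-12)

  # literal double sum over subjects and intervals
  set.seed(7)
  for (rep in 1:100) {
    n <- sample(2:6, 1); J <- sample(2:5, 1)
    tg <- randomTargets(n, J)
    h <- randomHazards(n, J)
    ref <- 0
    for (i in 1:n) for (j in 1:J) {
      if (tg@atRisk[i, j] == 0) next
      ref <- ref + if (tg@events[i, j] == 1) -log(h[i, j])
                   else -log(1 - h[i, j])
    }
    expect_equal(discreteSurvivalLoss(h, tg), ref, tolerance = 1e-12)
  }
})

test_that("loss decomposes over intervals and vanishes at perfect prediction", {
  set.seed(8)
  tg <- randomTargets(10, 5)
  h <- randomHazards(10, 5)
  perInterval <- vapply(1:5, function(j) {
    sub <- new("DiscreteTargets",
               events = tg@events[, j, drop = FALSE],
               atRisk = tg@atRisk[, j, drop = FALSE],
               subjectIds = tg@subjectIds,
               grid = intervalGrid(boundaries(tg)[c(1, j + 1)]))
    discreteSurvivalLoss(h[, j, drop = FALSE], sub)
  }, numeric(1))
  expect_equal(sum(perInterval), discreteSurvivalLoss(h, tg),
               tolerance = 1e-10)

  # perfect prediction: hazard at the clip boundary everywhere
  eps <- 1e-7
  hPerfect <- ifelse(tg@events == 1, 1 - eps, eps)
  hPerfect[hPerfect <= 0] <- eps
  expect_lt(discreteSurvivalLoss(hPerfect, tg), 10 * 5 * 2 * eps * 2)
})

test_that("loss gradient matches central differences and is monotone", {
  set.seed(9)
  tg <- randomTargets(6, 4)
  h <- randomHazards(6, 4)
  gr <- discreteSurvivalLossGradient(h, tg)
  eps <- 1e-6
  for (k in sample(length(h), 10)) {
    h1 <- h; h1[k] <- h1[k] + eps
    h2 <- h; h2[k] <- h2[k] - eps
    num <- (discreteSurvivalLoss(h1, tg) -
            discreteSurvivalLoss(h2, tg)) / (2 * eps)
    expect_equal(gr[k], num, tolerance = 1e-5)
  }
  # per-cell loss decreases toward h = 1 on failure cells, h = 0 on
  # survived at-risk cells
  gridH <- seq(0.05, 0.95, by = 0.1)
  fail <- which(tg@events == 1)[1]
  surv <- which(tg@atRisk == 1 & tg@events == 0)[1]
  lossesF <- vapply(gridH, function(v) {
    hh <- h; hh[fail] <- v; discreteSurvivalLoss(hh, tg)
  }, numeric(1))
  lossesS <- vapply(gridH, function(v) {
    hh <- h; hh[surv] <- v; discreteSurvivalLoss(hh, tg)
  }, numeric(1))
  expect_true(all(diff(lossesF) < 0))
  expect_true(all(diff(lossesS) > 0))
})

test_that("hazards convert to monotone survival curves", {
  g <- intervalGrid(c(0, 180, 360))
  sc <- hazardsToSurvival(matrix(c(0.1, 0.2), 1), g)
  expect_equal(as.numeric(sc@probabilities), c(0.9, 0.72))

  # near-zero hazards give a flat curve at 1
  eps <- 1e-7
  sc0 <- hazardsToSurvival(matrix(eps, 1, 3),
                           intervalGrid(c(0, 1, 2, 3)))
  expect_equal(as.numeric(sc0@probabilities), rep(1, 3),
               tolerance = 1e-5)

  set.seed(10)
  h <- randomHazards(7, 6)
  sc2 <- hazardsToSurvival(h, intervalGrid(seq(0, 600, by = 100)))
  expect_true(validObject(sc2))
  for (i in 1:7)
    expect_equal(sc2@probabilities[i, 6], prod(1 - h[i, ]),
                 tolerance = 1e-12)
})

test_that("survival curves evaluate as right-continuous step functions", {
  g <- intervalGrid(c(0, 180, 360))
  sc <- hazardsToSurvival(matrix(c(0.1, 0.2), 1), g)
  expect_equal(as.numeric(survivalAt(sc, 0)), 1)
  expect_equal(as.numeric(survivalAt(sc, 200)), 0.9)
  expect_equal(as.numeric(survivalAt(sc, 180)), 0.9)
  expect_equal(as.numeric(survivalAt(sc, 360)), 0.72)
  expect_error(survivalAt(sc, 400), "extrapolation")
})

test_that("Kaplan-Meier matches closed forms and the empirical survivor", {
  rec <- data.frame(subject_id = c("a", "b"), time = c(100, 200),
                    event = 1)
  km <- kaplanMeier(rec)
  expect_equal(as.numeric(survivalAt(km, 100)), 0.5)
  expect_equal(as.numeric(survivalAt(km, 200)), 0)

  # censoring does not drop the curve
  rec2 <- data.frame(subject_id = c("a", "b"), time = c(100, 150),
                     event = c(1, 0))
  km2 <- kaplanMeier(rec2)
  expect_equal(as.numeric(survivalAt(km2, 100)), 0.5)
  expect_equal(as.numeric(survivalAt(km2, 100.5)), 0.5)

  # no censoring: equals the empirical survival function exactly
  set.seed(11)
  t3 <- sort(rexp(40, 1 / 200))
  rec3 <- data.frame(subject_id = as.character(1:40), time = t3,
                     event = 1)
  km3 <- kaplanMeier(rec3)
  for (tt in t3)
    expect_equal(as.numeric(survivalAt(km3, tt)), mean(t3 > tt),
                 tolerance = 1e-12)

  # large-sample agreement with the true exponential survival
  set.seed(12)
  lam <- 1 / 365
  t4 <- rexp(200, lam)
  rec4 <- data.frame(subject_id = as.character(1:200), time = t4,
                     event = 1)
  km4 <- kaplanMeier(rec4)
  ts <- seq(10, max(t4) * 0.9, length.out = 50)
  diffs <- vapply(ts, function(tt)
    abs(as.numeric(survivalAt(km4, tt)) - exp(-lam * tt)), numeric(1))
  expect_lt(max(diffs), 0.1)

  expect_error(kaplanMeier(data.frame()), "nonempty")
})
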