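# Shared fixture builders. Everything is generated in code; no files.

# random survival records with roughly the requested censoring fraction
randomRecords <- function(n, censorFrac = 0.3, rate = 1 / 365,
                          maxT = 2000) {
  e <- rexp(n, rate)
  cens <- rbinom(n, 1, censorFrac) == 1
  time <- ifelse(cens, pmin(e * runif(n), maxT), pmin(e, maxT))
  data.frame(subject_id = sprintf("s%03d", seq_len(n)),
             time = pmax(time, 0.5),
             event = as.integer(!cens & e <= maxT),
             stringsAsFactors = FALSE)
}

# random valid (d, r) targets on a J-interval grid for n subjects
randomTargets <- function(n, J, maxT = J * 100) {
  grid <- intervalGrid(seq(0, maxT, length.out = J + 1))
  rec <- data.frame(subject_id = sprintf("s%03d", seq_len(n)),
                    time = runif(n, 1, maxT),
                    event = rbinom(n, 1, 0.6),
                    stringsAsFactors = FALSE)
  encodeTargets(rec, grid)
}

randomHazards <- function(n, J) {
  matrix(runif(n * J, 0.05, 0.95), n, J)
}

# a disc-shaped ImageSample for preprocessing tests
discSample <- function(side, center, radius, level = 120, id = "s1",
                       sliceIndex = 1L) {
  xs <- matrix(seq_len(side) - center[1], side, side)
  ys <- matrix(seq_len(side) - center[2], side, side, byrow = TRUE)
  mask <- ((xs^2 + ys^2) <= radius^2) * 1
  px <- pmin(pmax(level + 20 * matrix(rnorm(side^2), side), 0), 255)
  imageSample(px * mask, mask, subjectId = id, sliceIndex = sliceIndex)
}

# literal O(n^2) pair-enumeration concordance oracle
ciOracle <- function(scores, records, ties = "strict") {
  credit <- 0; pairs <- 0
  for (i in seq_len(nrow(records))) {
    if (records$event[i] != 1) next
    for (j in seq_len(nrow(records))) {
      if (records$time[j] <= records$time[i]) next
      pairs <- pairs + 1
      if (scores[i] < scores[j]) credit <- credit + 1
      else if (ties == "half" && scores[i] == scores[j])
        credit <- credit + 0.5
    }
  }
  if (pairs == 0) stop("no pairs")
  credit / pairs
}

# literal per-subject IPCW Brier oracle using survfit for the censoring KM
brierOracle <- function(surv, records, tStar) {
  Gfit <- survival::survfit(
    survival::Surv(records$time, 1 - records$event) ~ 1)
  G <- function(t) {
    i <- findInterval(t, Gfit$time)
    if (i == 0) 1 else Gfit$surv[i]
  }
  total <- 0
  for (i in seq_len(nrow(records))) {
    Ti <- records$time[i]
    if (records$event[i] == 1 && Ti <= tStar) {
      total <- total + surv[i]^2 / G(Ti - 1e-9)
    } else if (Ti > tStar) {
      total <- total + (1 - surv[i])^2 / G(tStar)
    }
  }
  total / nrow(records)
}
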