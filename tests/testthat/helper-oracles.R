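# Independent naive re-implementations of the two filters and the AUC,
# used as oracles. Deliberately written with different machinery than the
# package code (lm() for slopes, restart scans, explicit loops).

# Slope filter oracle: after the plausibility bounds, repeatedly rescan all
# three-reading windows of surviving readings from the start and remove the
# trailing reading of the earliest window violating both rules, until no
# window fires.
oracle_slope_filter <- function(trace, cfg = filter_config()) {
  time <- trace$time
  temp <- trace$temperature
  implausible <- temp < cfg$temp_min | temp > cfg$temp_max
  flagged <- rep(FALSE, length(time))
  repeat {
    surv <- which(!implausible & !flagged)
    fired <- FALSE
    if (length(surv) >= 3L) {
      for (pos in 3:length(surv)) {
        w <- surv[(pos - 2L):pos]
        sl <- unname(coef(lm(temp[w] ~ time[w]))[2L])
        if (abs(sl) > cfg$slope_threshold &&
            abs(temp[w[3L]] - temp[w[2L]]) > cfg$jump_threshold) {
          flagged[w[3L]] <- TRUE
          fired <- TRUE
          break
        }
      }
    }
    if (!fired) break
  }
  as.integer(implausible | flagged)
}

# Interval filter oracle: explicit segment bookkeeping via split().
oracle_interval_filter <- function(trace, cfg = filter_config()) {
  time <- trace$time
  temp <- trace$temperature
  implausible <- temp < cfg$temp_min | temp > cfg$temp_max
  lab <- as.integer(implausible)
  surv <- which(!implausible)
  if (length(surv) < 2L) return(lab)
  segs <- split(seq_along(surv),
                cumsum(c(0, as.integer(diff(time[surv]) > cfg$gap_threshold))))
  valid <- segs[[1L]]  # positions within surv currently considered valid
  for (k in seq_along(segs)[-1L]) {
    seg <- segs[[k]]
    if (length(seg) < cfg$min_readings_after_gap) {
      lab[surv[seg]] <- 1L
      next
    }
    if (!length(valid)) {
      valid <- seg
      next
    }
    anchor <- surv[max(valid)]
    kept_from <- NA_integer_
    for (j in seg) {
      sl <- (temp[surv[j]] - temp[anchor]) / (time[surv[j]] - time[anchor])
      if (abs(sl) < cfg$gap_slope_threshold) {
        kept_from <- j
        break
      }
      lab[surv[j]] <- 1L
    }
    if (!is.na(kept_from)) valid <- c(valid, kept_from:seg[length(seg)])
  }
  lab
}

# Hypothermia AUC oracle: explicit enumeration of every retained segment.
oracle_auc <- function(trace, labels, threshold = 36) {
  keep <- labels == 0L
  tm <- trace$time[keep]
  tv <- trace$temperature[keep]
  total <- 0
  if (length(tm) < 2L) return(total)
  for (i in 1:(length(tm) - 1L)) {
    h1 <- max(0, threshold - tv[i])
    h2 <- max(0, threshold - tv[i + 1L])
    total <- total + (h1 + h2) / 2 * (tm[i + 1L] - tm[i])
  }
  total
}

# Random trace for property tests: smooth drift around 36 degC with
# occasional recording gaps, spikes/dips and out-of-band values.
random_test_trace <- function(n, id = "r") {
  intervals <- runif(max(n - 1L, 0L), 0.5, 2)
  if (n > 6L && runif(1L) < 0.5) {
    gi <- sample(n - 1L, sample(1:2, 1L))
    intervals[gi] <- intervals[gi] + runif(length(gi), 4, 12)
  }
  temp <- 36 + cumsum(rnorm(n, 0, 0.05))
  k <- sample(0:3, 1L)
  if (k > 0L) {
    idx <- sample(n, k)
    temp[idx] <- temp[idx] + runif(k, -6, 6)
  }
  temperature_trace(id, c(0, cumsum(intervals)), round(temp, 3))
}
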