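# The two artifact-reduction algorithms and the shared plausibility bounds.
#
# Both algorithms first drop physiologically implausible values (outside the
# open interval (temp_min, temp_max)), then operate left-to-right over the
# surviving readings. Confirmed artifacts are removed from consideration
# before later windows / bridges are formed, so every comparison anchors on
# the last *valid* reading, mirroring manual chart review.

filter_result <- function(case_id, rule) {
  labels <- as.integer(!is.na(rule))
  structure(list(case_id = case_id, labels = labels, rule = rule),
            class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat(sprintf("<filter_result> case '%s': %d of %d readings flagged\n",
              x$case_id, sum(x$labels), length(x$labels)))
  if (sum(x$labels)) print(table(rule = x$rule[!is.na(x$rule)]))
  invisible(x)
}

#' Ordinary least-squares slope of three adjacent readings
#'
#' The slope filter's primitive: the OLS slope (degrees C per minute) of
#' temperature on time over exactly three points.
#'
#' @param time,temperature numeric vectors of length 3; times must be
#'   distinct.
#' @return the slope, degrees C per minute.
#' @examples
#' ols_slope(c(0, 1, 2), c(36.0, 36.5, 37.0))  # 0.5
#' ols_slope(c(0, 1, 2), c(36, 37, 36))        # 0 (symmetric)
#' @export
ols_slope <- function(time, temperature) {
  if (length(time) != 3L || length(temperature) != 3L) {
    stop("ols_slope expects exactly three (time, temperature) points",
         call. = FALSE)
  }
  if (anyDuplicated(time)) {
    stop("degenerate input: repeated time values in three-point window",
         call. = FALSE)
  }
  tc <- time - mean(time)
  sum(tc * (temperature - mean(temperature))) / sum(tc^2)
}

#' Plausibility bounds filter
#'
#' Flags readings strictly below `temp_min` or strictly above `temp_max`
#' (defaults 32 and 40 degrees C); readings exactly at a bound are retained.
#' Runs first in both algorithms.
#'
#' @param trace a [temperature_trace()].
#' @param config a [filter_config()].
#' @return a `filter_result` (`labels` 0/1 per reading; `rule` is
#'   `"plausibility"` for flagged readings, `NA` otherwise).
#' @export
plausibility_filter <- function(trace, config = filter_config()) {
  stopifnot(inherits(trace, "temperature_trace"), inherits(config, "filter_config"))
  rule <- rep(NA_character_, n_readings(trace))
  out <- trace$temperature < config$temp_min | trace$temperature > config$temp_max
  rule[out] <- "plausibility"
  filter_result(trace$case_id, rule)
}

# Core of algorithm 1, operating on the survivors of the plausibility pass.
# `keep` is logical over the original readings. Returns the rule vector with
# "slope" written where the filter fires.
#
# Semantics: process surviving readings left to right; each reading from the
# third onward is judged by the window of itself and the two previous
# surviving readings. If |OLS slope| > slope_threshold AND the reading's
# absolute change from the previous surviving reading > jump_threshold, the
# reading is removed before later windows are formed. The candidate is the
# window's NEWEST point (not its center): a line fitted through a symmetric
# dip's centered window has slope ~0, so center attribution would be blind to
# exactly the probe-fall-out dips the rule exists to catch, while trailing
# attribution fires on the dip's falling edge. Because windows are keyed by
# their trailing point, a removal never alters an already-checked window,
# and this single pass equals the naive restart-after-every-removal scan.
slope_pass <- function(time, temp, keep, config, rule) {
  surv <- which(keep)
  if (length(surv) < 3L) {
    warning("fewer than 3 surviving readings; slope filter not applied",
            call. = FALSE)
    return(rule)
  }
  pos <- 3L
  while (pos <= length(surv)) {
    w <- surv[(pos - 2L):pos]
    sl <- ols_slope(time[w], temp[w])
    if (abs(sl) > config$slope_threshold &&
        abs(temp[w[3L]] - temp[w[2L]]) > config$jump_threshold) {
      rule[w[3L]] <- "slope"
      surv <- surv[-pos]
    } else {
      pos <- pos + 1L
    }
  }
  rule
}

# Core of algorithm 2. Surviving readings are split into segments at every
# inter-reading time gap > gap_threshold. The opening segment is always
# retained. Each later segment is discarded wholesale when shorter than
# min_readings_after_gap; otherwise the bridge slope from the last valid
# reading so far to the segment's first reading decides: |slope| below
# gap_slope_threshold retains the rest of the segment, else that reading is
# flagged and the bridge is retried against the next one, until a bridge
# holds or the segment is exhausted.
interval_pass <- function(time, temp, keep, config, rule) {
  surv <- which(keep)
  if (length(surv) < 2L) return(rule)
  gap_after <- which(diff(time[surv]) > config$gap_threshold)
  if (!length(gap_after)) return(rule)
  seg_start <- c(1L, gap_after + 1L)
  seg_end <- c(gap_after, length(surv))
  valid <- rep(TRUE, length(surv))
  for (s in seq_along(seg_start)[-1L]) {
    idx <- seg_start[s]:seg_end[s]
    if (length(idx) < config$min_readings_after_gap) {
      rule[surv[idx]] <- "gap_short_segment"
      valid[idx] <- FALSE
      next
    }
    prev_valid <- which(valid[seq_len(seg_start[s] - 1L)])
    if (!length(prev_valid)) next  # no anchor before this segment: retain
    anchor <- surv[max(prev_valid)]
    for (j in idx) {
      k <- surv[j]
      bridge <- (temp[k] - temp[anchor]) / (time[k] - time[anchor])
      if (abs(bridge) < config$gap_slope_threshold) break  # segment retained
      rule[k] <- "gap_slope"
      valid[j] <- FALSE
    }
  }
  rule
}

#' Slope-based artifact filter (algorithm 1)
#'
#' After the plausibility pass, slides a three-reading window over the
#' surviving readings. A window whose OLS slope magnitude strictly exceeds
#' `slope_threshold` makes its newest (third) reading a candidate; the
#' candidate is confirmed as an artifact when its absolute temperature change
#' from the previous surviving reading strictly exceeds `jump_threshold`.
#' Confirmed artifacts are removed before subsequent windows are formed. The
#' first two surviving readings are never candidates.
#'
#' @inheritParams plausibility_filter
#' @return a `filter_result`; flagged readings carry rule `"plausibility"`
#'   or `"slope"`.
#' @examples
#' tr <- temperature_trace("a", 0:4, c(36.8, 36.8, 33.0, 36.8, 36.8))
#' slope_filter(tr)$labels  # 0 0 1 0 0
#' @export
slope_filter <- function(trace, config = filter_config()) {
  res <- plausibility_filter(trace, config)
  rule <- slope_pass(trace$time, trace$temperature, is.na(res$rule), config,
                     res$rule)
  filter_result(trace$case_id, rule)
}

#' Interval-based artifact filter (algorithm 2)
#'
#' After the plausibility pass, looks for recording gaps strictly longer than
#' `gap_threshold` minutes between consecutive surviving readings. The
#' readings after a gap (up to the next gap or the end of the trace) form a
#' segment: segments with fewer than `min_readings_after_gap` readings are
#' flagged wholesale; otherwise the slope between the last valid pre-gap
#' reading and the segment's first reading is computed, the segment being
#' retained when its magnitude is strictly below `gap_slope_threshold` and
#' the first reading flagged (and the bridge retried on the next reading)
#' otherwise.
#'
#' @inheritParams plausibility_filter
#' @return a `filter_result`; flagged readings carry rule `"plausibility"`,
#'   `"gap_short_segment"` or `"gap_slope"`.
#' @export
interval_filter <- function(trace, config = filter_config()) {
  res <- plausibility_filter(trace, config)
  rule <- interval_pass(trace$time, trace$temperature, is.na(res$rule), config,
                        res$rule)
  filter_result(trace$case_id, rule)
}

#' Run one of the two artifact-reduction algorithms
#'
#' Composition of the plausibility bounds with the chosen filter. The
#' returned label vector covers every original reading and records which rule
#' fired first for each flagged reading.
#'
#' @inheritParams plausibility_filter
#' @param algorithm `"slope"` (algorithm 1) or `"interval"` (algorithm 2).
#' @return a `filter_result`.
#' @export
run_algorithm <- function(trace, config = filter_config(),
                          algorithm = c("slope", "interval")) {
  algorithm <- match.arg(algorithm)
  switch(algorithm,
         slope = slope_filter(trace, config),
         interval = interval_filter(trace, config))
}
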