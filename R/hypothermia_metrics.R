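# Per-case derived measures computed after artifact removal.

#' Hypothermia area under the curve
#'
#' Integrates the temperature deficit below a hypothermia threshold over the
#' retained readings, in minutes x degrees C. Between consecutive retained
#' readings the segment area is the trapezoid of the clipped heights
#' `h = max(0, threshold - T)`: `(h_i + h_(i+1)) / 2 * (t_(i+1) - t_i)`.
#' Heights are clipped per reading and segments crossing the threshold are by
#' default not split at the interpolated crossing time; set
#' `split_crossings = TRUE` to integrate the clipped line exactly instead.
#' Gaps between retained readings contribute plain trapezoid area across the
#' gap (no imputation).
#'
#' @param trace a [temperature_trace()].
#' @param labels aligned label carrier (0 = retained, 1 = artifact):
#'   a [label_vector()], a [run_algorithm()] result, or a bare 0/1 vector.
#'   `NULL` retains every reading (raw-data AUC).
#' @param threshold hypothermia threshold, degrees C (default 36).
#' @param split_crossings integrate threshold crossings exactly by splitting
#'   segments at the interpolated crossing time (default `FALSE`).
#' @return non-negative AUC in minutes x degrees C.
#' @examples
#' tr <- temperature_trace("a", c(0, 10), c(36, 34))
#' hypothermia_auc(tr, c(0, 0))  # trapezoid: (0 + 2)/2 * 10 = 10
#' @export
hypothermia_auc <- function(trace, labels = NULL, threshold = 36,
                            split_crossings = FALSE) {
  stopifnot(inherits(trace, "temperature_trace"))
  keep <- if (is.null(labels)) rep(TRUE, n_readings(trace)) else
    as_labels(labels, trace) == 0L
  if (!any(keep)) {
    stop("undefined measure: no retained readings for case '", trace$case_id,
         "'", call. = FALSE)
  }
  tm <- trace$time[keep]
  h <- pmax(0, threshold - trace$temperature[keep])
  n <- length(tm)
  if (n < 2L) return(0)
  if (!split_crossings) {
    return(sum((h[-n] + h[-1L]) / 2 * diff(tm)))
  }
  # exact integral of the piecewise-linear clipped deficit: segments that
  # cross the threshold contribute a triangle on the hypothermic side
  temp <- trace$temperature[keep]
  total <- 0
  for (i in seq_len(n - 1L)) {
    h1 <- h[i]; h2 <- h[i + 1L]; dt <- tm[i + 1L] - tm[i]
    if (h1 > 0 && h2 > 0) {
      total <- total + (h1 + h2) / 2 * dt
    } else if (h1 > 0 || h2 > 0) {
      hp <- max(h1, h2)
      frac <- hp / abs(temp[i + 1L] - temp[i])  # time fraction below threshold
      total <- total + hp * frac * dt / 2
    }
  }
  total
}

#' Mean temperature after artifact removal
#'
#' Unweighted arithmetic mean of the retained temperature readings (a mean
#' over readings, not a time-weighted average).
#'
#' @inheritParams hypothermia_auc
#' @return mean temperature, degrees C.
#' @export
mean_temperature <- function(trace, labels = NULL) {
  stopifnot(inherits(trace, "temperature_trace"))
  keep <- if (is.null(labels)) rep(TRUE, n_readings(trace)) else
    as_labels(labels, trace) == 0L
  if (!any(keep)) {
    stop("undefined measure: no retained readings for case '", trace$case_id,
         "'", call. = FALSE)
  }
  mean(trace$temperature[keep])
}

#' Per-case summary after artifact removal
#'
#' @inheritParams hypothermia_auc
#' @param config a [filter_config()]; supplies the hypothermia threshold.
#' @return one-row `data.frame` with `case_id`, `mean_temperature`,
#'   `hypothermia_auc`, `n_retained`, `n_flagged`.
#' @export
summarize_case <- function(trace, labels = NULL, config = filter_config()) {
  lab <- if (is.null(labels)) rep(0L, n_readings(trace)) else
    as_labels(labels, trace)
  data.frame(case_id = trace$case_id,
             mean_temperature = mean_temperature(trace, lab),
             hypothermia_auc = hypothermia_auc(trace, lab,
                                               config$hypothermia_threshold),
             n_retained = sum(lab == 0L),
             n_flagged = sum(lab == 1L),
             stringsAsFactors = FALSE)
}

#' Summaries for a collection of cases
#'
#' @param traces list of [temperature_trace()].
#' @param labels parallel list of label carriers, or `NULL` for raw data.
#' @param config a [filter_config()].
#' @return `data.frame` with one [summarize_case()] row per case.
#' @export
summarize_cohort <- function(traces, labels = NULL, config = filter_config()) {
  stopifnot(is.list(traces))
  if (!is.null(labels) && length(labels) != length(traces)) {
    stop("`labels` must parallel `traces`", call. = FALSE)
  }
  rows <- lapply(seq_along(traces), function(i) {
    summarize_case(traces[[i]], if (is.null(labels)) NULL else labels[[i]],
                   config)
  })
  do.call(rbind, rows)
}
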