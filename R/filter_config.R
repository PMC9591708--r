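#' Filtering thresholds with study defaults
#'
#' Bundles every threshold used by the plausibility bounds and the two
#' artifact filters. Defaults are the study's published values; all
#' comparisons against these thresholds are strict ("greater than" /
#' "less than"), so a reading exactly at a bound is retained.
#'
#' @param temp_min lower plausibility bound, degrees C (default 32): readings
#'   strictly below are artifacts.
#' @param temp_max upper plausibility bound, degrees C (default 40): readings
#'   strictly above are artifacts.
#' @param slope_threshold slope filter trigger, degrees C per minute
#'   (default 0.08): a three-point OLS slope whose magnitude strictly exceeds
#'   this makes the window's center a candidate artifact.
#' @param jump_threshold confirmation jump, degrees C (default 0.25): a
#'   candidate is confirmed when its absolute change from the previous
#'   surviving reading strictly exceeds this.
#' @param gap_threshold recording gap, minutes (default 5): inter-reading
#'   intervals strictly longer than this trigger the interval filter.
#' @param min_readings_after_gap count (default 5): post-gap segments with
#'   strictly fewer readings are discarded wholesale.
#' @param gap_slope_threshold bridge slope, degrees C per minute
#'   (default 0.35): a post-gap segment is retained when the slope from the
#'   last valid pre-gap reading to its first reading is strictly below this.
#' @param hypothermia_threshold degrees C (default 36): hypothermia AUC
#'   integrates the deficit below this line.
#' @return object of class `filter_config` (named list of the thresholds).
#' @examples
#' cfg <- filter_config()
#' cfg$slope_threshold
#' @export
filter_config <- function(temp_min = 32, temp_max = 40,
                          slope_threshold = 0.08, jump_threshold = 0.25,
                          gap_threshold = 5, min_readings_after_gap = 5L,
                          gap_slope_threshold = 0.35,
                          hypothermia_threshold = 36) {
  cfg <- list(temp_min = as.numeric(temp_min), temp_max = as.numeric(temp_max),
              slope_threshold = as.numeric(slope_threshold),
              jump_threshold = as.numeric(jump_threshold),
              gap_threshold = as.numeric(gap_threshold),
              min_readings_after_gap = as.integer(min_readings_after_gap),
              gap_slope_threshold = as.numeric(gap_slope_threshold),
              hypothermia_threshold = as.numeric(hypothermia_threshold))
  if (anyNA(unlist(cfg))) stop("filter_config fields must be numeric", call. = FALSE)
  if (cfg$temp_min >= cfg$temp_max) {
    stop("temp_min must be strictly below temp_max", call. = FALSE)
  }
  pos <- c("slope_threshold", "jump_threshold", "gap_threshold",
           "min_readings_after_gap", "gap_slope_threshold",
           "hypothermia_threshold")
  bad <- pos[vapply(cfg[pos], function(v) v <= 0, logical(1L))]
  if (length(bad)) {
    stop("threshold(s) must be strictly positive: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(cfg, class = "filter_config")
}

#' @export
print.filter_config <- function(x, ...) {
  cat("<filter_config>\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Read a filter configuration from a JSON file
#'
#' The file holds an object whose keys are [filter_config()] argument names;
#' absent keys keep their defaults, unknown keys are an error.
#'
#' @param path JSON file.
#' @return a `filter_config`.
#' @export
read_filter_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(vals), names(formals(filter_config)))
  if (length(unknown)) {
    stop("unknown filter_config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(filter_config, vals)
}
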