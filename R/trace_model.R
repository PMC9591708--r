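# Domain types and delimited-text IO for intraoperative temperature traces.

#' Construct a temperature trace
#'
#' A temperature trace is one case's time-ordered sequence of core-temperature
#' readings. Times are minutes from the first reading of the case (real-valued,
#' non-negative); temperatures are degrees Celsius.
#'
#' @param case_id single string identifying the case.
#' @param time numeric vector of reading times in minutes, strictly increasing.
#' @param temperature numeric vector of temperatures in degrees C, same length
#'   as `time`.
#' @return An object of class `temperature_trace`: a list with elements
#'   `case_id`, `time`, `temperature`.
#' @examples
#' tr <- temperature_trace("case1", 0:5, c(36.5, 36.4, 36.3, 36.3, 36.2, 36.2))
#' n_readings(tr)
#' @export
temperature_trace <- function(case_id, time, temperature) {
  stopifnot(is.character(case_id), length(case_id) == 1L, nzchar(case_id))
  time <- as.numeric(time)
  temperature <- as.numeric(temperature)
  if (length(time) != length(temperature)) {
    stop("`time` and `temperature` must have equal length", call. = FALSE)
  }
  if (anyNA(time) || anyNA(temperature)) {
    stop("trace readings must not contain missing values", call. = FALSE)
  }
  if (length(time) && any(time < 0)) {
    stop("reading times must be non-negative minutes", call. = FALSE)
  }
  if (length(time) > 1L && any(diff(time) <= 0)) {
    if (any(diff(sort(time)) == 0)) {
      stop("duplicate timestamps within case '", case_id, "'", call. = FALSE)
    }
    o <- order(time)
    time <- time[o]
    temperature <- temperature[o]
  }
  structure(list(case_id = case_id, time = time, temperature = temperature),
            class = "temperature_trace")
}

#' @export
print.temperature_trace <- function(x, ...) {
  cat(sprintf("<temperature_trace> case '%s': %d readings", x$case_id,
              n_readings(x)))
  if (n_readings(x)) {
    cat(sprintf(", %.1f-%.1f min, %.1f-%.1f degC",
                min(x$time), max(x$time),
                min(x$temperature), max(x$temperature)))
  }
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.temperature_trace <- function(x, ...) {
  data.frame(case_id = rep(x$case_id, n_readings(x)),
             time_min = x$time, temperature_c = x$temperature,
             stringsAsFactors = FALSE)
}

#' Number of readings in a trace
#' @param trace a [temperature_trace()].
#' @return integer count.
#' @export
n_readings <- function(trace) {
  stopifnot(inherits(trace, "temperature_trace"))
  length(trace$time)
}

#' Construct a per-reading label vector
#'
#' Binary adjudication aligned to a trace: 1 marks an artifact reading,
#' 0 a valid reading.
#'
#' @param case_id single string, the paired trace's case id.
#' @param labels vector coercible to 0/1 integers.
#' @return An object of class `label_vector`: list with `case_id`, `labels`.
#' @export
label_vector <- function(case_id, labels) {
  stopifnot(is.character(case_id), length(case_id) == 1L)
  labels <- as.integer(labels)
  if (anyNA(labels) || !all(labels %in% c(0L, 1L))) {
    stop("labels must be binary (0 = valid, 1 = artifact)", call. = FALSE)
  }
  structure(list(case_id = case_id, labels = labels), class = "label_vector")
}

#' @export
print.label_vector <- function(x, ...) {
  cat(sprintf("<label_vector> case '%s': %d readings, %d flagged\n",
              x$case_id, length(x$labels), sum(x$labels)))
  invisible(x)
}

# Coerce the various label carriers (bare vector, label_vector, filter_result)
# to a plain 0/1 integer vector, checking alignment when a trace is given.
as_labels <- function(labels, trace = NULL) {
  out <- if (inherits(labels, "filter_result")) {
    labels$labels
  } else if (inherits(labels, "label_vector")) {
    labels$labels
  } else {
    as.integer(labels)
  }
  if (anyNA(out) || !all(out %in% c(0L, 1L))) {
    stop("labels must be binary (0 = valid, 1 = artifact)", call. = FALSE)
  }
  if (!is.null(trace) && length(out) != n_readings(trace)) {
    stop(sprintf("label length (%d) does not match trace '%s' reading count (%d)",
                 length(out), trace$case_id, n_readings(trace)), call. = FALSE)
  }
  out
}

#' Check a trace against the study eligibility rule
#'
#' A case is eligible when it carries at least 3 temperature readings;
#' shorter records are excluded (the filters' three-point windows and bridge
#' slopes are meaningless below that).
#'
#' @param trace a [temperature_trace()].
#' @param min_readings minimum reading count for eligibility (default 3).
#' @return list with `eligible` (logical) and `reason` (`NULL` when eligible,
#'   otherwise a string stating the observed count).
#' @examples
#' validate_trace(temperature_trace("a", 0:2, c(36, 36, 36)))$eligible  # TRUE
#' validate_trace(temperature_trace("b", 0:1, c(36, 36)))$reason
#' @export
validate_trace <- function(trace, min_readings = 3L) {
  n <- n_readings(trace)
  if (n < min_readings) {
    list(eligible = FALSE,
         reason = sprintf("case '%s' has %d temperature reading%s; minimum is %d",
                          trace$case_id, n, if (n == 1L) "" else "s",
                          min_readings))
  } else {
    list(eligible = TRUE, reason = NULL)
  }
}

#' Read temperature traces from a delimited text file
#'
#' Expects one row per reading with columns for case id, time and temperature
#' (canonical header `case_id,time_min,temperature_c`). Times may be raw
#' minutes or ISO-8601 timestamps; timestamps are converted to minutes from
#' each case's first reading. Rows are sorted by time within case; duplicate
#' (case, time) pairs are an error because the filters' slopes would divide
#' by zero.
#'
#' @param path file to read.
#' @param delim field delimiter (default `","`).
#' @param col_case,col_time,col_temp column names holding case id, time and
#'   temperature.
#' @param time_format `"auto"` (detect), `"minutes"`, or `"timestamp"`
#'   (ISO-8601, converted to minutes from the case's first reading).
#' @return named list of [temperature_trace()] objects, one per distinct
#'   case id, in order of first appearance.
#' @export
read_traces <- function(path, delim = ",", col_case = "case_id",
                        col_time = "time_min", col_temp = "temperature_c",
                        time_format = c("auto", "minutes", "timestamp")) {
  time_format <- match.arg(time_format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, sep = delim, stringsAsFactors = FALSE,
                 colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(c(col_case, col_time, col_temp), names(df))
  if (length(missing_cols)) {
    stop("format error: missing column(s) ", paste(missing_cols, collapse = ", "),
         " in ", path, call. = FALSE)
  }
  if (nrow(df) == 0L) return(structure(list(), names = character()))

  raw_time <- df[[col_time]]
  if (time_format == "auto") {
    # key on the first value: a numeric leads a minutes column, anything
    # else a timestamp column; later malformed rows error with their line
    time_format <- if (grepl("^[-+0-9.eE]+$", raw_time[1L])) "minutes" else "timestamp"
  }
  if (time_format == "timestamp") {
    p1 <- strptime(raw_time, "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
    p2 <- strptime(raw_time, "%Y-%m-%d %H:%M:%OS", tz = "UTC")
    time_num <- ifelse(!is.na(p1), as.numeric(p1), as.numeric(p2))
    if (anyNA(time_num)) {
      bad <- which(is.na(time_num))[1L]
      stop(sprintf("parse error at data line %d: non-numeric time or unparseable timestamp '%s'",
                   bad, raw_time[bad]), call. = FALSE)
    }
    # seconds since epoch; re-based to minutes per case below
  } else {
    time_num <- suppressWarnings(as.numeric(raw_time))
    if (anyNA(time_num)) {
      bad <- which(is.na(time_num))[1L]
      stop(sprintf("parse error at data line %d: non-numeric time '%s'",
                   bad, raw_time[bad]), call. = FALSE)
    }
  }
  temp_num <- suppressWarnings(as.numeric(df[[col_temp]]))
  if (anyNA(temp_num)) {
    bad <- which(is.na(temp_num))[1L]
    stop(sprintf("parse error at data line %d: non-numeric temperature '%s'",
                 bad, df[[col_temp]][bad]), call. = FALSE)
  }

  ids <- df[[col_case]]
  traces <- lapply(unique(ids), function(id) {
    sel <- ids == id
    tm <- time_num[sel]
    if (anyDuplicated(tm)) {
      stop(sprintf("validation error: duplicate timestamp within case '%s'", id),
           call. = FALSE)
    }
    if (time_format == "timestamp") tm <- (tm - min(tm)) / 60
    temperature_trace(id, tm, temp_num[sel])
  })
  names(traces) <- unique(ids)
  traces
}

#' Write labeled traces to a delimited text file
#'
#' Emits columns `case_id, time_min, temperature_c` plus one label column per
#' label set (`label` for a single set; the set's name as given otherwise,
#' e.g. `label_rater1`). Re-reading with [read_labels()] reproduces the data.
#'
#' @param traces list of [temperature_trace()].
#' @param labels list parallel to `traces`; each element is a label carrier
#'   ([label_vector()], [filter_result][run_algorithm()] or bare 0/1 vector)
#'   or a named list of several such carriers (multi-rater output).
#' @param path output file.
#' @param delim field delimiter.
#' @return `path`, invisibly.
#' @export
write_labels <- function(traces, labels, path, delim = ",") {
  stopifnot(is.list(traces), is.list(labels), length(traces) == length(labels))
  label_cols <- "label"
  if (length(labels)) {
    first <- labels[[1L]]
    if (is.list(first) && !inherits(first, c("label_vector", "filter_result"))) {
      label_cols <- names(first)
      if (is.null(label_cols) || any(!nzchar(label_cols))) {
        stop("multi-rater label sets must be named", call. = FALSE)
      }
    }
  }
  rows <- lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    li <- labels[[i]]
    if (!is.list(li) || inherits(li, c("label_vector", "filter_result"))) {
      li <- stats::setNames(list(li), label_cols)
    }
    out <- as.data.frame(tr)
    for (nm in label_cols) out[[nm]] <- as_labels(li[[nm]], tr)
    out
  })
  df <- if (length(rows)) do.call(rbind, rows) else {
    empty <- data.frame(case_id = character(), time_min = numeric(),
                        temperature_c = numeric(), stringsAsFactors = FALSE)
    empty[label_cols] <- integer()
    empty
  }
  write.csv_delim(df, path, delim)
  invisible(path)
}

# write.csv with a configurable delimiter and no row names
write.csv_delim <- function(df, path, delim = ",") {
  utils::write.table(df, path, sep = delim, row.names = FALSE, quote = FALSE)
}

#' Read labeled traces written by [write_labels()]
#'
#' @inheritParams read_traces
#' @return named list (one element per case) of lists with `trace`
#'   (a [temperature_trace()]) and `labels` (an integer matrix, one column
#'   per label column in the file).
#' @export
read_labels <- function(path, delim = ",") {
  traces <- read_traces(path, delim = delim)
  df <- read.csv(path, sep = delim, stringsAsFactors = FALSE, check.names = FALSE)
  lab_cols <- grep("^label", names(df), value = TRUE)
  if (!length(lab_cols)) {
    stop("format error: no label column (expected 'label' or 'label_<rater>') in ",
         path, call. = FALSE)
  }
  lapply(traces, function(tr) {
    sel <- df$case_id == tr$case_id
    o <- order(as.numeric(df$time_min[sel]))
    labs <- as.matrix(df[sel, lab_cols, drop = FALSE])[o, , drop = FALSE]
    storage.mode(labs) <- "integer"
    rownames(labs) <- NULL
    if (anyNA(labs) || !all(labs %in% c(0L, 1L))) {
      stop("validation error: non-binary labels for case '", tr$case_id, "'",
           call. = FALSE)
    }
    list(trace = tr, labels = labs)
  })
}
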