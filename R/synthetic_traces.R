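# Seeded generator of anesthesia-typical temperature traces with
# truth-labeled injected artifacts. Stands in for registry data that cannot
# be deposited: general anesthesia redistributes heat from core to periphery,
# so a typical trace starts near 36.5 degC, declines for the first hour or
# so, then plateaus and slowly rewarms. Artifacts of three mechanistic kinds
# are injected: probe fall-out dips toward ambient, probe warm-up ramps after
# reinsertion, and implausible readings following a recording gap.

# Evaluate code with a temporary RNG state; the caller's stream is untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Deterministic per-case seed fan-out from the master seed (kept below 2^31
# because R seeds are 32-bit integers).
case_seed <- function(seed, case_index) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(case_index)) %% 2147483629)
}

#' Simulation parameters for the synthetic cohort
#'
#' Defaults emulate the study cohort: 200 cases; per-case reading counts
#' log-normal with median 103 and quartiles near 51 and 185.5 (`meanlog =
#' log(103)`, `sdlog = 0.95`), truncated below at the 3-reading inclusion
#' minimum; roughly minute-level sampling with jitter; a core-temperature
#' curve that starts near 36.5 degC, cools by ~1.3 degC with a 60-minute time
#' constant (initial slope ~0.02 degC/min) and rewarms slowly after 90
#' minutes; and artifacts injected at an overall per-reading rate of 1%.
#'
#' @param n_cases number of cases (default 200).
#' @param readings_meanlog,readings_sdlog log-normal parameters of the
#'   per-case reading count.
#' @param min_readings lower truncation of the reading count (default 3).
#' @param max_readings upper truncation, bounding runtime (default 2000).
#' @param sampling_interval nominal inter-reading interval, minutes.
#' @param interval_jitter relative uniform jitter on each interval.
#' @param baseline_start starting core temperature, degC.
#' @param cooling_drop asymptotic core-temperature drop, degC.
#' @param cooling_tau cooling time constant, minutes.
#' @param rewarm_start minutes after which slow rewarming begins.
#' @param rewarm_rate rewarming slope, degC per minute.
#' @param noise_sd measurement noise SD, degC (default 0.02, well below the
#'   filters' jump threshold so clean traces are never flagged).
#' @param artifact_rate per-reading artifact probability (default 0.01).
#' @param artifact_mix named proportions of the three artifact kinds
#'   (`fall_out_dip`, `warm_up_ramp`, `post_gap_garbage`); must sum to 1.
#' @param gap_rate per-interval probability of a benign recording gap.
#' @param gap_length range (minutes) of inserted gaps, benign or artifactual.
#' @param dip_range range (degC) of ambient-dip target temperatures; the
#'   default reaches above 32 degC so some dips land inside the plausibility
#'   band and exercise the slope rule rather than only the bounds.
#' @param seed master seed; fans out deterministically to per-case seeds so
#'   any single case is regenerable in isolation.
#' @return object of class `simulation_params`.
#' @export
simulation_params <- function(n_cases = 200L,
                              readings_meanlog = log(103),
                              readings_sdlog = 0.95,
                              min_readings = 3L, max_readings = 2000L,
                              sampling_interval = 1, interval_jitter = 0.25,
                              baseline_start = 36.5, cooling_drop = 1.3,
                              cooling_tau = 60, rewarm_start = 90,
                              rewarm_rate = 0.01,
                              noise_sd = 0.02,
                              artifact_rate = 0.01,
                              artifact_mix = c(fall_out_dip = 0.4,
                                               warm_up_ramp = 0.3,
                                               post_gap_garbage = 0.3),
                              gap_rate = 0.01, gap_length = c(6, 15),
                              dip_range = c(24, 34),
                              seed = 1L) {
  p <- list(n_cases = as.integer(n_cases), readings_meanlog = readings_meanlog,
            readings_sdlog = readings_sdlog, min_readings = as.integer(min_readings),
            max_readings = as.integer(max_readings),
            sampling_interval = sampling_interval,
            interval_jitter = interval_jitter,
            baseline_start = baseline_start, cooling_drop = cooling_drop,
            cooling_tau = cooling_tau, rewarm_start = rewarm_start,
            rewarm_rate = rewarm_rate, noise_sd = noise_sd,
            artifact_rate = artifact_rate, artifact_mix = artifact_mix,
            gap_rate = gap_rate, gap_length = gap_length,
            dip_range = dip_range, seed = as.integer(seed))
  if (p$n_cases < 1L) stop("n_cases must be positive", call. = FALSE)
  if (p$artifact_rate < 0 || p$artifact_rate > 1 ||
      p$gap_rate < 0 || p$gap_rate > 1) {
    stop("artifact_rate and gap_rate must lie in [0, 1]", call. = FALSE)
  }
  if (!setequal(names(p$artifact_mix),
                c("fall_out_dip", "warm_up_ramp", "post_gap_garbage")) ||
      abs(sum(p$artifact_mix) - 1) > 1e-8 || any(p$artifact_mix < 0)) {
    stop("artifact_mix must be named proportions of the three kinds summing to 1",
         call. = FALSE)
  }
  if (p$noise_sd < 0 || length(p$gap_length) != 2L ||
      p$gap_length[1L] > p$gap_length[2L]) {
    stop("invalid noise_sd or gap_length", call. = FALSE)
  }
  structure(p, class = "simulation_params")
}

# Underlying physiologic curve: exponential core cooling toward
# (baseline - drop), then slow linear rewarming, capped at baseline.
core_curve <- function(t, p) {
  pmin(p$baseline_start,
       p$baseline_start - p$cooling_drop * (1 - exp(-t / p$cooling_tau)) +
         p$rewarm_rate * pmax(0, t - p$rewarm_start))
}

# Run lengths per artifact kind (readings consumed by one event).
event_length <- function(kind) {
  switch(kind,
         fall_out_dip = sample(1:4, 1L),
         warm_up_ramp = sample(2:5, 1L),
         post_gap_garbage = sample(1:4, 1L))
}

#' Generate one synthetic trace with truth labels
#'
#' The per-case artifact-reading budget is drawn `Binomial(n, artifact_rate)`
#' and artifact events (kinds per `artifact_mix`) are composed to meet it, so
#' cohort-level artifact fractions concentrate like a plain binomial. Events
#' keep at least 5 clean readings of margin from the trace ends and 6 from
#' each other, so injected artifacts never interact and clean stretches stay
#' clean.
#'
#' @param params a [simulation_params()].
#' @param case_index 1-based case index; fixes the per-case seed.
#' @return list with `trace` (a [temperature_trace()]), `truth`
#'   (a [label_vector()]), and `events` (data.frame of kind/start/length).
#' @export
generate_trace <- function(params, case_index) {
  stopifnot(inherits(params, "simulation_params"), case_index >= 1)
  p <- params
  with_seed(case_seed(p$seed, case_index), {
    n <- round(rlnorm(1L, p$readings_meanlog, p$readings_sdlog))
    n <- as.integer(min(max(n, p$min_readings), p$max_readings))

    intervals <- if (n > 1L) {
      p$sampling_interval * runif(n - 1L, 1 - p$interval_jitter,
                                  1 + p$interval_jitter)
    } else numeric()

    # --- plan artifact events on index space -------------------------------
    budget <- rbinom(1L, n, p$artifact_rate)
    events <- data.frame(kind = character(), start = integer(),
                         length = integer(), stringsAsFactors = FALSE)
    blocked <- rep(FALSE, n)   # readings unavailable for new events (+margin)
    injected <- 0L
    guard <- 0L
    while (injected < budget && guard < 50L) {
      guard <- guard + 1L
      kind <- sample(names(p$artifact_mix), 1L, prob = p$artifact_mix)
      len <- min(event_length(kind), budget - injected)
      ok <- which(!vapply(seq_len(n), function(s) {
        s < 2L || s + len - 1L > n - 5L ||
          any(blocked[max(1L, s - 6L):min(n, s + len + 5L)])
      }, logical(1L)))
      if (!length(ok)) break
      s <- if (length(ok) == 1L) ok else sample(ok, 1L)
      events <- rbind(events, data.frame(kind = kind, start = s, length = len,
                                         stringsAsFactors = FALSE))
      blocked[s:(s + len - 1L)] <- TRUE
      injected <- injected + len
    }

    # --- benign recording gaps --------------------------------------------
    # interval i sits between readings i and i+1; keep 5+ readings after any
    # gap and 6 readings of spacing from events and other gaps
    gap_iv <- integer()
    if (n > 1L && p$gap_rate > 0) {
      cand <- which(runif(n - 1L) < p$gap_rate)
      for (i in cand) {
        if (i > n - 5L) next
        if (any(blocked[max(1L, i - 6L):min(n, i + 6L)])) next
        if (length(gap_iv) && min(abs(gap_iv - i)) < 6L) next
        gap_iv <- c(gap_iv, i)
      }
    }
    for (i in gap_iv) intervals[i] <- intervals[i] + runif(1L, p$gap_length[1L],
                                                           p$gap_length[2L])
    gap_events <- events$start[events$kind == "post_gap_garbage"]
    for (s in gap_events) {
      intervals[s - 1L] <- intervals[s - 1L] + runif(1L, p$gap_length[1L],
                                                     p$gap_length[2L])
    }

    tm <- c(0, cumsum(intervals))
    core <- core_curve(tm, p)
    temp <- core + rnorm(n, 0, p$noise_sd)
    truth <- rep(0L, n)

    # --- write artifact values --------------------------------------------
    for (e in seq_len(nrow(events))) {
      s <- events$start[e]; len <- events$length[e]
      idx <- s:(s + len - 1L)
      if (events$kind[e] == "fall_out_dip") {
        target <- runif(1L, p$dip_range[1L], p$dip_range[2L])
        frac <- if (len == 1L) 1 else seq(0.6, 1, length.out = len)
        temp[idx] <- core[idx] - (core[idx] - target) * frac +
          rnorm(len, 0, p$noise_sd)
      } else if (events$kind[e] == "warm_up_ramp") {
        start_val <- runif(1L, 30, 34.5)
        temp[idx] <- core[idx] - (core[idx] - start_val) *
          exp(-(seq_len(len) - 1L) / 1.2) + rnorm(len, 0, p$noise_sd)
      } else {  # post_gap_garbage
        temp[idx] <- runif(len, p$dip_range[1L], p$dip_range[2L])
      }
      truth[idx] <- 1L
    }

    id <- sprintf("case_%04d", as.integer(case_index))
    list(trace = temperature_trace(id, tm, temp),
         truth = label_vector(id, truth),
         events = events)
  })
}

#' Generate a synthetic cohort
#'
#' @param params a [simulation_params()].
#' @return object of class `synthetic_cohort`: list with `cases` (list of
#'   [generate_trace()] results), `manifest` (data.frame of per-case seeds,
#'   reading counts and injected-artifact counts), and `params`.
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  cases <- lapply(seq_len(params$n_cases), function(i) generate_trace(params, i))
  manifest <- data.frame(
    case_id = vapply(cases, function(cs) cs$trace$case_id, character(1L)),
    seed = vapply(seq_len(params$n_cases),
                  function(i) case_seed(params$seed, i), integer(1L)),
    n_readings = vapply(cases, function(cs) n_readings(cs$trace), integer(1L)),
    n_artifact = vapply(cases, function(cs) sum(cs$truth$labels), integer(1L)),
    stringsAsFactors = FALSE)
  structure(list(cases = cases, manifest = manifest, params = params),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d cases, %d readings, %d injected artifacts (%.2f%%)\n",
              nrow(x$manifest), sum(x$manifest$n_readings),
              sum(x$manifest$n_artifact),
              100 * sum(x$manifest$n_artifact) / sum(x$manifest$n_readings)))
  invisible(x)
}

#' Simulate expert raters from truth labels
#'
#' Each rater's labels are the truth independently perturbed: a true artifact
#' is missed with probability `miss_rate`, a valid reading falsely flagged
#' with probability `false_alarm_rate`. The defaults (miss 0.2, false alarm
#' 0.025) put three-rater unanimity near the low-90s percent on a
#' ~1%-artifact cohort.
#'
#' @param truth a label carrier.
#' @param miss_rate,false_alarm_rate scalar rates, or one per rater.
#' @param n_raters number of raters (default 3).
#' @param seed optional seed.
#' @return items x raters integer matrix of labels.
#' @export
simulate_raters <- function(truth, miss_rate = 0.2, false_alarm_rate = 0.025,
                            n_raters = 3L, seed = NULL) {
  lab <- as_labels(truth)
  miss <- rep_len(miss_rate, n_raters)
  fa <- rep_len(false_alarm_rate, n_raters)
  if (any(miss < 0 | miss > 1 | fa < 0 | fa > 1)) {
    stop("error rates must lie in [0, 1]", call. = FALSE)
  }
  with_seed(seed, {
    m <- vapply(seq_len(n_raters), function(r) {
      out <- lab
      out[lab == 1L & runif(length(lab)) < miss[r]] <- 0L
      out[lab == 0L & runif(length(lab)) < fa[r]] <- 1L
      out
    }, integer(length(lab)))
    if (is.null(dim(m))) m <- matrix(m, nrow = length(lab))
    colnames(m) <- paste0("rater", seq_len(n_raters))
    m
  })
}
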