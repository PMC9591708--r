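# Evaluation harness: consensus labels, classification metrics, chance-
# corrected agreement, Bland-Altman, jackknife and agreement-study design.

# Coerce a set of aligned rater labelings (list of carriers, or a matrix with
# one column per rater) to an items x raters integer matrix.
rater_matrix <- function(rater_labels) {
  if (is.matrix(rater_labels)) {
    m <- rater_labels
  } else {
    stopifnot(is.list(rater_labels), length(rater_labels) >= 1L)
    cols <- lapply(rater_labels, as_labels)
    len <- vapply(cols, length, integer(1L))
    if (length(unique(len)) != 1L) {
      stop("validation error: rater label vectors have unequal lengths (",
           paste(len, collapse = ", "), ")", call. = FALSE)
    }
    m <- do.call(cbind, cols)
  }
  storage.mode(m) <- "integer"
  if (anyNA(m) || !all(m %in% c(0L, 1L))) {
    stop("labels must be binary (0 = valid, 1 = artifact)", call. = FALSE)
  }
  m
}

#' Majority-rule consensus of rater labels
#'
#' A reading is an artifact in the consensus when more than half of the
#' raters marked it so (with 3 raters: at least 2 of 3).
#'
#' @param rater_labels aligned labelings: a list of label carriers or an
#'   items x raters 0/1 matrix.
#' @return integer 0/1 consensus vector.
#' @examples
#' majority_vote(list(c(1, 1, 0), c(1, 0, 0), c(1, 1, 1)))  # 1 1 0
#' @export
majority_vote <- function(rater_labels) {
  m <- rater_matrix(rater_labels)
  as.integer(rowSums(m) > ncol(m) / 2)
}

#' Confusion counts between predicted and reference labels
#'
#' Artifact (label 1) is the positive class.
#'
#' @param predicted,reference aligned label carriers.
#' @return object of class `confusion_counts`: list with `tp`, `fp`, `fn`,
#'   `tn`.
#' @export
confusion <- function(predicted, reference) {
  p <- as_labels(predicted)
  r <- as_labels(reference)
  if (length(p) != length(r)) {
    stop(sprintf("validation error: predicted (%d) and reference (%d) lengths differ",
                 length(p), length(r)), call. = FALSE)
  }
  structure(list(tp = sum(p == 1L & r == 1L), fp = sum(p == 1L & r == 0L),
                 fn = sum(p == 0L & r == 1L), tn = sum(p == 0L & r == 0L)),
            class = "confusion_counts")
}

#' Add confusion counts across cases
#' @param ... `confusion_counts` objects (or a single list of them).
#' @return pooled `confusion_counts`.
#' @export
pool_confusion <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && !inherits(xs[[1L]], "confusion_counts")) xs <- xs[[1L]]
  out <- list(tp = 0L, fp = 0L, fn = 0L, tn = 0L)
  for (x in xs) {
    stopifnot(inherits(x, "confusion_counts"))
    for (nm in names(out)) out[[nm]] <- out[[nm]] + x[[nm]]
  }
  structure(out, class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> tp=%d fp=%d fn=%d tn=%d\n",
              x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Classification metrics from confusion counts
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, precision
#' `tp/(tp+fp)` and the F1 score (harmonic mean of precision and
#' sensitivity). A metric whose denominator is zero is reported as `NA`
#' (undefined, not 0); the names of the vanished denominators are returned
#' in `undefined`.
#'
#' @param counts a [confusion()] result.
#' @return list with `sensitivity`, `specificity`, `precision`, `f_score`,
#'   `undefined` (character vector, possibly empty).
#' @examples
#' m <- classification_metrics(confusion(c(1, 0, 0, rep(0, 7)),
#'                                       c(1, 1, 0, rep(0, 7))))
#' m$sensitivity  # 0.5
#' @export
classification_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  undef <- character()
  ratio <- function(num, den, what) {
    if (den == 0L) {
      undef <<- c(undef, what)
      NA_real_
    } else num / den
  }
  sens <- ratio(counts$tp, counts$tp + counts$fn, "sensitivity: tp+fn = 0")
  spec <- ratio(counts$tn, counts$tn + counts$fp, "specificity: tn+fp = 0")
  prec <- ratio(counts$tp, counts$tp + counts$fp, "precision: tp+fp = 0")
  f <- if (is.na(sens) || is.na(prec)) {
    undef <- c(undef, "f_score: undefined component")
    NA_real_
  } else if (prec + sens == 0) {
    undef <- c(undef, "f_score: precision+sensitivity = 0")
    NA_real_
  } else 2 * prec * sens / (prec + sens)
  list(sensitivity = sens, specificity = spec, precision = prec, f_score = f,
       undefined = undef)
}

#' Artifact prevalence with a binomial confidence interval
#'
#' @param n_artifacts,n_total artifact and total reading counts.
#' @param confidence confidence level (default 0.95).
#' @param method `"wald"` (normal approximation, default) or `"wilson"`.
#' @return list with `estimate`, `ci_low`, `ci_high` (clamped to \[0, 1\]).
#' @examples
#' artifact_rate(289, 27683)$estimate  # ~0.0104
#' @export
artifact_rate <- function(n_artifacts, n_total, confidence = 0.95,
                          method = c("wald", "wilson")) {
  method <- match.arg(method)
  if (length(n_total) != 1L || n_total <= 0) {
    stop("validation error: n_total must be a positive count", call. = FALSE)
  }
  if (n_artifacts < 0 || n_artifacts > n_total) {
    stop("validation error: n_artifacts must lie in [0, n_total]", call. = FALSE)
  }
  p <- n_artifacts / n_total
  z <- qnorm(1 - (1 - confidence) / 2)
  if (method == "wald") {
    half <- z * sqrt(p * (1 - p) / n_total)
    lo <- p - half
    hi <- p + half
  } else {
    denom <- 1 + z^2 / n_total
    center <- (p + z^2 / (2 * n_total)) / denom
    half <- z * sqrt(p * (1 - p) / n_total + z^2 / (4 * n_total^2)) / denom
    lo <- center - half
    hi <- center + half
  }
  list(estimate = p, ci_low = max(0, lo), ci_high = min(1, hi))
}

#' Gwet's AC1 chance-corrected agreement coefficient
#'
#' For two or more raters assigning binary labels to the same items. The
#' observed agreement `Pa` is the average pairwise agreement per item; the
#' chance agreement is `Pe = 2 * pi * (1 - pi)` with `pi` the artifact
#' prevalence averaged over raters; `AC1 = (Pa - Pe) / (1 - Pe)`. Unlike
#' kappa, AC1 stays well-behaved when one category is rare, which is the
#' regime of artifact adjudication (~1% prevalence). The standard error uses
#' Gwet's variance estimator for a single group of items (no rater sampling),
#' and the confidence interval uses a t critical value with `n - 1` degrees
#' of freedom, truncated to \[-1, 1\].
#'
#' @param rater_labels aligned labelings: list of label carriers or an
#'   items x raters 0/1 matrix with at least 2 raters and 2 items.
#' @param confidence confidence level for the interval (default 0.95).
#' @return list with `ac1`, `se`, `ci_low`, `ci_high`, `pa`, `pe`.
#' @export
gwet_ac1 <- function(rater_labels, confidence = 0.95) {
  m <- rater_matrix(rater_labels)
  n <- nrow(m)
  r <- ncol(m)
  if (r < 2L) stop("validation error: at least 2 raters required", call. = FALSE)
  if (n < 2L) stop("validation error: at least 2 items required", call. = FALSE)

  r1 <- rowSums(m)            # raters voting "artifact" per item
  r0 <- r - r1
  pa_i <- (r1 * (r1 - 1) + r0 * (r0 - 1)) / (r * (r - 1))
  pa <- mean(pa_i)
  pi1 <- mean(r1 / r)         # mean artifact prevalence across raters
  pe <- 2 * pi1 * (1 - pi1)
  ac1 <- (pa - pe) / (1 - pe)

  # Gwet's variance: item-level coefficients corrected for the chance term
  ac1_i <- (pa_i - pe) / (1 - pe)
  # per-item chance contribution; averages to pe over items and is
  # symmetric in the two categories
  pe_i <- (r1 / r) * (1 - pi1) + (r0 / r) * pi1
  ac1_star <- ac1_i - 2 * (1 - ac1) * (pe_i - pe) / (1 - pe)
  v <- sum((ac1_star - mean(ac1_star))^2) / (n * (n - 1))
  se <- sqrt(v)
  tcrit <- qt(1 - (1 - confidence) / 2, df = n - 1)
  list(ac1 = ac1, se = se,
       ci_low = max(-1, ac1 - tcrit * se),
       ci_high = min(1, ac1 + tcrit * se),
       pa = pa, pe = pe)
}

#' Bland-Altman agreement analysis
#'
#' Bias (mean of the paired differences `a - b`), sample SD of the
#' differences, and the 95% limits of agreement `bias +/- 1.96 * SD`.
#'
#' @param a,b paired per-case measures from the two methods, or `a` a
#'   two-column matrix/data.frame with `b` missing. At least 2 pairs.
#' @param loa_mult limits-of-agreement multiplier (fixed at 1.96 for 95%
#'   limits by default).
#' @return object of class `agreement_report`: list with `bias`, `sd_diff`,
#'   `loa_low`, `loa_high`, `n`.
#' @export
bland_altman <- function(a, b = NULL, loa_mult = 1.96) {
  if (is.null(b)) {
    a <- as.matrix(a)
    stopifnot(ncol(a) == 2L)
    b <- a[, 2L]
    a <- a[, 1L]
  }
  if (length(a) != length(b)) {
    stop("validation error: paired measures have different lengths", call. = FALSE)
  }
  if (length(a) < 2L) {
    stop("validation error: at least 2 pairs required", call. = FALSE)
  }
  d <- a - b
  bias <- mean(d)
  s <- sd(d)
  structure(list(bias = bias, sd_diff = s,
                 loa_low = bias - loa_mult * s, loa_high = bias + loa_mult * s,
                 n = length(d)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> n=%d bias=%.4g LoA=[%.4g, %.4g] (SD %.4g)\n",
              x$n, x$bias, x$loa_low, x$loa_high, x$sd_diff))
  invisible(x)
}

#' Find clusters of consecutive artifact readings
#'
#' Maximal runs of artifact labels of at least `min_size` consecutive
#' readings, in trace order.
#'
#' @param labels a label carrier.
#' @param min_size minimum run length to count as a cluster (default 3).
#' @return `data.frame` with columns `start` (1-based index of the first
#'   reading in the run) and `length`; zero rows when there is no cluster.
#' @examples
#' find_clusters(c(1, 1, 0, 1, 1, 1, 1))  # one cluster: start 4, length 4
#' @export
find_clusters <- function(labels, min_size = 3L) {
  lab <- as_labels(labels)
  if (!length(lab)) {
    return(data.frame(start = integer(), length = integer()))
  }
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- r$values == 1L & r$lengths >= min_size
  data.frame(start = starts[sel], length = r$lengths[sel])
}

#' Leave-one-out jackknife for agreement summaries
#'
#' Recomputes a summary statistic of per-case differences with each case
#' left out in turn, to expose influential cases and estimate the
#' statistic's variance. The jackknife SE is
#' `sqrt((n-1)/n * sum((theta_i - mean(theta))^2))`.
#'
#' @param values per-case differences (numeric, length >= 2; length >= 3 for
#'   the limit statistics, which need a leave-one-out SD).
#' @param statistic `"bias"` (mean), `"loa_low"` or `"loa_high"`
#'   (mean -/+ 1.96 SD).
#' @param influence_threshold absolute deviation of a leave-one-out estimate
#'   from the full-sample estimate beyond which a case is flagged as
#'   influential (default 10% of the full-sample SD of `values`, floored at
#'   `.Machine$double.eps`).
#' @return list with `statistic`, `full` (full-sample estimate),
#'   `estimates` (n leave-one-out estimates), `se` (jackknife SE),
#'   `influential` (logical vector).
#' @examples
#' jackknife_summaries(c(0, 2), "bias")$estimates  # 2, 0
#' @export
jackknife_summaries <- function(values,
                                statistic = c("bias", "loa_low", "loa_high"),
                                influence_threshold = NULL) {
  statistic <- match.arg(statistic)
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2L) stop("validation error: at least 2 cases required", call. = FALSE)
  if (statistic != "bias" && n < 3L) {
    stop("validation error: limit statistics need at least 3 cases", call. = FALSE)
  }
  stat_fn <- switch(statistic,
                    bias = mean,
                    loa_low = function(x) mean(x) - 1.96 * sd(x),
                    loa_high = function(x) mean(x) + 1.96 * sd(x))
  full <- stat_fn(values)
  est <- vapply(seq_len(n), function(i) stat_fn(values[-i]), numeric(1L))
  se <- sqrt((n - 1) / n * sum((est - mean(est))^2))
  if (is.null(influence_threshold)) {
    influence_threshold <- max(0.1 * sd(values), .Machine$double.eps)
  }
  list(statistic = statistic, full = full, estimates = est, se = se,
       influential = abs(est - full) > influence_threshold)
}

#' Design parameters for a Bland-Altman agreement study
#'
#' @param mu_diff expected mean paired difference (measure units).
#' @param sd_diff expected SD of the paired differences.
#' @param delta maximum allowable difference: the agreement limits, with
#'   their confidence bounds, must fall inside `[-delta, +delta]`.
#' @param confidence confidence level of the limits of agreement themselves
#'   (default 0.95, i.e. 1.96-SD limits).
#' @param ci_confidence confidence level of the interval around each limit
#'   (default 0.95).
#' @param power target power (default 0.80).
#' @return object of class `sample_size_spec`.
#' @export
sample_size_spec <- function(mu_diff, sd_diff, delta, confidence = 0.95,
                             ci_confidence = 0.95, power = 0.80) {
  stopifnot(sd_diff > 0, power > 0, power < 1,
            confidence > 0, confidence < 1, ci_confidence > 0, ci_confidence < 1)
  if (delta <= abs(mu_diff)) {
    stop("infeasible design: delta must exceed |mu_diff|", call. = FALSE)
  }
  structure(list(mu_diff = mu_diff, sd_diff = sd_diff, delta = delta,
                 confidence = confidence, ci_confidence = ci_confidence,
                 power = power),
            class = "sample_size_spec")
}

#' Power of a Bland-Altman agreement study at a given sample size
#'
#' Approximate power, after Lu et al., that both limits of agreement --
#' together with their one-sided confidence bounds -- fall within
#' `[-delta, +delta]`. With `z` the limits' normal quantile
#' (`qnorm(1 - (1 - confidence)/2)`) and
#' `se = sd * sqrt(1/n + z^2 / (2(n-1)))`, the power is
#' `pnorm(tau1 - crit) + pnorm(tau2 - crit) - 1` where
#' `tau1 = (delta - mu - z*sd)/se`, `tau2 = (delta + mu - z*sd)/se` and
#' `crit` is the one-sided critical value at `ci_confidence`. Published
#' variants of the method differ in that critical value; the default
#' (`variant = "t"`, a t quantile with `n - 1` df) reproduces the method's
#' worked design instance, while `variant = "z"` uses the normal quantile.
#'
#' @param n sample size (cases), `n >= 3`.
#' @param spec a [sample_size_spec()].
#' @param variant `"t"` (default) or `"z"` critical value for the limits'
#'   confidence bounds.
#' @return power in \[0, 1\] (lower-bounded at 0).
#' @export
ba_agreement_power <- function(n, spec, variant = c("t", "z")) {
  variant <- match.arg(variant)
  stopifnot(inherits(spec, "sample_size_spec"), n >= 3)
  z <- qnorm(1 - (1 - spec$confidence) / 2)
  se <- spec$sd_diff * sqrt(1 / n + z^2 / (2 * (n - 1)))
  crit <- switch(variant,
                 t = qt(spec$ci_confidence, df = n - 1),
                 z = qnorm(spec$ci_confidence))
  tau1 <- (spec$delta - spec$mu_diff - z * spec$sd_diff) / se
  tau2 <- (spec$delta + spec$mu_diff - z * spec$sd_diff) / se
  max(0, pnorm(tau1 - crit) + pnorm(tau2 - crit) - 1)
}

#' Required sample size for a Bland-Altman agreement study
#'
#' Smallest `n` at which [ba_agreement_power()] reaches the target power,
#' found by iterating `n` upward from 3.
#'
#' @inheritParams ba_agreement_power
#' @param n_max search ceiling (default 1e6).
#' @return integer sample size.
#' @examples
#' agreement_sample_size(sample_size_spec(0.2, 1.02, 2.56))  # 147
#' @export
agreement_sample_size <- function(spec, variant = c("t", "z"), n_max = 1e6) {
  variant <- match.arg(variant)
  stopifnot(inherits(spec, "sample_size_spec"))
  z <- qnorm(1 - (1 - spec$confidence) / 2)
  # asymptotic power is 1 iff delta > |mu| + z*sd; otherwise it tops out below
  if (spec$delta <= abs(spec$mu_diff) + z * spec$sd_diff) {
    stop("infeasible design: delta must exceed |mu_diff| + z * sd_diff ",
         sprintf("(= %.4g) for the limits to fit inside it",
                 abs(spec$mu_diff) + z * spec$sd_diff), call. = FALSE)
  }
  n <- 3L
  while (n <= n_max) {
    if (ba_agreement_power(n, spec, variant) >= spec$power) return(n)
    n <- n + 1L
  }
  stop("no n <= n_max reaches the target power", call. = FALSE)
}
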