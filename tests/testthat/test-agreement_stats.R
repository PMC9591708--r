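test_that("majority vote follows the 2-of-3 rule", {
  expect_equal(majority_vote(list(c(1), c(1), c(1))), 1L)
  expect_equal(majority_vote(list(c(1), c(1), c(0))), 1L)
  expect_equal(majority_vote(list(c(1), c(0), c(0))), 0L)
  expect_equal(majority_vote(list(c(1, 1, 0), c(1, 0, 0), c(1, 1, 1))),
               c(1L, 1L, 0L))
  expect_error(majority_vote(list(c(1, 0), c(1, 0, 0), c(0, 0))),
               "unequal lengths")
})

test_that("confusion counts tally every combination", {
  pred <- c(rep(1, 5), rep(0, 15))
  cc <- confusion(pred, pred)
  expect_equal(unclass(cc), list(tp = 5L, fp = 0L, fn = 0L, tn = 15L))

  cc <- confusion(rep(0, 10), c(rep(1, 3), rep(0, 7)))
  expect_equal(cc$fn, 3L)
  expect_equal(cc$tn, 7L)

  cc <- confusion(c(1, 1, 0, 0), c(1, 0, 1, 0))  # all four cells once
  expect_equal(unclass(cc), list(tp = 1L, fp = 1L, fn = 1L, tn = 1L))
  expect_error(confusion(c(1, 0), c(1, 0, 0)), "lengths differ")

  pooled <- pool_confusion(confusion(c(1, 0), c(1, 0)),
                           confusion(c(0, 0), c(1, 0)))
  expect_equal(pooled$tp + pooled$fp + pooled$fn + pooled$tn, 4L)
})

test_that("classification metrics match hand-derived values", {
  m <- classification_metrics(
    structure(list(tp = 1L, fp = 0L, fn = 1L, tn = 8L),
              class = "confusion_counts"))
  expect_equal(m$sensitivity, 0.5, tolerance = 1e-12)
  expect_equal(m$specificity, 1.0)
  expect_equal(m$f_score, 2 / 3, tolerance = 1e-12)

  perfect <- classification_metrics(confusion(c(1, 0, 1), c(1, 0, 1)))
  expect_equal(unlist(perfect[1:4]), c(sensitivity = 1, specificity = 1,
                                       precision = 1, f_score = 1))

  degenerate <- classification_metrics(confusion(c(0, 0), c(0, 0)))
  expect_true(is.na(degenerate$sensitivity))
  expect_match(paste(degenerate$undefined, collapse = ";"), "tp\\+fn")
})

test_that("classification metrics agree with direct recomputation", {
  set.seed(3)
  for (i in 1:50) {
    cc <- structure(as.list(stats::setNames(rpois(4, 8), c("tp", "fp", "fn", "tn"))),
                    class = "confusion_counts")
    m <- classification_metrics(cc)
    with(cc, {
      if (tp + fn > 0) expect_equal(m$sensitivity, tp / (tp + fn))
      if (tn + fp > 0) expect_equal(m$specificity, tn / (tn + fp))
      if (tp + fp > 0 && tp + fn > 0 && tp > 0) {
        p <- tp / (tp + fp); s <- tp / (tp + fn)
        expect_equal(m$f_score, 2 * p * s / (p + s))
      }
    })
  }
})

test_that("artifact rate and its intervals behave", {
  r <- artifact_rate(289, 27683)
  expect_equal(round(r$estimate, 2), 0.01)
  expect_equal(artifact_rate(0, 100)$estimate, 0)
  r <- artifact_rate(50, 100)
  expect_equal(r$estimate, 0.5)
  expect_equal(r$ci_low, 0.5 - qnorm(0.975) * 0.05, tolerance = 1e-12)
  expect_equal(r$ci_high, 0.5 + qnorm(0.975) * 0.05, tolerance = 1e-12)
  w <- artifact_rate(50, 100, method = "wilson")
  expect_lt(w$ci_low, 0.5)
  expect_gt(w$ci_high, 0.5)
  expect_error(artifact_rate(5, 0), "n_total")
  expect_error(artifact_rate(11, 10), "n_artifacts")
})

test_that("Gwet AC1 matches hand-computed values", {
  # perfect agreement with mixed categories
  m <- cbind(c(1, 0, 0, 1, 0), c(1, 0, 0, 1, 0), c(1, 0, 0, 1, 0))
  expect_equal(gwet_ac1(m)$ac1, 1)

  # 3 raters, 10 items: unanimous "valid" on 9, split 2-1 on one.
  # Pa = (9 + 1/3)/10 = 14/15; pi = 1/30; Pe = 2*(1/30)*(29/30) = 29/450;
  # AC1 = (14/15 - 29/450) / (1 - 29/450) = 391/421.
  m <- rbind(matrix(0L, 9, 3), c(1L, 0L, 0L))
  g <- gwet_ac1(m)
  expect_equal(g$ac1, 391 / 421, tolerance = 1e-10)
  expect_equal(g$pa, 14 / 15, tolerance = 1e-12)
  expect_equal(g$pe, 29 / 450, tolerance = 1e-12)
  expect_gt(g$se, 0)
  expect_lte(g$ci_high, 1)

  # two raters who always disagree: Pa = 0, prevalence 1/2 -> AC1 = -1
  m <- cbind(c(1, 0), c(0, 1))
  g <- gwet_ac1(m)
  expect_equal(g$pa, 0)
  expect_lt(g$ac1, 0)
  expect_equal(g$ac1, -1)

  expect_error(gwet_ac1(cbind(c(1, 0))), "2 raters")
  expect_error(gwet_ac1(rbind(c(1, 0))), "2 items")
})

test_that("AC1 is invariant to swapping the two categories", {
  set.seed(5)
  for (i in 1:20) {
    m <- matrix(rbinom(60, 1, runif(1, 0.05, 0.95)), ncol = 3)
    g <- gwet_ac1(m)
    g_swap <- gwet_ac1(1L - m)
    expect_equal(g_swap$ac1, g$ac1, tolerance = 1e-12)
    expect_equal(g_swap$se, g$se, tolerance = 1e-12)
  }
})

test_that("Bland-Altman matches hand computation and is equivariant", {
  r <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(c(r$bias, r$loa_low, r$loa_high), c(0, 0, 0))

  r <- bland_altman(c(1, 2, 3), c(1, 2, 3) + 0.7)
  expect_equal(r$bias, -0.7, tolerance = 1e-12)
  expect_equal(r$loa_low, -0.7)
  expect_equal(r$loa_high, -0.7)

  r <- bland_altman(c(-1, 1), c(0, 0))
  expect_equal(r$bias, 0)
  expect_equal(r$sd_diff, sqrt(2), tolerance = 1e-12)
  expect_equal(r$loa_high, 1.96 * sqrt(2), tolerance = 1e-12)

  expect_error(bland_altman(1, 1), "at least 2 pairs")

  set.seed(9)
  a <- rnorm(20); b <- rnorm(20); k <- 3.2
  r0 <- bland_altman(a, b)
  r1 <- bland_altman(a + k, b)
  expect_equal(r1$bias, r0$bias + k, tolerance = 1e-12)
  expect_equal(r1$loa_low, r0$loa_low + k, tolerance = 1e-12)
  expect_equal(r1$loa_high, r0$loa_high + k, tolerance = 1e-12)

  # matrix input form
  expect_equal(bland_altman(cbind(a, b)), r0)
})

test_that("find_clusters returns maximal qualifying runs", {
  expect_equal(find_clusters(c(1, 1, 1)), data.frame(start = 1L, length = 3L))
  expect_equal(find_clusters(c(1, 1, 0, 1, 1, 1, 1)),
               data.frame(start = 4L, length = 4L))
  expect_equal(nrow(find_clusters(rep(0, 10))), 0)
  expect_equal(nrow(find_clusters(integer())), 0)

  set.seed(13)
  for (i in 1:30) {
    lab <- rbinom(sample(5:60, 1), 1, 0.4)
    cl <- find_clusters(lab)
    if (nrow(cl)) {
      for (j in seq_len(nrow(cl))) {
        s <- cl$start[j]; len <- cl$length[j]
        expect_true(all(lab[s:(s + len - 1)] == 1))       # all artifact
        if (s > 1) expect_equal(lab[s - 1], 0)            # maximal left
        if (s + len <= length(lab)) expect_equal(lab[s + len], 0)  # right
      }
      expect_false(is.unsorted(cl$start))
      expect_true(all(diff(cl$start) > head(cl$length, -1)))  # disjoint
    }
    # coverage: flagged readings inside qualifying runs are exactly counted
    r <- rle(lab)
    expect_equal(sum(cl$length), sum(r$lengths[r$values == 1 & r$lengths >= 3]))
  }
})

test_that("jackknife summaries expose influence and variance", {
  j <- jackknife_summaries(rep(2.5, 6), "bias")
  expect_equal(j$estimates, rep(2.5, 6))
  expect_equal(j$se, 0)
  expect_false(any(j$influential))

  j <- jackknife_summaries(c(0, 2), "bias")
  expect_equal(j$estimates, c(2, 0))

  vals <- rnorm(17)
  expect_length(jackknife_summaries(vals, "bias")$estimates, 17)

  # limit statistics recompute mean +/- 1.96 sd without case i
  j <- jackknife_summaries(c(0, 1, 2, 5), "loa_high")
  expect_equal(j$estimates[4], mean(c(0, 1, 2)) + 1.96 * sd(c(0, 1, 2)),
               tolerance = 1e-12)
  expect_gt(j$se, 0)

  expect_error(jackknife_summaries(1, "bias"), "at least 2")
  expect_error(jackknife_summaries(c(1, 2), "loa_low"), "at least 3")
})

test_that("agreement sample size reproduces the design instance", {
  spec <- sample_size_spec(0.2, 1.02, 2.56)
  expect_equal(agreement_sample_size(spec), 147)
  # the returned n is minimal: power crosses the target exactly there
  expect_lt(ba_agreement_power(146, spec), 0.8)
  expect_gte(ba_agreement_power(147, spec), 0.8)
})

test_that("agreement sample size is monotone and guards infeasibility", {
  base <- sample_size_spec(0.2, 1.02, 2.56)
  n_base <- agreement_sample_size(base)
  expect_lt(agreement_sample_size(sample_size_spec(0.2, 1.02, 2 * 2.56)),
            n_base)
  expect_gte(agreement_sample_size(sample_size_spec(0.2, 1.02, 2.56,
                                                    power = 0.9)), n_base)
  expect_gte(agreement_sample_size(sample_size_spec(0.2, 1.3, 2.56 * 1.5)),
             agreement_sample_size(sample_size_spec(0.2, 1.02, 2.56 * 1.5)))
  expect_error(sample_size_spec(0.2, 1.02, 0.1), "infeasible")
  # delta above |mu| but inside the limits themselves: no n can ever work
  expect_error(agreement_sample_size(sample_size_spec(0.2, 1.02, 1.5)),
               "infeasible")
  # variant choice is exposed; the normal variant gives a nearby n
  expect_lte(abs(agreement_sample_size(base, variant = "z") - n_base), 2)
})
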