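test_that("response scoring is exact-set membership after normalisation", {
  key <- answer_key(list(lbbb = list(
    canonical = "left bundle branch block",
    accepted = c("left bundle branch", "LBBB"))))
  expect_true(score_response("LBBB", key$lbbb))
  expect_true(score_response("  left Bundle  branch ", key$lbbb))
  expect_false(score_response("bundle branch block", key$lbbb))
  af <- answer_key(list(af = list(canonical = "atrial fibrillation",
                                  accepted = "AF")))
  expect_false(score_response("arrhythmia", af$af))
  expect_false(score_response("SVT", af$af))
  expect_false(score_response("", af$af))
  expect_true(score_response("af", af$af))
})

test_that("mcnemar matches the corrected formula on all small tables", {
  expect_equal(mcnemar_test(1, 8)$chi2, 4.0)     # (|1-8|-1)^2 / 9
  expect_equal(mcnemar_test(1, 8)$df, 1L)
  sym <- mcnemar_test(3, 3)
  expect_equal(sym$chi2, 0)                      # floored correction
  expect_equal(sym$p, 1)
  expect_error(mcnemar_test(0, 0), "undefined")
  # exhaustive small-instance oracle: independent evaluation of the
  # continuity-corrected statistic and its chi-square tail
  for (b in 0:10) for (c in 0:10) {
    if (b + c == 0) next
    res <- mcnemar_test(b, c)
    chi <- (max(abs(b - c) - 1, 0))^2 / (b + c)
    expect_equal(res$chi2, chi)
    expect_equal(res$p, 1 - pchisq(chi, 1), tolerance = 1e-12)
  }
})

test_that("wilcoxon signed-rank matches enumeration on small samples", {
  res <- wilcoxon_signed_rank(c(2, 4, 6), c(1, 2, 3))  # diffs 1, 2, 3
  expect_equal(res$V, 6)
  expect_equal(res$p, 0.25)
  expect_error(wilcoxon_signed_rank(1:4, 1:4), "undefined")

  set.seed(17)
  for (i in 1:25) {
    n <- sample(3:10, 1)
    x <- round(rnorm(n, 0, 3), 3)
    y <- round(rnorm(n, 0, 3), 3)
    if (all(x == y)) next
    res <- wilcoxon_signed_rank(x, y)
    ora <- oracle_signed_rank(x, y)
    expect_equal(res$V, ora$V)
    d <- (x - y)[x != y]
    if (!anyDuplicated(abs(d))) {
      # tie-free: exact signed-rank p must equal full enumeration
      expect_equal(res$p, ora$p, tolerance = 1e-10,
                   label = sprintf("instance %d p", i))
    } else {
      ref <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                                 exact = FALSE))
      expect_equal(res$p, ref$p.value, tolerance = 1e-10)
    }
    # negating all differences reflects V and preserves p
    neg <- wilcoxon_signed_rank(y, x)
    expect_equal(neg$V, res$n * (res$n + 1) / 2 - res$V)
    expect_equal(neg$p, res$p, tolerance = 1e-12)
  }
})

test_that("wilcoxon agrees with the reference implementation", {
  set.seed(23)
  # exact path
  x <- rnorm(12); y <- rnorm(12)
  ours <- wilcoxon_signed_rank(x, y)
  ref <- stats::wilcox.test(x, y, paired = TRUE)
  expect_equal(ours$V, unname(ref$statistic))
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  # tied/normal-approximation path
  xt <- c(1, 2, 2, 5, 7, 7, 9, 12, 15, 3)
  yt <- c(2, 1, 4, 2, 6, 9, 4, 6, 9, 3.5)
  ours2 <- wilcoxon_signed_rank(xt, yt)
  ref2 <- suppressWarnings(stats::wilcox.test(xt, yt, paired = TRUE,
                                              exact = FALSE, correct = TRUE))
  expect_equal(ours2$V, unname(ref2$statistic))
  expect_equal(ours2$p, ref2$p.value, tolerance = 1e-12)
})

test_that("bonferroni thresholds divide alpha by the test count", {
  expect_equal(bonferroni_alpha(0.05, 9), 0.05 / 9)
  expect_equal(round(bonferroni_alpha(0.05, 9), 3), 0.006)
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_equal(bonferroni_alpha(0.05, 10), 0.005)
  expect_error(bonferroni_alpha(0.05, 0))
})

test_that("study-level accuracy and fixation tables assemble per stimulus", {
  acc <- matrix(c(1, 0), 2, 3)    # group 1 always right, group 2 never
  sc <- simulation_scenario(n_per_group = c(4L, 4L), n_stimuli = 3L,
                            fixations_mean = 10, accuracy = acc, seed = 2L)
  sim <- simulate_study(sc)
  scored <- score_responses(sim$dataset, sc$answer_key)
  agg <- aggregate(correct ~ participant, scored, mean)
  og <- sim$dataset$participants
  expect_true(all(agg$correct[og$order_group == "history_first"] == 1))
  expect_true(all(agg$correct[og$order_group == "history_last"] == 0))
  summ <- accuracy_summary(sim$dataset, sc$answer_key)
  expect_true(all(summ$pct_correct %in% c(0, 100)))

  at <- accuracy_table(sim$dataset, sc$answer_key)
  expect_equal(at$stimulus, paste0("ecg", 1:3))
  expect_true(all(is.na(at$p)))   # no discordant pairs in this scenario
  fm <- fixation_metric_table(sim$dataset)
  expect_equal(nrow(fm), 3L)
  expect_true(all(c("count_V", "count_p", "duration_V", "duration_p") %in%
                    names(fm)))
  expect_true(all(fm$n == 8L))
})
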