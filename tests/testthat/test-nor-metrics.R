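test_that("binning conserves exploration time and saturates at the bin width", {
  # 120 consecutive true frames at 2 fps inside one bin -> 60 s
  s <- make_series(c(rep(TRUE, 120), rep(FALSE, 120)))
  b <- bin_series(s)
  expect_equal(b$left_s[1], 60)
  expect_equal(b$left_s[2], 0)
  # all-false -> all-zero bins
  expect_true(all(bin_series(make_series(rep(FALSE, 240)))$left_s == 0))
  # conservation for an arbitrary series
  set.seed(4)
  s <- make_series(runif(500) < 0.3, runif(500) < 0.2 & !(runif(500) < 0.3))
  s$explore_right <- s$explore_right & !s$explore_left
  b <- bin_series(s)
  expect_equal(sum(b$left_s), 0.5 * sum(s$explore_left))
  expect_equal(sum(b$right_s), 0.5 * sum(s$explore_right))
  expect_error(bin_series(s, bin_width_s = 60.25), "multiple")
})

test_that("display smoothing preserves mass shape and constants", {
  # impulse: kernel-shaped, symmetric, positive
  x <- c(rep(0, 20), 1, rep(0, 20))
  sm <- smooth_for_display(x, sigma_bins = 4)
  expect_equal(which.max(sm), 21)
  expect_equal(sm[21 - 3], sm[21 + 3])
  # constant input is preserved exactly (edge renormalization)
  expect_equal(smooth_for_display(rep(2.5, 30)), rep(2.5, 30))
  # sigma -> 0 approaches identity
  expect_equal(smooth_for_display(x, sigma_bins = 1e-6), x, tolerance = 1e-6)
})

test_that("discrimination index matches its closed form and flags 0/0", {
  expect_equal(discrimination_index(167, 100), 67 / 267)
  expect_equal(discrimination_index(5, 5), 0)
  expect_equal(discrimination_index(3, 0), 1)
  expect_true(is.na(discrimination_index(0, 0)))
  expect_error(discrimination_index(-1, 2), "non-negative")
  # antisymmetry and range, property-style
  set.seed(7)
  a <- runif(200, 0, 100); b <- runif(200, 0, 100)
  expect_equal(discrimination_index(a, b), -discrimination_index(b, a))
  expect_true(all(abs(discrimination_index(a, b)) <= 1))
})

test_that("analysis windows start at the first test interaction and clip", {
  sched <- phase_schedule(c(habituation = 100, sample = 600,
                            retention = 100, test = 2000))
  n <- 2800 * 2
  left <- rep(FALSE, n)
  left[(885) * 2 + 1] <- TRUE  # first test exploration at phase start + 85 s
  s <- make_series(left)
  w <- analysis_windows(sched, s)
  expect_equal(w$sample, c(100, 700))
  expect_equal(w$test, c(885, 2085))
  expect_equal(w$test_first_s, 885)
  # windows are a pure function of (schedule, series)
  expect_identical(w, analysis_windows(sched, s))
  # no exploration in test -> undefined flag
  w0 <- analysis_windows(sched, make_series(rep(FALSE, n)))
  expect_false(w0$test_defined)
  expect_true(is.na(w0$test_first_s))
  # first interaction close to phase end -> clipped window
  left2 <- rep(FALSE, n)
  left2[(2700) * 2 + 1] <- TRUE
  w2 <- analysis_windows(sched, make_series(left2))
  expect_equal(w2$test, c(2700, 2800))
})

test_that("relative DI is the paired difference with propagated flags", {
  expect_equal(relative_di(0.296, 0.013), 0.283)
  expect_equal(relative_di(0.4, 0.4), 0)
  expect_equal(relative_di(1, -1), 2)
  expect_true(is.na(relative_di(NA_real_, 0.2)))
})

test_that("latency and binned peak follow the phase structure", {
  sched <- phase_schedule(c(habituation = 60, sample = 300,
                            retention = 60, test = 300))
  n <- 720 * 2
  left <- rep(FALSE, n)
  # single bout starting 30 s into the sample phase
  left[(90 * 2 + 1):(90 * 2 + 10)] <- TRUE
  lp <- latency_and_peak(make_series(left), sched, "sample")
  expect_equal(lp$latency_s, 30)
  expect_equal(lp$peak_bin_s, 5)
  # no exploration: flagged latency, zero peak
  lp0 <- latency_and_peak(make_series(rep(FALSE, n)), sched, "retention")
  expect_true(is.na(lp0$latency_s))
  expect_equal(lp0$peak_bin_s, 0)
})

test_that("sample-phase peak exceeds retention-phase peak in cohorts", {
  cohort <- sim_cohort(8, seed0 = 600)
  peaks <- vapply(cohort, function(s) {
    c(sample = latency_and_peak(s$labels, s$schedule, "sample")$peak_bin_s,
      retention = latency_and_peak(s$labels, s$schedule, "retention")$peak_bin_s)
  }, c(sample = 0, retention = 0))
  expect_gt(mean(peaks["sample", ]), mean(peaks["retention", ]))
  tt <- paired_t(peaks["sample", ], peaks["retention", ])
  expect_gt(tt$statistic, 0)
})

test_that("first-approach proportions and exact binomial tests are correct", {
  cohort <- sim_cohort(10, seed0 = 800)
  fa <- first_approach(cohort, phase = "test")
  expect_true(all(fa$first_side %in% c("novel", "familiar", NA)))
  expect_equal(fa$proportion, fa$n_novel / fa$n_total)
  # binomial oracle values: tail sums of the symmetric binomial
  expect_equal(exact_binomial(15, 19)$p_value, 5036 / 524288, tolerance = 1e-12)
  expect_equal(exact_binomial(10, 20)$p_value,
               0.5 + choose(20, 10) / 2^21, tolerance = 1e-12)
  expect_equal(exact_binomial(14, 20)$statistic, 0.70)
})

test_that("novel-side exploration bias makes novel-first approaches dominate", {
  cohort <- sim_cohort(20, seed0 = 900)
  fa <- first_approach(cohort, phase = "test")
  # generator law: P(first bout on novel side) = f / (1 + f) = 0.625
  expect_gt(fa$proportion, 0.5)
})

test_that("sample-exploration vs relative-DI correlation behaves", {
  # collinear points -> r = 1
  sc <- data.frame(t_novel_sample_s = c(1, 2, 3),
                   t_familiar_sample_s = c(1, 1, 1),
                   relative_di = c(2, 4, 6))
  expect_equal(sample_vs_relative_di_correlation(sc, "novel")$r, 1)
  # constructed negative dependence: fast encoders recognize less
  set.seed(11)
  t_nov <- runif(30, 10, 100)
  sc2 <- data.frame(t_novel_sample_s = t_nov,
                    t_familiar_sample_s = runif(30, 10, 100),
                    relative_di = 0.5 - 0.004 * t_nov + rnorm(30, 0, 0.05))
  r <- sample_vs_relative_di_correlation(sc2, "novel")
  expect_lt(r$r, 0)
  expect_lt(r$p_value, 0.05)
  # zero variance flags
  sc3 <- data.frame(t_novel_sample_s = rep(2, 5),
                    t_familiar_sample_s = 1:5, relative_di = 1:5 / 10)
  expect_true(sample_vs_relative_di_correlation(sc3, "novel")$flagged)
})

test_that("statistical wrappers match closed forms", {
  # paired differences 1,2,3: t = mean/ (sd/sqrt(3)) = 3.464, df 2
  tt <- paired_t(c(2, 4, 6), c(1, 2, 3))
  expect_equal(tt$statistic, 2 / (1 / sqrt(3)), tolerance = 1e-6)
  expect_equal(tt$df, 2)
  # BH step-up on 0.01..0.04 -> all 0.04
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  # degenerate inputs flag instead of erroring
  expect_true(one_sample_t(c(1, 1, 1))$flagged)
  expect_true(shapiro_wilk(c(1, 2))$flagged)
  expect_false(shapiro_wilk(rnorm(20))$flagged)
})

test_that("three-way ANOVA isolates a single-factor effect in a balanced design", {
  design <- expand.grid(facility = c("A", "B"), object = c("wood", "metal"),
                        side = c("left", "right"), rep = 1:5)
  set.seed(21)
  design$value <- ifelse(design$side == "right", 10, 0) + rnorm(nrow(design), 0, 0.5)
  tab <- three_way_anova(design)
  f_side <- tab$F[tab$term == "side"]
  others <- tab$F[!tab$term %in% c("side", "Residuals")]
  expect_gt(f_side, 100)
  expect_true(all(others < f_side / 20, na.rm = TRUE))
})
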