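test_that("dwell heatmap conserves tracked time and finds the nest", {
  s <- default_session()
  lay <- s$truth_params$layout
  hm <- dwell_heatmap(s$keypoints, lay, schedule = s$schedule)
  w_s <- phase_window(s$schedule, "sample")
  w_r <- phase_window(s$schedule, "retention")
  n_frames <- sum((s$keypoints$time_s >= w_s["start"] & s$keypoints$time_s < w_s["end"]) |
                  (s$keypoints$time_s >= w_r["start"] & s$keypoints$time_s < w_r["end"]))
  expect_equal(sum(hm$seconds), n_frames / 2)
  # argmax within one grid cell of the configured nest
  expect_lt(abs(hm$argmax_px[["x"]] - s$truth_params$nest_position[1]), 2 * lay$px_per_cm)
  expect_lt(abs(hm$argmax_px[["y"]] - s$truth_params$nest_position[2]), 2 * lay$px_per_cm)
  expect_error(dwell_heatmap(s$keypoints[0, ], lay), "empty")
})

test_that("a stationary track concentrates all time in one cell", {
  s <- default_session()
  tr <- s$keypoints[1:100, , drop = FALSE]
  for (cn in grep("\\.(x)$", names(tr), value = TRUE)) tr[[cn]] <- 50
  for (cn in grep("\\.(y)$", names(tr), value = TRUE)) tr[[cn]] <- 60
  attr(tr, "frame_rate") <- 2
  class(tr) <- class(s$keypoints)
  hm <- dwell_heatmap(tr, s$truth_params$layout)
  expect_equal(max(hm$seconds), 50)
  expect_equal(sum(hm$seconds > 0), 1)
})

test_that("nest-side grouping recovers constructed groups and handles edge cases", {
  lay <- cage_layout()
  set.seed(3)
  nests <- data.frame(
    d_left_cm = c(runif(5, 2, 6), runif(5, 28, 34)),
    d_right_cm = c(runif(5, 28, 34), runif(5, 2, 6))
  )
  g <- assign_nest_sides(nests, seed = 1)
  expect_equal(as.vector(g), rep(c("left", "right"), each = 5))
  expect_equal(attr(g, "method"), "kmeans")
  # permutation invariance over mice
  perm <- sample(10)
  g2 <- assign_nest_sides(nests[perm, ], seed = 1)
  expect_equal(as.vector(g2), as.vector(g)[perm])
  # single mouse: nearest-object fallback
  g1 <- assign_nest_sides(nests[1, , drop = FALSE])
  expect_equal(as.vector(g1), "left")
  expect_equal(attr(g1, "method"), "nearest")
  # identical nests: fallback with warning
  same <- data.frame(d_left_cm = rep(10, 4), d_right_cm = rep(20, 4))
  expect_warning(gs <- assign_nest_sides(same), "degenerate")
  expect_equal(as.vector(gs), rep("left", 4))
  # exact equidistance breaks to the left
  tie <- data.frame(d_left_cm = c(15, 5), d_right_cm = c(15, 30))
  expect_warning(gt <- assign_nest_sides(tie), "degenerate")
  expect_equal(as.vector(gt)[1], "left")
})

test_that("nest-side coupling produces a right-object bias and only that", {
  lay <- cage_layout()
  mk <- function(i, nest_x) simulate_session(session_sim_config(
    phase_durations = c(habituation = 300, sample = 3600,
                        retention = 600, test = 1800),
    seed = 4000 + i, nest_position = c(nest_x, 30), right_nest_boost = 4))
  cohort <- c(lapply(1:6, mk, nest_x = 40), lapply(7:12, mk, nest_x = 160))
  expl <- do.call(rbind, lapply(cohort, function(s) {
    sel <- s$labels$time_s >= 300 & s$labels$time_s < 3900
    data.frame(left_min = sum(s$labels$explore_left[sel]) / 2 / 60,
               right_min = sum(s$labels$explore_right[sel]) / 2 / 60)
  }))
  nests <- do.call(rbind, lapply(cohort, function(s) {
    nest_from_heatmap(dwell_heatmap(s$keypoints, lay, schedule = s$schedule), lay)
  }))
  g <- assign_nest_sides(nests, seed = 1)
  expect_equal(as.vector(g), rep(c("left", "right"), each = 6))
  res <- nest_bias_test(expl, g)
  right_row <- res[res$object_side == "right", ]
  left_row <- res[res$object_side == "left", ]
  expect_lt(right_row$p_adjusted, 0.05)
  expect_gt(right_row$mean_nest_right, right_row$mean_nest_left)
  expect_gt(left_row$p_adjusted, 0.05)
  # identical group values -> zero difference, flagged t
  same <- data.frame(left_min = rep(2, 4), right_min = rep(3, 4))
  res0 <- nest_bias_test(same, c("left", "left", "right", "right"))
  expect_equal(res0$mean_nest_left, res0$mean_nest_right)
})

test_that("coupling off rarely produces significant nest-bias calls", {
  lay <- cage_layout()
  n_sig <- 0L
  for (k in 1:8) {
    cohort <- c(
      lapply(1:4, function(i) simulate_session(short_cfg(
        seed = 5000 + 20 * k + i, nest_position = c(40, 30)))),
      lapply(5:8, function(i) simulate_session(short_cfg(
        seed = 5000 + 20 * k + i, nest_position = c(160, 30)))))
    expl <- do.call(rbind, lapply(cohort, function(s) {
      w <- phase_window(s$schedule, "sample")
      sel <- s$labels$time_s >= w["start"] & s$labels$time_s < w["end"]
      data.frame(left_min = sum(s$labels$explore_left[sel]) / 2 / 60,
                 right_min = sum(s$labels$explore_right[sel]) / 2 / 60)
    }))
    g <- rep(c("left", "right"), each = 4)
    res <- nest_bias_test(expl, g)
    if (any(res$p_adjusted < 0.05, na.rm = TRUE)) n_sig <- n_sig + 1L
  }
  expect_lte(n_sig, 2L)
})

test_that("corridor scores code same/opposite-side first exploration", {
  visits <- data.frame(side = c("left", "right", "left"),
                       exit_time_s = c(0, 100, 200))
  bouts <- data.frame(side = c("left", "right", "right"),
                      start_s = c(10, 50, 150), end_s = c(12, 52, 152),
                      duration_s = c(2, 2, 2))
  cs <- corridor_scores(visits, bouts)
  # interval 1: first bout left after left exit -> 0 (the bout at 50 is later)
  # interval 2: right bout after right exit -> 0; interval 3: no bout -> skipped
  expect_equal(cs$scores$score, c(0, 0))
  expect_equal(cs$n, 2)
  # always-opposite gives mean 1
  bouts_opp <- data.frame(side = c("right", "left"), start_s = c(10, 150),
                          end_s = c(12, 152), duration_s = c(2, 2))
  expect_equal(corridor_scores(visits, bouts_opp)$mean_score, 1)
  # no qualifying interval flags
  expect_true(corridor_scores(visits, bouts[0, ])$flagged)
})

test_that("corridor coupling extremes and the neutral setting behave", {
  # coupling = 1: always same side -> scores all 0
  s1 <- simulate_session(short_cfg(seed = 21, corridor_side_coupling = 1,
                                   corridor_visit_rate = 0.02))
  cs1 <- corridor_scores(s1$events$corridor_visits, segment_bouts(s1$labels),
                         s1$schedule)
  expect_equal(cs1$mean_score, 0)
  # coupling = 0: always opposite -> scores all 1
  s0 <- simulate_session(short_cfg(seed = 22, corridor_side_coupling = 0,
                                   corridor_visit_rate = 0.02))
  cs0 <- corridor_scores(s0$events$corridor_visits, segment_bouts(s0$labels),
                         s0$schedule)
  expect_equal(cs0$mean_score, 1)
  # neutral coupling: cohort mean within 3 SE of 0.5
  cohort <- sim_cohort(8, seed0 = 7000, corridor_visit_rate = 0.02)
  scores <- unlist(lapply(cohort, function(s) {
    corridor_scores(s$events$corridor_visits, segment_bouts(s$labels),
                    s$schedule)$scores$score
  }))
  se <- sd(scores) / sqrt(length(scores))
  expect_lt(abs(mean(scores) - 0.5), 3 * se)
})

test_that("corridor scoring is invariant to mirror-flipping the cage", {
  s <- default_session()
  cs <- corridor_scores(s$events$corridor_visits, segment_bouts(s$labels),
                        s$schedule)
  flip <- function(x) ifelse(x == "left", "right", "left")
  visits_m <- s$events$corridor_visits
  visits_m$side <- flip(visits_m$side)
  bouts_m <- segment_bouts(s$labels)
  bouts_m$side <- flip(bouts_m$side)
  cs_m <- corridor_scores(visits_m, bouts_m, s$schedule)
  expect_equal(cs_m$scores$score, cs$scores$score)
})
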