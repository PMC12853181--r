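#' Bin an exploration series into fixed-width time bins
#'
#' Groups exploratory frames into bins (default 1 min) and reports seconds
#' explored per side per bin. Binning conserves total exploration time:
#' the bin sums equal the true-frame counts times the frame period.
#'
#' @param series an `exploration_series` data frame.
#' @param bin_width_s bin width in seconds; must be a multiple of the frame
#'   period.
#' @return a `binned_exploration` data frame: `bin_start_s`, `left_s`,
#'   `right_s`.
#' @export
bin_series <- function(series, bin_width_s = 60) {
  fr <- attr(series, "frame_rate") %||% infer_frame_rate(series$time_s)
  dt <- 1 / fr
  if (abs(bin_width_s / dt - round(bin_width_s / dt)) > 1e-9)
    stop("bin width must be a multiple of the frame period")
  bin <- floor(series$time_s / bin_width_s) * bin_width_s
  agg <- function(flag) {
    x <- tapply(flag, bin, sum) * dt
    x[is.na(x)] <- 0
    x
  }
  l <- agg(series$explore_left)
  r <- agg(series$explore_right)
  out <- data.frame(bin_start_s = as.numeric(names(l)),
                    left_s = as.numeric(l), right_s = as.numeric(r))
  out <- out[order(out$bin_start_s), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "bin_width_s") <- bin_width_s
  class(out) <- c("binned_exploration", "data.frame")
  out
}

#' Gaussian smoothing of binned time courses (display only)
#'
#' Convolves a binned exploration curve with a discrete Gaussian kernel
#' (default sigma = 4 bins), truncated at +/- 4 sigma and renormalized at the
#' edges so a constant input is preserved. Smoothed values are for plotting
#' only; all statistics are computed on unsmoothed bins.
#'
#' @param x numeric vector of per-bin values.
#' @param sigma_bins kernel standard deviation in bins (> 0).
#' @return numeric vector, same length as `x`.
#' @export
smooth_for_display <- function(x, sigma_bins = 4) {
  if (sigma_bins <= 0) stop("sigma must be positive")
  half <- max(1L, ceiling(4 * sigma_bins))
  k <- exp(-(-half:half)^2 / (2 * sigma_bins^2))
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- max(1, i - half):min(n, i + half)
    w <- k[j - i + half + 1]
    out[i] <- sum(x[j] * w) / sum(w)
  }
  out
}

#' Discrimination index
#'
#' `(t_a - t_b) / (t_a + t_b)`: +1 means exclusive exploration of the first
#' object, 0 equal exploration, -1 exclusive exploration of the second. With
#' novel time first this is the NOR discrimination index; a ~67% increase in
#' novel-object exploration (factor 1.67) corresponds to DI = 0.25.
#' Returns `NA` (flagged undefined) when both times are zero.
#'
#' @param t_a_s,t_b_s exploration times in seconds (vectorized, >= 0).
#' @return numeric in `[-1, 1]`, `NA` on 0/0.
#' @examples
#' discrimination_index(167, 100)  # 0.2509
#' @export
discrimination_index <- function(t_a_s, t_b_s) {
  if (any(t_a_s < 0, na.rm = TRUE) || any(t_b_s < 0, na.rm = TRUE))
    stop("exploration times must be non-negative")
  tot <- t_a_s + t_b_s
  ifelse(tot > 0, (t_a_s - t_b_s) / tot, NA_real_)
}

#' Analysis windows for the sample and test phases
#'
#' The sample-phase DI uses the entire sample phase. The test-phase DI uses
#' the first 20 minutes from the animal's first interaction with either
#' object in the test phase (clipped at the phase end), where most
#' exploration occurs. Windows are half-open `[start, end)`.
#'
#' @param schedule a [phase_schedule()].
#' @param series an `exploration_series` covering the session.
#' @param test_window_s test-window length from first interaction (default
#'   1200 s).
#' @return list with `sample = c(start, end)`, `test = c(start, end)` (or
#'   `NULL` with `test_defined = FALSE` when the test phase has no
#'   exploration), and `test_first_s`.
#' @export
analysis_windows <- function(schedule, series, test_window_s = 1200) {
  sw <- phase_window(schedule, "sample")
  tw <- phase_window(schedule, "test")
  in_test <- series$time_s >= tw["start"] & series$time_s < tw["end"]
  any_exp <- series$explore_left | series$explore_right
  first <- series$time_s[in_test & any_exp]
  if (!length(first)) {
    return(list(sample = unname(sw), test = NULL,
                test_defined = FALSE, test_first_s = NA_real_))
  }
  t0 <- min(first)
  list(sample = unname(sw),
       test = c(t0, min(t0 + test_window_s, tw["end"])),
       test_defined = TRUE, test_first_s = t0)
}

window_times <- function(series, window, fr) {
  sel <- series$time_s >= window[1] & series$time_s < window[2]
  c(left = sum(series$explore_left[sel]) / fr,
    right = sum(series$explore_right[sel]) / fr)
}

#' Per-phase discrimination indices for one animal
#'
#' Computes novel/familiar exploration times and DIs in the sample window
#' (full phase; "novel" and "familiar" mean the side where the novel or
#' familiar object will subsequently appear in the test phase) and in the
#' 20-min test window, plus the relative (paired) DI, test minus sample.
#'
#' @param series an `exploration_series`.
#' @param schedule a [phase_schedule()].
#' @param test_window_s see [analysis_windows()].
#' @return one-row data frame: `t_novel_sample_s`, `t_familiar_sample_s`,
#'   `di_sample`, `t_novel_test_s`, `t_familiar_test_s`, `di_test`,
#'   `relative_di`, `test_first_s`, plus side-based DIs `di_side_sample`,
#'   `di_side_test` (left minus right, novelty ignored).
#' @export
score_session <- function(series, schedule, test_window_s = 1200) {
  fr <- attr(series, "frame_rate") %||% infer_frame_rate(series$time_s)
  win <- analysis_windows(schedule, series, test_window_s)
  nov <- schedule$novel_side
  pick <- function(tt) {
    if (nov == "left") c(tt[["left"]], tt[["right"]]) else c(tt[["right"]], tt[["left"]])
  }
  ts <- window_times(series, win$sample, fr)
  s_nf <- pick(ts)
  di_sample <- discrimination_index(s_nf[1], s_nf[2])
  if (win$test_defined) {
    tt <- window_times(series, win$test, fr)
    t_nf <- pick(tt)
    di_test <- discrimination_index(t_nf[1], t_nf[2])
    di_side_test <- discrimination_index(tt[["left"]], tt[["right"]])
  } else {
    t_nf <- c(NA_real_, NA_real_); di_test <- NA_real_; di_side_test <- NA_real_
  }
  data.frame(
    t_novel_sample_s = s_nf[1], t_familiar_sample_s = s_nf[2],
    di_sample = di_sample,
    t_novel_test_s = t_nf[1], t_familiar_test_s = t_nf[2],
    di_test = di_test,
    relative_di = relative_di(di_test, di_sample),
    test_first_s = win$test_first_s,
    di_side_sample = discrimination_index(ts[["left"]], ts[["right"]]),
    di_side_test = di_side_test
  )
}

#' Relative (paired) discrimination index
#'
#' `di_test - di_sample` for the same animal, in `[-2, 2]`. Pairing the two
#' phases cancels stable side preferences and other per-animal biases, which
#' is why this is the headline recognition measure. Undefined inputs
#' propagate as `NA`.
#'
#' @param di_test,di_sample discrimination indices.
#' @return numeric.
#' @export
relative_di <- function(di_test, di_sample) di_test - di_sample

#' Latency to first exploration and peak binned exploration in a phase
#'
#' Latency is the time from the phase start (the object change) to the first
#' exploratory frame on either side; the peak is the maximum unsmoothed
#' 1-min-bin exploration value (both sides summed) within the phase.
#'
#' @param series an `exploration_series`.
#' @param schedule a [phase_schedule()].
#' @param phase phase name.
#' @param bin_width_s bin width for the peak, seconds.
#' @return list `latency_s` (`NA` if no exploration) and `peak_bin_s`.
#' @export
latency_and_peak <- function(series, schedule, phase, bin_width_s = 60) {
  w <- phase_window(schedule, phase)
  sel <- series$time_s >= w["start"] & series$time_s < w["end"]
  sub <- series[sel, , drop = FALSE]
  attr(sub, "frame_rate") <- attr(series, "frame_rate")
  any_exp <- sub$explore_left | sub$explore_right
  latency <- if (any(any_exp)) min(sub$time_s[any_exp]) - w[["start"]] else NA_real_
  if (nrow(sub)) {
    b <- bin_series(sub, bin_width_s)
    peak <- max(b$left_s + b$right_s)
  } else peak <- 0
  list(latency_s = latency, peak_bin_s = peak)
}

#' Cohort peak exploration at the group-level argmax bin
#'
#' For group comparisons of peak exploration, the bin with the maximal
#' group-mean exploration is found per phase, and each animal's unsmoothed
#' value in that bin is returned.
#'
#' @param binned_list list of `binned_exploration` tables, one per animal,
#'   on a common bin grid (restricted to one phase).
#' @return list `peak_bin_start_s` and numeric `values` (one per animal).
#' @export
cohort_peak_values <- function(binned_list) {
  grids <- lapply(binned_list, `[[`, "bin_start_s")
  common <- Reduce(intersect, grids)
  if (!length(common)) stop("no common bins across animals")
  tot <- vapply(binned_list, function(b) {
    m <- match(common, b$bin_start_s)
    b$left_s[m] + b$right_s[m]
  }, numeric(length(common)))
  tot <- matrix(tot, nrow = length(common))
  peak_bin <- common[which.max(rowMeans(tot))]
  list(peak_bin_start_s = peak_bin,
       values = tot[match(peak_bin, common), ])
}

#' First-approach analysis
#'
#' Which object does each animal approach first in the test phase? Returns
#' the per-animal side (novel/familiar), the cohort proportion approaching
#' the novel object first, and an exact binomial test against 0.5 (one-sided
#' toward novel-first by default, reflecting the directional hypothesis).
#'
#' For the sample and retention phases the novel/familiar labels are assigned
#' by the side on which the objects will subsequently appear in the test
#' phase.
#'
#' @param sessions list of lists with elements `series` (or `labels`, as in
#'   simulated sessions) and `schedule`, one per animal.
#' @param phase phase in which to score the first approach.
#' @param alternative passed to [stats::binom.test()]; default `"greater"`.
#' @return list `first_side` (character, `NA` when the animal never explores
#'   in the phase), `n_novel`, `n_total`, `proportion`, `p_value`.
#' @export
first_approach <- function(sessions, phase = "test", alternative = "greater") {
  first_side <- vapply(sessions, function(s) {
    series <- s$series %||% s$labels
    w <- phase_window(s$schedule, phase)
    sel <- series$time_s >= w["start"] & series$time_s < w["end"]
    sub <- series[sel, , drop = FALSE]
    idx <- which(sub$explore_left | sub$explore_right)
    if (!length(idx)) return(NA_character_)
    side <- if (sub$explore_left[idx[1]]) "left" else "right"
    if (side == s$schedule$novel_side) "novel" else "familiar"
  }, "")
  scored <- first_side[!is.na(first_side)]
  n_novel <- sum(scored == "novel")
  n_total <- length(scored)
  p <- if (n_total > 0)
    binom.test(n_novel, n_total, p = 0.5, alternative = alternative)$p.value
  else NA_real_
  list(first_side = first_side, n_novel = n_novel, n_total = n_total,
       proportion = if (n_total > 0) n_novel / n_total else NA_real_,
       p_value = p)
}

#' Correlation between sample-phase exploration and the relative DI
#'
#' Tests whether animals that explored the future-novel (or future-familiar)
#' side more during the sample phase show weaker novel-object recognition
#' (the relative DI). Pearson correlation with the usual t-transform p-value.
#'
#' @param scores data frame from rbinding [score_session()] rows across a
#'   cohort.
#' @param side `"novel"` or `"familiar"`: which sample-phase exploration time
#'   to correlate.
#' @return list `r`, `p_value`, `n`, `flagged` (TRUE when variance is zero or
#'   n < 3).
#' @export
sample_vs_relative_di_correlation <- function(scores, side = c("novel", "familiar")) {
  side <- match.arg(side)
  x <- if (side == "novel") scores$t_novel_sample_s else scores$t_familiar_sample_s
  y <- scores$relative_di
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3 || sd(x) == 0 || sd(y) == 0)
    return(list(r = NA_real_, p_value = NA_real_, n = length(x), flagged = TRUE))
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x), flagged = FALSE)
}
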