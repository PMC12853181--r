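#' Extract per-frame posture features for exploration detection
#'
#' For each frame and each object side, computes the geometric quantities a
#' scorer would use to decide whether the mouse is exploring: snout-to-object
#' distance (cm), heading alignment (degrees between the head axis, ears
#' midpoint to snout, and the snout-to-object vector), body elongation
#' (snout to tail base, cm) and speed of the body centre (cm/s). Frames whose
#' snout or ear confidence falls below `confidence_floor` are flagged
#' unreliable.
#'
#' @param track a `keypoint_track` data frame (see [read_keypoints()] or
#'   [simulate_session()]).
#' @param layout a [cage_layout()].
#' @param confidence_floor minimum keypoint likelihood for a frame to count
#'   as reliable (default 0.6).
#' @return a `posture_features` data frame with one row per frame: `frame`,
#'   `time_s`, `dist_left_cm`, `dist_right_cm`, `align_left_deg`,
#'   `align_right_deg`, `elongation_cm`, `speed_cm_s`, `reliable`.
#' @export
extract_features <- function(track, layout, confidence_floor = 0.6) {
  if (layout$px_per_cm <= 0) stop("px_per_cm calibration must be positive")
  needed <- c("snout", "ear_left", "ear_right", "tail_base")
  for (p in needed) {
    for (suf in c(".x", ".y", ".likelihood")) {
      if (!paste0(p, suf) %in% names(track))
        stop("format error: missing body part column: ", paste0(p, suf))
    }
  }
  ppc <- layout$px_per_cm
  fr <- attr(track, "frame_rate") %||% infer_frame_rate(track$time_s)

  sx <- track$snout.x; sy <- track$snout.y
  mx <- (track$ear_left.x + track$ear_right.x) / 2
  my <- (track$ear_left.y + track$ear_right.y) / 2
  hx <- sx - mx; hy <- sy - my  # head axis

  angle_to <- function(obj) {
    ox <- obj[1] - sx; oy <- obj[2] - sy
    dot <- hx * ox + hy * oy
    den <- sqrt(hx^2 + hy^2) * sqrt(ox^2 + oy^2)
    a <- acos(pmin(pmax(dot / den, -1), 1)) * 180 / pi
    a[den == 0] <- 0  # snout on the object or degenerate head axis
    a
  }
  dist_to <- function(obj) sqrt((sx - obj[1])^2 + (sy - obj[2])^2) / ppc

  spine_cols_x <- grep("^spine_[0-9]+\\.x$", names(track), value = TRUE)
  if (length(spine_cols_x)) {
    bx <- rowMeans(track[spine_cols_x])
    by <- rowMeans(track[sub("\\.x$", ".y", spine_cols_x)])
  } else {
    bx <- mx; by <- my
  }
  n <- nrow(track)
  speed <- if (n > 1) {
    c(0, sqrt(diff(bx)^2 + diff(by)^2)) / ppc * fr
  } else rep(0, n)

  out <- data.frame(
    frame = track$frame,
    time_s = track$time_s,
    dist_left_cm = dist_to(layout$object_left),
    dist_right_cm = dist_to(layout$object_right),
    align_left_deg = angle_to(layout$object_left),
    align_right_deg = angle_to(layout$object_right),
    elongation_cm = sqrt((sx - track$tail_base.x)^2 + (sy - track$tail_base.y)^2) / ppc,
    speed_cm_s = speed,
    reliable = track$snout.likelihood >= confidence_floor &
      track$ear_left.likelihood >= confidence_floor &
      track$ear_right.likelihood >= confidence_floor
  )
  attr(out, "frame_rate") <- fr
  class(out) <- c("posture_features", "data.frame")
  out
}

infer_frame_rate <- function(time_s) {
  if (length(time_s) < 2) return(2)
  step <- diff(time_s)
  if (any(step <= 0)) stop("format error: time must be strictly increasing")
  if (max(step) - min(step) > 1e-6)
    stop("format error: frame period must be constant")
  1 / step[1]
}

#' Geometric rule classifier for object exploration
#'
#' A frame counts as exploring a side iff the snout is within `max_distance`
#' of that side's object window, the head axis points at the object within
#' `max_angle`, and the frame is reliable. Within `near_distance` of the
#' object the angle criterion is waived: with the snout essentially on the
#' object the snout-object vector is shorter than the tracking noise, so the
#' computed alignment is ill-conditioned, and scorers count snout-on-object
#' contact as exploration regardless of head angle. If both sides qualify the
#' nearer object wins (the two windows are on opposite walls, so both cannot
#' be genuinely explored at once). Unreliable frames inherit the previous
#' frame's label only if that frame was exploratory (i.e. inside a bout),
#' otherwise they are non-exploratory.
#'
#' @param features a `posture_features` data frame from [extract_features()].
#' @param max_distance snout-object distance threshold, cm (default 3).
#' @param max_angle heading alignment threshold, degrees (default 45).
#' @param near_distance distance (cm) within which proximity alone decides.
#' @return an `exploration_series` data frame (`frame`, `time_s`,
#'   `explore_left`, `explore_right`), with the thresholds recorded in
#'   attribute `params`.
#' @export
rule_classify <- function(features, max_distance = 3, max_angle = 45,
                          near_distance = 1.5) {
  if (max_distance <= 0 || max_angle <= 0) stop("thresholds must be positive")
  ok_l <- features$dist_left_cm <= max_distance &
    (features$align_left_deg <= max_angle | features$dist_left_cm <= near_distance)
  ok_r <- features$dist_right_cm <= max_distance &
    (features$align_right_deg <= max_angle | features$dist_right_cm <= near_distance)
  both <- ok_l & ok_r
  nearer_left <- features$dist_left_cm <= features$dist_right_cm
  ok_l[both] <- nearer_left[both]
  ok_r[both] <- !nearer_left[both]
  lab <- integer(nrow(features))  # 0 none, 1 left, 2 right
  lab[ok_l] <- 1L
  lab[ok_r] <- 2L
  unrel <- !features$reliable
  if (any(unrel)) {
    for (i in which(unrel)) {
      lab[i] <- if (i > 1 && lab[i - 1] > 0L) lab[i - 1] else 0L
    }
  }
  out <- data.frame(
    frame = features$frame,
    time_s = features$time_s,
    explore_left = lab == 1L,
    explore_right = lab == 2L
  )
  attr(out, "frame_rate") <- attr(features, "frame_rate")
  attr(out, "params") <- list(max_distance_cm = max_distance,
                              max_angle_deg = max_angle,
                              near_distance_cm = near_distance,
                              classifier = "rule")
  class(out) <- c("exploration_series", "data.frame")
  out
}

#' Balanced accuracy between two exploration series
#'
#' Mean per-class recall over the three per-frame classes (none, left,
#' right).
#'
#' @param truth,pred `exploration_series` data frames of equal length.
#' @return a single number in `[0, 1]`.
#' @export
balanced_accuracy <- function(truth, pred) {
  stopifnot(nrow(truth) == nrow(pred))
  to_class <- function(s) ifelse(s$explore_left, 1L, ifelse(s$explore_right, 2L, 0L))
  tc <- to_class(truth); pc <- to_class(pred)
  classes <- sort(unique(tc))
  mean(vapply(classes, function(k) mean(pc[tc == k] == k), 0))
}
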