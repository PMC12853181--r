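#' Dwell-time heatmap of mouse position
#'
#' Accumulates seconds spent per spatial grid cell using the body centre
#' (mean of the spine keypoints). Mice spend most of their time in the nest,
#' so the maximum-dwell cell marks the nest location. By default only the
#' sample and retention phases contribute.
#'
#' @param track a `keypoint_track`.
#' @param layout a [cage_layout()].
#' @param grid_cm cell size in cm (default 1).
#' @param schedule optional [phase_schedule()]; when given, only frames in
#'   `phases` are used.
#' @param phases phases contributing to the heatmap.
#' @return An object of class `dwell_heatmap`: list with `seconds` (matrix,
#'   rows = y cells, cols = x cells), `x_breaks_px`, `y_breaks_px`,
#'   `grid_cm`, and `argmax_px` (centre of the maximal cell).
#' @export
dwell_heatmap <- function(track, layout, grid_cm = 1, schedule = NULL,
                          phases = c("sample", "retention")) {
  if (nrow(track) == 0) stop("empty track")
  if (grid_cm <= 0) stop("grid size must be positive")
  fr <- attr(track, "frame_rate") %||% infer_frame_rate(track$time_s)
  keep <- rep(TRUE, nrow(track))
  if (!is.null(schedule)) {
    keep <- rep(FALSE, nrow(track))
    for (ph in phases) {
      w <- phase_window(schedule, ph)
      keep <- keep | (track$time_s >= w["start"] & track$time_s < w["end"])
    }
  }
  spine_x <- grep("^spine_[0-9]+\\.x$", names(track), value = TRUE)
  if (length(spine_x)) {
    bx <- rowMeans(track[spine_x])[keep]
    by <- rowMeans(track[sub("\\.x$", ".y", spine_x)])[keep]
  } else {
    bx <- ((track$ear_left.x + track$ear_right.x) / 2)[keep]
    by <- ((track$ear_left.y + track$ear_right.y) / 2)[keep]
  }
  cell_px <- grid_cm * layout$px_per_cm
  nx <- ceiling(layout$arena_w_px / cell_px)
  ny <- ceiling(layout$arena_h_px / cell_px)
  ix <- pmin(pmax(floor(bx / cell_px), 0), nx - 1) + 1
  iy <- pmin(pmax(floor(by / cell_px), 0), ny - 1) + 1
  m <- matrix(0, nrow = ny, ncol = nx)
  for (k in seq_along(ix)) m[iy[k], ix[k]] <- m[iy[k], ix[k]] + 1
  m <- m / fr
  arg <- which(m == max(m), arr.ind = TRUE)[1, ]
  structure(list(
    seconds = m,
    x_breaks_px = (0:nx) * cell_px,
    y_breaks_px = (0:ny) * cell_px,
    grid_cm = grid_cm,
    argmax_px = c(x = (unname(arg["col"]) - 0.5) * cell_px,
                  y = (unname(arg["row"]) - 0.5) * cell_px)
  ), class = "dwell_heatmap")
}

#' Locate the nest and its distances to the objects
#'
#' @param heatmap a [dwell_heatmap()].
#' @param layout a [cage_layout()].
#' @return one-row data frame: `nest_x_px`, `nest_y_px`, `d_left_cm`,
#'   `d_right_cm`.
#' @export
nest_from_heatmap <- function(heatmap, layout) {
  p <- heatmap$argmax_px
  d <- function(obj) sqrt((p[["x"]] - obj[1])^2 + (p[["y"]] - obj[2])^2) / layout$px_per_cm
  data.frame(nest_x_px = p[["x"]], nest_y_px = p[["y"]],
             d_left_cm = d(layout$object_left), d_right_cm = d(layout$object_right))
}

#' Group mice into nest-left / nest-right by k-means on object distances
#'
#' Clusters the cohort's (distance-to-left-object, distance-to-right-object)
#' vectors with k-means (k = 2, fixed seed, 10 restarts) and labels the
#' cluster whose mean distance-to-left is smaller as the nest-left group.
#' Degenerate cohorts (a single mouse, identical nests, or a cluster failure)
#' fall back to a per-mouse nearest-object rule with a warning; exact
#' equidistance breaks the tie to the left.
#'
#' @param nests data frame with columns `d_left_cm`, `d_right_cm` (one row
#'   per mouse), e.g. rbinding [nest_from_heatmap()] rows.
#' @param seed integer seed for the k-means restarts.
#' @return character vector (`"left"`/`"right"`), one per mouse, with
#'   attribute `method` (`"kmeans"` or `"nearest"`).
#' @export
assign_nest_sides <- function(nests, seed = 1L) {
  x <- as.matrix(nests[, c("d_left_cm", "d_right_cm")])
  nearest <- ifelse(x[, "d_left_cm"] <= x[, "d_right_cm"], "left", "right")
  fallback <- function(msg) {
    warning("k-means grouping degenerate (", msg, "); using nearest-object rule")
    structure(nearest, method = "nearest")
  }
  if (nrow(x) < 2) return(structure(nearest, method = "nearest"))
  if (nrow(unique(x)) < 2) return(fallback("all nests identical"))
  if (length(unique(nearest)) < 2) return(fallback("all nests on one side"))
  set.seed(as.integer(seed))
  km <- tryCatch(kmeans(x, centers = 2, nstart = 10), error = function(e) NULL)
  if (is.null(km)) return(fallback("kmeans failed"))
  left_cluster <- which.min(km$centers[, "d_left_cm"])
  structure(ifelse(km$cluster == left_cluster, "left", "right"),
            method = "kmeans")
}

#' Nest-position bias in object exploration
#'
#' Compares exploration time of the left object and of the right object
#' between the nest-left and nest-right groups (Welch two-sample t per object
#' side, Benjamini-Hochberg corrected across the two comparisons).
#'
#' @param exploration data frame with columns `left_min`, `right_min`
#'   (per-mouse exploration minutes of each object).
#' @param side_group character vector from [assign_nest_sides()].
#' @return data frame with one row per object side: `object_side`,
#'   `mean_nest_left`, `mean_nest_right`, `statistic`, `df`, `p_value`,
#'   `p_adjusted`, `flagged`.
#' @export
nest_bias_test <- function(exploration, side_group) {
  stopifnot(nrow(exploration) == length(side_group))
  g_l <- side_group == "left"
  one <- function(v, nm) {
    row <- two_sample_t(v[g_l], v[!g_l])
    data.frame(object_side = nm,
               mean_nest_left = mean(v[g_l]),
               mean_nest_right = mean(v[!g_l]),
               statistic = row$statistic, df = row$df,
               p_value = row$p_value, flagged = row$flagged)
  }
  out <- rbind(one(exploration$left_min, "left"),
               one(exploration$right_min, "right"))
  out$p_adjusted <- bh_adjust(out$p_value)
  out
}

#' Corridor-exit side-preference score
#'
#' For every interval between two consecutive corridor visits (sample and
#' retention phases), scores 0 if the first object explored is on the same
#' side as the corridor just exited and 1 if on the opposite side; intervals
#' with no exploration are skipped. A mean near 0.5 indicates no
#' corridor-based strategy; the mean is tested against 0.5 with a one-sample
#' t test.
#'
#' @param visits data frame of corridor visits (`side`, `exit_time_s`), e.g.
#'   `session$events$corridor_visits`.
#' @param bouts a [segment_bouts()] table.
#' @param schedule optional [phase_schedule()]; restricts intervals to the
#'   given phases.
#' @param phases phases whose intervals are scored.
#' @return list `scores` (data frame: `exited_side`, `first_object`, `score`),
#'   `mean_score`, `n`, `t_test` (one-sample vs 0.5), `flagged`.
#' @export
corridor_scores <- function(visits, bouts, schedule = NULL,
                            phases = c("sample", "retention")) {
  if (!is.null(schedule)) {
    keep <- rep(FALSE, nrow(visits))
    for (ph in phases) {
      w <- phase_window(schedule, ph)
      keep <- keep | (visits$exit_time_s >= w["start"] & visits$exit_time_s < w["end"])
    }
    visits <- visits[keep, , drop = FALSE]
  }
  visits <- visits[order(visits$exit_time_s), , drop = FALSE]
  n_v <- nrow(visits)
  rows <- list()
  for (i in seq_len(n_v)) {
    t0 <- visits$exit_time_s[i]
    t1 <- if (i < n_v) visits$exit_time_s[i + 1] else Inf
    cand <- bouts[bouts$start_s >= t0 & bouts$start_s < t1, , drop = FALSE]
    if (!nrow(cand)) next
    first_obj <- cand$side[which.min(cand$start_s)]
    rows[[length(rows) + 1]] <- data.frame(
      exited_side = visits$side[i],
      first_object = first_obj,
      score = as.integer(first_obj != visits$side[i])
    )
  }
  if (!length(rows)) {
    return(list(scores = data.frame(exited_side = character(0),
                                    first_object = character(0),
                                    score = integer(0)),
                mean_score = NA_real_, n = 0L,
                t_test = flag_row("one_sample_t"), flagged = TRUE))
  }
  scores <- do.call(rbind, rows)
  list(scores = scores, mean_score = mean(scores$score), n = nrow(scores),
       t_test = one_sample_t(scores$score, mu = 0.5), flagged = FALSE)
}
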