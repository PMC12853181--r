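#' Write and read keypoint tracks
#'
#' Two on-disk dialects are supported: the pose-estimation CSV layout with
#' three header rows (scorer / bodyparts / coords, columns x, y, likelihood
#' per body part) and a tidy long CSV (`frame, time_s, bodypart, x, y,
#' likelihood`). Both round-trip exactly. Coordinates are image pixels,
#' origin top-left, y downward; frames are 0-based.
#'
#' @param track a `keypoint_track` data frame.
#' @param path file path.
#' @param dialect `"dlc_csv"` (3 header rows) or `"tidy_csv"`.
#' @param frame_rate frames per second, required metadata when reading a
#'   dlc_csv file (the format stores no time axis); default 2.
#' @param fill_gaps when reading: forward-fill single-frame gaps instead of
#'   rejecting them (tidy dialect only; gaps larger than one frame are always
#'   rejected).
#' @param scorer scorer string written into the dlc header.
#' @return `read_keypoints()` returns a `keypoint_track`;
#'   `write_keypoints()` returns `path` invisibly.
#' @name keypoints_io
NULL

#' @rdname keypoints_io
#' @export
write_keypoints <- function(track, path, dialect = c("dlc_csv", "tidy_csv"),
                            scorer = "norcage") {
  dialect <- match.arg(dialect)
  parts <- attr(track, "bodyparts") %||%
    unique(sub("\\.(x|y|likelihood)$", "",
               grep("\\.(x|y|likelihood)$", names(track), value = TRUE)))
  if (dialect == "dlc_csv") {
    cols <- unlist(lapply(parts, function(p) paste0(p, c(".x", ".y", ".likelihood"))))
    h1 <- paste(c("scorer", rep(scorer, length(cols))), collapse = ",")
    h2 <- paste(c("bodyparts", rep(parts, each = 3)), collapse = ",")
    h3 <- paste(c("coords", rep(c("x", "y", "likelihood"), length(parts))), collapse = ",")
    body <- cbind(track$frame, format(as.matrix(track[cols]), trim = TRUE, digits = 15))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(h1, h2, h3), con)
    write.table(body, con, sep = ",", row.names = FALSE, col.names = FALSE,
                quote = FALSE)
  } else {
    long <- do.call(rbind, lapply(parts, function(p) {
      data.frame(frame = track$frame, time_s = track$time_s, bodypart = p,
                 x = track[[paste0(p, ".x")]], y = track[[paste0(p, ".y")]],
                 likelihood = track[[paste0(p, ".likelihood")]])
    }))
    long <- long[order(long$frame, match(long$bodypart, parts)), ]
    write.csv(long, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname keypoints_io
#' @export
read_keypoints <- function(path, dialect = c("dlc_csv", "tidy_csv"),
                           frame_rate = 2, fill_gaps = FALSE) {
  dialect <- match.arg(dialect)
  if (dialect == "dlc_csv") {
    hdr <- readLines(path, n = 3)
    h <- lapply(hdr, function(l) strsplit(l, ",", fixed = TRUE)[[1]])
    if (length(h) < 3 || h[[1]][1] != "scorer" || h[[2]][1] != "bodyparts" ||
        h[[3]][1] != "coords")
      stop("format error: expected 3 header rows scorer/bodyparts/coords")
    parts_row <- h[[2]][-1]
    coords_row <- h[[3]][-1]
    raw <- read.csv(path, skip = 3, header = FALSE)
    if (ncol(raw) != length(parts_row) + 1)
      stop("format error: header/body column mismatch")
    out <- data.frame(frame = as.integer(raw[[1]]))
    out$time_s <- out$frame / frame_rate
    for (j in seq_along(parts_row)) {
      out[[paste0(parts_row[j], ".", coords_row[j])]] <- as.numeric(raw[[j + 1]])
    }
    parts <- unique(parts_row)
  } else {
    long <- read.csv(path, comment.char = "#")
    needed <- c("frame", "time_s", "bodypart", "x", "y", "likelihood")
    miss <- setdiff(needed, names(long))
    if (length(miss)) stop("format error: missing columns: ", paste(miss, collapse = ", "))
    parts <- unique(long$bodypart)
    frames <- sort(unique(long$frame))
    out <- data.frame(frame = frames,
                      time_s = long$time_s[match(frames, long$frame)])
    for (p in parts) {
      sub <- long[long$bodypart == p, ]
      m <- match(frames, sub$frame)
      out[[paste0(p, ".x")]] <- sub$x[m]
      out[[paste0(p, ".y")]] <- sub$y[m]
      out[[paste0(p, ".likelihood")]] <- sub$likelihood[m]
    }
  }
  validate_track(out, parts, frame_rate, fill_gaps)
}

validate_track <- function(out, parts, frame_rate, fill_gaps) {
  if (any(diff(out$frame) <= 0))
    stop("format error: nonmonotone frame order")
  gaps <- diff(out$frame)
  if (any(gaps > 1)) {
    if (!fill_gaps || any(gaps > 2))
      stop("format error: gaps in frame index (", sum(gaps > 1), " gaps)")
    # forward-fill single missing frames
    full <- data.frame(frame = seq(min(out$frame), max(out$frame)))
    m <- match(full$frame, out$frame)
    filled <- out[ifelse(is.na(m), NA, m), ]
    for (i in which(is.na(m))) filled[i, ] <- filled[i - 1, ]
    filled$frame <- full$frame
    filled$time_s <- filled$frame / frame_rate
    out <- filled
  }
  if (nrow(out) > 1) infer_frame_rate(out$time_s)  # validates constant step
  lik <- grep("\\.likelihood$", names(out), value = TRUE)
  bad <- vapply(lik, function(cn) any(out[[cn]] < 0 | out[[cn]] > 1, na.rm = TRUE), TRUE)
  if (any(bad)) stop("format error: likelihood outside [0, 1] in ",
                     paste(lik[bad], collapse = ", "))
  attr(out, "frame_rate") <- frame_rate
  attr(out, "bodyparts") <- parts
  class(out) <- c("keypoint_track", "data.frame")
  out
}

#' Write and read exploration label series
#'
#' Tidy CSV with columns `frame, time_s, explore_left, explore_right`
#' (0/1). Reading validates mutual exclusivity of the two sides.
#'
#' @param series an `exploration_series`.
#' @param path file path.
#' @param frame_rate frames per second (stored as a `#` metadata line on
#'   write; the value in the file wins on read).
#' @name labels_io
#' @export
write_labels <- function(series, path, frame_rate = NULL) {
  fr <- frame_rate %||% attr(series, "frame_rate") %||% infer_frame_rate(series$time_s)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# frame_rate=%g", fr), con)
  out <- data.frame(frame = series$frame, time_s = series$time_s,
                    explore_left = as.integer(series$explore_left),
                    explore_right = as.integer(series$explore_right))
  write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname labels_io
#' @export
read_labels <- function(path) {
  first <- readLines(path, n = 1)
  fr <- if (grepl("^# frame_rate=", first))
    as.numeric(sub("^# frame_rate=", "", first)) else NULL
  df <- read.csv(path, comment.char = "#")
  needed <- c("frame", "time_s", "explore_left", "explore_right")
  miss <- setdiff(needed, names(df))
  if (length(miss)) stop("format error: missing columns: ", paste(miss, collapse = ", "))
  df$explore_left <- df$explore_left != 0
  df$explore_right <- df$explore_right != 0
  if (any(df$explore_left & df$explore_right))
    stop("validation error: explore_left and explore_right both true on a frame")
  attr(df, "frame_rate") <- fr %||% infer_frame_rate(df$time_s)
  class(df) <- c("exploration_series", "data.frame")
  df
}

#' Write and read phase schedules (YAML or JSON)
#'
#' @param schedule a [phase_schedule()].
#' @param path file path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @name schedule_io
#' @export
write_schedule <- function(schedule, path) {
  obj <- list(novel_side = schedule$novel_side,
              phases = lapply(seq_len(nrow(schedule$phases)), function(i)
                as.list(schedule$phases[i, ])))
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(obj, path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else stop("schedule path must end in .yaml, .yml or .json")
  invisible(path)
}

#' @rdname schedule_io
#' @export
read_schedule <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else if (grepl("\\.json$", path)) jsonlite::read_json(path)
  else stop("schedule path must end in .yaml, .yml or .json")
  phases <- do.call(rbind, lapply(obj$phases, function(p)
    data.frame(name = p$name, start_s = as.numeric(p$start_s),
               end_s = as.numeric(p$end_s),
               object_left = p$object_left %||% NA_character_,
               object_right = p$object_right %||% NA_character_)))
  validate_schedule(structure(list(phases = phases, novel_side = obj$novel_side),
                              class = "phase_schedule"))
}

#' Write an analysis report CSV with metadata header
#'
#' All pipeline outputs share one CSV convention: `#`-prefixed metadata lines
#' (package version, seed, parameters) followed by a regular CSV table, so a
#' rerun with the same inputs and seed is byte-identical apart from nothing
#' (no timestamps are written).
#'
#' @param df data frame to write.
#' @param path file path.
#' @param meta named list of metadata scalars.
#' @export
write_report <- function(df, path, meta = list()) {
  meta <- c(list(package = "norcage",
                 version = as.character(utils::packageVersion("norcage"))),
            meta)
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(meta)) writeLines(sprintf("# %s=%s", nm, meta[[nm]]), con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write all outputs of a simulated session to a directory
#'
#' Emits `keypoints_dlc.csv`, `keypoints_tidy.csv`, `labels.csv`,
#' `schedule.yaml`, `corridor_visits.csv` and `nest_intervals.csv`.
#'
#' @param session a [simulate_session()] result.
#' @param dir output directory (created if missing).
#' @return the directory path, invisibly.
#' @export
write_session <- function(session, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_keypoints(session$keypoints, file.path(dir, "keypoints_dlc.csv"), "dlc_csv")
  write_keypoints(session$keypoints, file.path(dir, "keypoints_tidy.csv"), "tidy_csv")
  write_labels(session$labels, file.path(dir, "labels.csv"))
  write_schedule(session$schedule, file.path(dir, "schedule.yaml"))
  meta <- list(seed = session$truth_params$seed)
  write_report(session$events$corridor_visits,
               file.path(dir, "corridor_visits.csv"), meta)
  write_report(session$events$nest_intervals,
               file.path(dir, "nest_intervals.csv"), meta)
  invisible(dir)
}
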