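#' Phase schedule for a NOR session
#'
#' The NOR task runs in four contiguous phases: habituation (baseline objects),
#' sample (two new identical-novelty objects), retention (baseline restored)
#' and test (one familiar replica, one novel object). The schedule records the
#' phase boundaries, the object identity presented on each side in each phase,
#' and which side carries the novel object in the test phase.
#'
#' @param durations_s named numeric vector of phase durations in seconds, with
#'   names `habituation`, `sample`, `retention`, `test`, in that order.
#' @param novel_side `"left"` or `"right"`: side of the novel object in the
#'   test phase.
#' @param objects named list giving per-phase `c(left, right)` object
#'   identities from `{baseline, wood, metal, acrylic}`; a sensible default is
#'   filled in.
#' @return An object of class `phase_schedule`: a list with a `phases`
#'   data frame (`name`, `start_s`, `end_s`, `object_left`, `object_right`)
#'   and `novel_side`.
#' @export
phase_schedule <- function(durations_s = c(habituation = 9 * 86400,
                                           sample = 86400,
                                           retention = 86400,
                                           test = 7200),
                           novel_side = "left",
                           objects = NULL) {
  required <- c("habituation", "sample", "retention", "test")
  if (!identical(names(durations_s), required))
    stop("durations_s must be named habituation, sample, retention, test (in order)")
  if (any(!is.finite(durations_s)) || any(durations_s <= 0))
    stop("all phase durations must be positive")
  novel_side <- match.arg(novel_side, c("left", "right"))
  if (is.null(objects)) {
    objects <- list(
      habituation = c("baseline", "baseline"),
      sample      = c("wood", "metal"),
      retention   = c("baseline", "baseline"),
      test        = if (novel_side == "left") c("acrylic", "metal") else c("wood", "acrylic")
    )
  }
  ends <- cumsum(durations_s)
  phases <- data.frame(
    name = required,
    start_s = c(0, ends[-4]),
    end_s = unname(ends),
    object_left = vapply(objects[required], `[`, "", 1),
    object_right = vapply(objects[required], `[`, "", 2),
    stringsAsFactors = FALSE
  )
  rownames(phases) <- NULL
  validate_schedule(structure(list(phases = phases, novel_side = novel_side),
                              class = "phase_schedule"))
}

validate_schedule <- function(schedule) {
  p <- schedule$phases
  if (!all(c("name", "start_s", "end_s") %in% names(p)))
    stop("schedule phases need columns name, start_s, end_s")
  if (any(p$end_s <= p$start_s)) stop("phase end must exceed start")
  if (nrow(p) > 1 && any(abs(p$start_s[-1] - p$end_s[-nrow(p)]) > 1e-9))
    stop("phases must be contiguous and non-overlapping")
  if (!schedule$novel_side %in% c("left", "right"))
    stop("exactly one novel side (left or right) must be set for the test phase")
  schedule
}

#' @export
print.phase_schedule <- function(x, ...) {
  cat("<phase_schedule> novel side in test:", x$novel_side, "\n")
  print(x$phases)
  invisible(x)
}

phase_window <- function(schedule, phase) {
  p <- schedule$phases
  row <- p[p$name == phase, , drop = FALSE]
  if (nrow(row) != 1) stop("phase not found in schedule: ", phase)
  c(start = row$start_s, end = row$end_s)
}
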