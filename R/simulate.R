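#' Configuration for the synthetic homecage session generator
#'
#' The generator is a discrete-time (per-frame) Markov-modulated state process
#' over five occupancy states: nest, corridor, roaming, exploring the left
#' object and exploring the right object. Exploration bouts start from the
#' roaming state with a per-side hazard
#'
#' \deqn{\lambda_{side}(t) = h_0 \cdot b_{side} \cdot
#'   (1 + A_{phase} e^{-(t - t_{change})/\tau}) \cdot
#'   (f \; \mathrm{on\ the\ novel\ side\ in\ test})}
#'
#' where \eqn{h_0} is the baseline bout-start rate, \eqn{b_{side}} the
#' multiplicative side bias (right side), \eqn{A_{phase}} the novelty boost
#' triggered by each object change (scaled down in the retention phase, where
#' the change is back to familiar baseline objects), \eqn{\tau} the novelty
#' decay constant and \eqn{f} the novel:familiar exploration ratio. Bout and
#' dwell durations are exponential.
#'
#' @param frame_rate frames per second (default 2).
#' @param phase_durations named seconds per phase (habituation, sample,
#'   retention, test); defaults 9 d / 24 h / 24 h / 2 h.
#' @param baseline_hazard exploration bout starts per second per side while
#'   roaming, before modulation.
#' @param novelty_boost_amplitude dimensionless boost added at an object
#'   change; the default, with the default bout duration, yields a
#'   peak exploration rate of roughly 10-13 s/min that relaxes to baseline in
#'   20-30 min (3 tau with the default tau of 8 min).
#' @param novelty_decay_tau decay constant of the boost, seconds.
#' @param novel_side_factor ratio of novel:familiar exploration hazard during
#'   the test phase (default 1.67, i.e. a ~67% increase).
#' @param side_bias multiplier on the right-side hazard (1 = unbiased).
#' @param bout_duration_mean mean exploration bout duration, seconds.
#' @param nest_position cage x/y of the nest in pixels (default: layout's).
#' @param corridor_visit_rate corridor entries per second from roaming.
#' @param corridor_side_coupling probability that the first exploration bout
#'   after leaving a corridor (sample/retention phases) targets the same-side
#'   object; 0.5 = no strategy.
#' @param corridor_dwell_mean mean corridor dwell, seconds.
#' @param nest_entry_rate nest entries per second from roaming.
#' @param nest_dwell_mean mean nest dwell, seconds.
#' @param retention_boost_scale multiplier on the boost amplitude at the
#'   retention-phase object change (familiar objects return, so the rebound is
#'   weaker).
#' @param right_nest_boost extra multiplier on the right-side hazard when the
#'   nest sits in the right half of the cage; 1 disables the coupling.
#' @param keypoint_jitter_px isotropic Gaussian jitter SD on emitted
#'   keypoints.
#' @param novel_side side of the novel object in the test phase.
#' @param layout a [cage_layout()].
#' @param seed integer seed; expanded internally into independent substreams.
#' @return An object of class `session_sim_config`.
#' @seealso [simulate_session()]
#' @export
session_sim_config <- function(frame_rate = 2,
                               phase_durations = c(habituation = 9 * 86400,
                                                   sample = 86400,
                                                   retention = 86400,
                                                   test = 7200),
                               baseline_hazard = 0.004,
                               novelty_boost_amplitude = 7,
                               novelty_decay_tau = 480,
                               novel_side_factor = 1.67,
                               side_bias = 1,
                               bout_duration_mean = 4,
                               nest_position = NULL,
                               corridor_visit_rate = 0.003,
                               corridor_side_coupling = 0.5,
                               corridor_dwell_mean = 20,
                               nest_entry_rate = 0.002,
                               nest_dwell_mean = 300,
                               retention_boost_scale = 0.2,
                               right_nest_boost = 1,
                               keypoint_jitter_px = 1,
                               novel_side = "left",
                               layout = cage_layout(),
                               seed = 1L) {
  if (frame_rate <= 0) stop("configuration error: frame_rate must be > 0")
  if (any(phase_durations <= 0)) stop("configuration error: all phase durations must be > 0")
  if (novel_side_factor <= 0) stop("configuration error: novel_side_factor must be > 0")
  if (side_bias <= 0) stop("configuration error: side_bias must be > 0")
  if (corridor_side_coupling < 0 || corridor_side_coupling > 1)
    stop("configuration error: corridor_side_coupling must be in [0, 1]")
  if (baseline_hazard <= 0 || bout_duration_mean <= 0 ||
      corridor_visit_rate < 0 || nest_entry_rate < 0)
    stop("configuration error: rates and durations must be positive")
  if (is.null(nest_position)) nest_position <- layout$nest_default
  structure(list(
    frame_rate = frame_rate, phase_durations = phase_durations,
    baseline_hazard = baseline_hazard,
    novelty_boost_amplitude = novelty_boost_amplitude,
    novelty_decay_tau = novelty_decay_tau,
    novel_side_factor = novel_side_factor,
    side_bias = side_bias, bout_duration_mean = bout_duration_mean,
    nest_position = nest_position,
    corridor_visit_rate = corridor_visit_rate,
    corridor_side_coupling = corridor_side_coupling,
    corridor_dwell_mean = corridor_dwell_mean,
    nest_entry_rate = nest_entry_rate, nest_dwell_mean = nest_dwell_mean,
    retention_boost_scale = retention_boost_scale,
    right_nest_boost = right_nest_boost,
    keypoint_jitter_px = keypoint_jitter_px,
    novel_side = match.arg(novel_side, c("left", "right")),
    layout = layout, seed = as.integer(seed)
  ), class = "session_sim_config")
}

#' Per-side exploration hazard over a session
#'
#' Evaluates the generator's per-frame exploration hazard (bout starts per
#' second while roaming) for both sides; exposed so tests can integrate it.
#'
#' @param config a [session_sim_config()].
#' @param time_s vector of session times (seconds).
#' @param schedule the session's [phase_schedule()].
#' @return data frame with columns `time_s`, `lambda_left`, `lambda_right`.
#' @export
exploration_hazard <- function(config, time_s, schedule) {
  p <- schedule$phases
  boost <- rep(1, length(time_s))
  for (ph in c("sample", "retention", "test")) {
    row <- p[p$name == ph, ]
    amp <- config$novelty_boost_amplitude *
      if (ph == "retention") config$retention_boost_scale else 1
    in_ph <- time_s >= row$start_s & time_s < row$end_s
    boost[in_ph] <- 1 + amp * exp(-(time_s[in_ph] - row$start_s) / config$novelty_decay_tau)
  }
  test_row <- p[p$name == "test", ]
  in_test <- time_s >= test_row$start_s & time_s < test_row$end_s
  fac_l <- ifelse(in_test & schedule$novel_side == "left", config$novel_side_factor, 1)
  fac_r <- ifelse(in_test & schedule$novel_side == "right", config$novel_side_factor, 1)
  right_mult <- config$side_bias *
    if (config$nest_position[1] > config$layout$arena_w_px / 2) config$right_nest_boost else 1
  data.frame(
    time_s = time_s,
    lambda_left = config$baseline_hazard * boost * fac_l,
    lambda_right = config$baseline_hazard * right_mult * boost * fac_r
  )
}

#' Simulate one homecage NOR session
#'
#' Runs the per-frame state process described in [session_sim_config()] and
#' emits keypoints geometrically consistent with the ground-truth exploration
#' labels: during a bout the snout lies within the object-access radius with
#' the head axis pointing at the object; otherwise body position follows the
#' occupancy state (nest, corridor, or a reflected random walk while roaming).
#'
#' @param config a [session_sim_config()].
#' @return An object of class `nor_session`: list with elements `keypoints`
#'   (a `keypoint_track` data frame), `labels` (an `exploration_series` data
#'   frame with ground truth), `schedule`, `events` (corridor visits and nest
#'   intervals), `states` (per-frame occupancy state) and `truth_params`
#'   (the config).
#' @examples
#' cfg <- session_sim_config(
#'   phase_durations = c(habituation = 60, sample = 600,
#'                       retention = 300, test = 600),
#'   seed = 42
#' )
#' sess <- simulate_session(cfg)
#' table(sess$states)
#' @export
simulate_session <- function(config) {
  if (!inherits(config, "session_sim_config"))
    stop("config must be a session_sim_config")
  schedule <- phase_schedule(config$phase_durations, novel_side = config$novel_side)
  fr <- config$frame_rate
  dt <- 1 / fr
  n <- as.integer(round(sum(config$phase_durations) * fr))
  time_s <- (seq_len(n) - 1L) * dt

  seeds <- derive_seeds(config$seed, 3L)
  haz <- exploration_hazard(config, time_s, schedule)
  in_test <- time_s >= phase_window(schedule, "test")["start"]
  p_l <- pmin(haz$lambda_left * dt, 1)
  p_r <- pmin(haz$lambda_right * dt, 1)
  p_corr <- min(config$corridor_visit_rate * dt, 1)
  p_nest <- min(config$nest_entry_rate * dt, 1)

  set.seed(seeds[1])
  u <- runif(n)            # state transition draws
  u_side <- runif(n)       # side / coupling draws
  u_corr_side <- runif(n)  # which corridor
  # states: 1 nest, 2 corridor L, 3 corridor R, 4 roam, 5 explore L, 6 explore R
  state <- integer(n)
  cur <- 4L
  countdown <- 0L
  pending_side <- 0L  # corridor side of a pending coupling (0 = none)
  corr_entry <- integer(0); corr_exit <- integer(0); corr_side <- integer(0)
  nest_entry <- integer(0); nest_exit <- integer(0)
  dwell_frames <- function(mean_s) max(1L, as.integer(round(rexp(1, 1 / mean_s) * fr)))

  end_dwell <- function(i) {
    # leaves the current dwell state; corridor exits may arm side coupling
    if (cur == 2L || cur == 3L) {
      corr_exit <<- c(corr_exit, i)
      if (!in_test[i] && config$corridor_side_coupling != 0.5)
        pending_side <<- cur - 1L  # 1 = left, 2 = right
    } else if (cur == 1L) {
      nest_exit <<- c(nest_exit, i)
    }
    cur <<- 4L
  }
  for (i in seq_len(n)) {
    if (cur != 4L) {
      state[i] <- cur
      countdown <- countdown - 1L
      if (countdown <= 0L) end_dwell(i)
      next
    }
    # roaming: cumulative thresholds on one uniform
    pe <- p_l[i] + p_r[i]
    if (u[i] < pe) {
      if (pending_side > 0L) {
        same <- u_side[i] < config$corridor_side_coupling
        side <- if (same) pending_side else 3L - pending_side
      } else {
        side <- if (u_side[i] < p_l[i] / pe) 1L else 2L
      }
      pending_side <- 0L
      cur <- if (side == 1L) 5L else 6L
      countdown <- dwell_frames(config$bout_duration_mean)
    } else if (u[i] < pe + p_corr) {
      cur <- if (u_corr_side[i] < 0.5) 2L else 3L
      corr_entry <- c(corr_entry, i)
      corr_side <- c(corr_side, cur - 1L)
      countdown <- dwell_frames(config$corridor_dwell_mean)
    } else if (u[i] < pe + p_corr + p_nest) {
      cur <- 1L
      nest_entry <- c(nest_entry, i)
      countdown <- dwell_frames(config$nest_dwell_mean)
    }
    state[i] <- cur
    if (cur != 4L) {
      # the frame that starts a dwell already counts toward it
      countdown <- countdown - 1L
      if (countdown <= 0L) end_dwell(i)
    }
  }
  # a dwell still open at session end is closed (nest) or dropped (corridor)
  if (length(nest_exit) < length(nest_entry)) nest_exit <- c(nest_exit, n)
  if (length(corr_exit) < length(corr_entry)) {
    corr_entry <- corr_entry[seq_along(corr_exit)]
    corr_side <- corr_side[seq_along(corr_exit)]
  }

  labels <- data.frame(
    frame = seq_len(n) - 1L,
    time_s = time_s,
    explore_left = state == 5L,
    explore_right = state == 6L
  )
  attr(labels, "frame_rate") <- fr
  class(labels) <- c("exploration_series", "data.frame")

  keypoints <- emit_keypoints(state, time_s, config, seeds[2])

  events <- list(
    corridor_visits = data.frame(
      side = c("left", "right")[corr_side],
      entry_time_s = time_s[corr_entry],
      exit_time_s = time_s[corr_exit[seq_along(corr_entry)]]
    ),
    nest_intervals = data.frame(
      entry_time_s = time_s[nest_entry],
      exit_time_s = time_s[nest_exit[seq_along(nest_entry)]]
    )
  )

  structure(list(keypoints = keypoints, labels = labels, schedule = schedule,
                 events = events, states = c("nest", "corridor_left",
                                             "corridor_right", "roam",
                                             "explore_left", "explore_right")[state],
                 truth_params = config),
            class = "nor_session")
}

#' @export
print.nor_session <- function(x, ...) {
  cat(sprintf("<nor_session> %d frames at %g fps; %.1f s exploration (L %.1f / R %.1f)\n",
              nrow(x$labels), x$truth_params$frame_rate,
              (sum(x$labels$explore_left) + sum(x$labels$explore_right)) / x$truth_params$frame_rate,
              sum(x$labels$explore_left) / x$truth_params$frame_rate,
              sum(x$labels$explore_right) / x$truth_params$frame_rate))
  invisible(x)
}

# Build the keypoint table from the state path. Body model: centre c, unit
# heading h; snout = c + 2.2 cm * h, ears straddle c + 1.4 cm * h, three spine
# points and the tail base trail behind. During bouts the snout is placed
# inside the object-access annulus with the head axis at the object.
emit_keypoints <- function(state, time_s, config, seed) {
  set.seed(seed)
  lay <- config$layout
  ppc <- lay$px_per_cm
  n <- length(state)

  # roaming path: reflected random walk over the arena
  step <- 6  # px per frame
  cx <- cumsum(c(runif(1, 0.2, 0.8) * lay$arena_w_px, rnorm(n - 1, 0, step)))
  cy <- cumsum(c(runif(1, 0.2, 0.8) * lay$arena_h_px, rnorm(n - 1, 0, step)))
  reflect <- function(v, lo, hi) {
    v <- (v - lo) %% (2 * (hi - lo))
    lo + ifelse(v > (hi - lo), 2 * (hi - lo) - v, v)
  }
  margin <- 12
  cx <- reflect(cx, margin, lay$arena_w_px - margin)
  cy <- reflect(cy, margin, lay$arena_h_px - margin)

  # pin states to their anchor positions
  jit <- function(k, s) rnorm(k, 0, s)
  idx_nest <- which(state == 1L)
  cx[idx_nest] <- config$nest_position[1] + jit(length(idx_nest), 2)
  cy[idx_nest] <- config$nest_position[2] + jit(length(idx_nest), 2)
  for (s in c(2L, 3L)) {
    anchor <- if (s == 2L) lay$corridor_left else lay$corridor_right
    idx <- which(state == s)
    cx[idx] <- anchor[1] + jit(length(idx), 2)
    cy[idx] <- anchor[2] + jit(length(idx), 2)
  }

  # headings: random-walk angle outside bouts
  theta <- cumsum(rnorm(n, 0, 0.5)) + runif(1, 0, 2 * pi)

  # exploration frames: snout in the access annulus, head axis at the object
  snout_off <- 2.2 * ppc
  for (s in c(5L, 6L)) {
    side <- if (s == 5L) "left" else "right"
    obj <- object_center(lay, side)
    idx <- which(state == s)
    if (!length(idx)) next
    # constant placement within a bout, resampled per bout
    bout_id <- cumsum(c(1L, diff(idx) != 1L))
    nb <- max(bout_id)
    d <- runif(nb, 0.25, 0.55) * lay$object_radius_px
    # approach from inside the arena: half-circle facing inward
    base_ang <- if (side == "left") 0 else pi
    ang <- base_ang + runif(nb, -pi / 3, pi / 3)
    sx <- obj[1] + d * cos(ang)
    sy <- obj[2] + d * sin(ang)
    # head axis = towards the object, with small angular noise
    axis <- atan2(obj[2] - sy, obj[1] - sx) + rnorm(nb, 0, 0.15)
    theta[idx] <- axis[bout_id]
    cx[idx] <- sx[bout_id] - snout_off * cos(axis[bout_id]) + jit(length(idx), 0.5)
    cy[idx] <- sy[bout_id] - snout_off * sin(axis[bout_id]) + jit(length(idx), 0.5)
  }

  hx <- cos(theta); hy <- sin(theta)
  nxv <- -hy; nyv <- hx  # unit normal
  sd_j <- config$keypoint_jitter_px
  part <- function(fwd_cm, lat_cm = 0) {
    list(x = cx + fwd_cm * ppc * hx + lat_cm * ppc * nxv + rnorm(n, 0, sd_j),
         y = cy + fwd_cm * ppc * hy + lat_cm * ppc * nyv + rnorm(n, 0, sd_j))
  }
  parts <- list(
    snout = part(2.2),
    ear_left = part(1.0, -0.75),
    ear_right = part(1.0, 0.75),
    spine_1 = part(0.2),
    spine_2 = part(-1.0),
    spine_3 = part(-2.2),
    tail_base = part(-3.4)
  )
  out <- data.frame(frame = seq_len(n) - 1L, time_s = time_s)
  for (nm in names(parts)) {
    out[[paste0(nm, ".x")]] <- parts[[nm]]$x
    out[[paste0(nm, ".y")]] <- parts[[nm]]$y
    out[[paste0(nm, ".likelihood")]] <- rbeta(n, 20, 1.2)
  }
  attr(out, "frame_rate") <- config$frame_rate
  attr(out, "bodyparts") <- names(parts)
  class(out) <- c("keypoint_track", "data.frame")
  out
}
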