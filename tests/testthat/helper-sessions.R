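# Shared fixtures: short sessions keep the suite fast while preserving the
# generator's structure (all four phases, 2 fps).

short_cfg <- function(seed = 1, ...) {
  session_sim_config(
    phase_durations = c(habituation = 300, sample = 1800,
                        retention = 600, test = 1800),
    seed = seed, ...
  )
}

sim_cohort <- function(n, seed0 = 100, ...) {
  lapply(seq_len(n), function(i) simulate_session(short_cfg(seed = seed0 + i, ...)))
}

.session_cache <- new.env(parent = emptyenv())

default_session <- function() {
  if (is.null(.session_cache$s))
    .session_cache$s <- simulate_session(short_cfg(seed = 42))
  .session_cache$s
}

default_features <- function() {
  if (is.null(.session_cache$f)) {
    s <- default_session()
    .session_cache$f <- extract_features(s$keypoints, s$truth_params$layout)
  }
  .session_cache$f
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# hand-built exploration series on a 2-fps clock
make_series <- function(left, right = rep(FALSE, length(left)), frame_rate = 2) {
  out <- data.frame(frame = seq_along(left) - 1L,
                    time_s = (seq_along(left) - 1L) / frame_rate,
                    explore_left = left, explore_right = right)
  attr(out, "frame_rate") <- frame_rate
  class(out) <- c("exploration_series", "data.frame")
  out
}
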