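#' Simulate annotator label sets with controlled agreement
#'
#' Emulates independent annotators scoring the same session: each annotator
#' selects `round(ss * |truth|)` frames, of which `round(pef * ss * |truth|)`
#' are drawn uniformly without replacement from the true exploratory frames
#' and the remainder from a disjoint pool of non-exploratory frames
#' (near-miss frames in real annotation). `ss` is the annotator's sample size
#' as a fraction of the true count; `pef` is the proportion of the sample that
#' is truly exploratory. Counts use R's round-half-to-even rounding.
#'
#' @param truth_frames integer vector of true exploratory frame indices.
#' @param non_exploratory_pool integer vector of candidate false-positive
#'   frames, disjoint from `truth_frames`.
#' @param ss sample-size fraction (> 0).
#' @param pef proportion of truly exploratory frames in the sample, in (0, 1].
#' @param n_annotators number of independent annotators.
#' @param seed integer seed.
#' @return list of length `n_annotators`; each element an object of class
#'   `annotator_labels`: list with `annotator_id` and sorted integer `frames`.
#' @export
simulate_annotators <- function(truth_frames, non_exploratory_pool,
                                ss, pef, n_annotators = 4, seed = 1L) {
  truth_frames <- unique(as.integer(truth_frames))
  pool <- unique(as.integer(non_exploratory_pool))
  if (length(intersect(truth_frames, pool)))
    stop("truth_frames and non_exploratory_pool must be disjoint")
  if (ss <= 0) stop("ss must be > 0")
  if (pef <= 0 || pef > 1) stop("pef must be in (0, 1]")
  n_truth <- length(truth_frames)
  n_total <- round(ss * n_truth)
  n_true <- round(pef * ss * n_truth)
  if (n_true > n_truth)
    stop(sprintf(
      "parameter error: requested %d true frames but only %d exist (pef * ss must be <= 1)",
      n_true, n_truth))
  n_false <- n_total - n_true
  if (n_false > length(pool))
    stop(sprintf("parameter error: requested %d false frames but pool holds %d",
                 n_false, length(pool)))
  set.seed(as.integer(seed))
  lapply(seq_len(n_annotators), function(a) {
    frames <- c(
      if (n_true > 0) sample(truth_frames, n_true) else integer(0),
      if (n_false > 0) sample(pool, n_false) else integer(0)
    )
    annotator_labels(paste0("A", a), frames)
  })
}

#' Construct an annotator label set
#'
#' @param annotator_id character scalar.
#' @param frames integer vector of frame indices labelled exploratory;
#'   de-duplicated and sorted.
#' @return An object of class `annotator_labels`.
#' @export
annotator_labels <- function(annotator_id, frames) {
  structure(list(annotator_id = as.character(annotator_id),
                 frames = sort(unique(as.integer(frames)))),
            class = "annotator_labels")
}

#' Default non-exploratory pool: frames adjacent to true bouts
#'
#' False positives in real annotation are near-misses, so the default pool
#' for [simulate_annotators()] is the set of frames within `halo` frames of a
#' true exploratory frame that are not themselves true.
#'
#' @param truth_frames integer vector of true exploratory frames.
#' @param halo how many frames on each side of a bout to include.
#' @param n_frames session length (indices are clipped to `[0, n_frames - 1]`).
#' @return integer vector, disjoint from `truth_frames`.
#' @export
adjacent_pool <- function(truth_frames, halo = 10, n_frames = NULL) {
  truth_frames <- unique(as.integer(truth_frames))
  cand <- unique(as.integer(outer(truth_frames, -halo:halo, `+`)))
  cand <- setdiff(cand, truth_frames)
  cand <- cand[cand >= 0]
  if (!is.null(n_frames)) cand <- cand[cand < n_frames]
  sort(cand)
}
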