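#' Train a random-forest exploration classifier
#'
#' Fits an ensemble of decision trees on the posture features to predict the
#' per-frame class (none / exploring left / exploring right). The geometric
#' rule ([rule_classify()]) is transparent but rigid; the forest learns the
#' decision surface from labels and is the production classifier.
#'
#' @param features a `posture_features` data frame.
#' @param labels an `exploration_series` with ground-truth (or annotated)
#'   labels, same length as `features`.
#' @param ntree,mtry forest hyperparameters (passed to
#'   [randomForest::randomForest()]); `mtry = NULL` uses the default.
#' @param seed integer seed; the fit is deterministic under a fixed seed.
#' @return An object of class `exploration_forest`: list with the fitted
#'   `model`, the `feature_names` used, and `oob_error` (out-of-bag).
#' @export
train_forest <- function(features, labels, ntree = 200, mtry = NULL, seed = 1L) {
  stopifnot(nrow(features) == nrow(labels))
  y <- factor(ifelse(labels$explore_left, "left",
                     ifelse(labels$explore_right, "right", "none")),
              levels = c("none", "left", "right"))
  y <- droplevels(y)
  if (nlevels(y) < 2)
    stop("training error: labels contain a single class")
  feature_names <- c("dist_left_cm", "dist_right_cm", "align_left_deg",
                     "align_right_deg", "elongation_cm", "speed_cm_s")
  x <- features[feature_names]
  set.seed(as.integer(seed))
  args <- list(x = x, y = y, ntree = ntree)
  if (!is.null(mtry)) args$mtry <- mtry
  model <- do.call(randomForest::randomForest, args)
  structure(list(model = model,
                 feature_names = feature_names,
                 classes = levels(y),
                 oob_error = unname(model$err.rate[ntree, "OOB"])),
            class = "exploration_forest")
}

#' @export
print.exploration_forest <- function(x, ...) {
  cat(sprintf("<exploration_forest> %d trees, OOB error %.3f\n",
              x$model$ntree, x$oob_error))
  invisible(x)
}

#' Predict per-frame exploration with a trained forest
#'
#' Applies the forest and then post-processes the label sequence: unreliable
#' frames inherit an ongoing bout's label (else none), gaps of up to
#' `close_gaps` frames inside a side's bouts are closed, and bouts shorter
#' than `min_bout` frames are dropped. The defaults (1 and 2 frames) smooth
#' single-frame flicker at 2 fps.
#'
#' @param object an `exploration_forest` from [train_forest()].
#' @param features a `posture_features` data frame with the training schema.
#' @param close_gaps maximum gap (frames) to close within a bout.
#' @param min_bout minimum bout length (frames) to keep.
#' @param ... unused.
#' @return an `exploration_series` data frame.
#' @export
predict.exploration_forest <- function(object, features, close_gaps = 1,
                                       min_bout = 2, ...) {
  missing <- setdiff(object$feature_names, names(features))
  if (length(missing))
    stop("schema mismatch: missing features: ", paste(missing, collapse = ", "))
  n <- nrow(features)
  if (n == 0) {
    out <- data.frame(frame = integer(0), time_s = numeric(0),
                      explore_left = logical(0), explore_right = logical(0))
    class(out) <- c("exploration_series", "data.frame")
    return(out)
  }
  pred <- as.character(predict(object$model, features[object$feature_names]))
  lab <- match(pred, c("none", "left", "right")) - 1L
  unrel <- !features$reliable
  for (i in which(unrel)) {
    lab[i] <- if (i > 1 && lab[i - 1] > 0L) lab[i - 1] else 0L
  }
  for (side in 1:2) lab <- postprocess_side(lab, side, close_gaps, min_bout)
  out <- data.frame(
    frame = features$frame,
    time_s = features$time_s,
    explore_left = lab == 1L,
    explore_right = lab == 2L
  )
  attr(out, "frame_rate") <- attr(features, "frame_rate")
  attr(out, "params") <- list(classifier = "forest",
                              close_gaps = close_gaps, min_bout = min_bout)
  class(out) <- c("exploration_series", "data.frame")
  out
}

# close gaps <= g between same-side runs, then drop runs < b frames
postprocess_side <- function(lab, side, g, b) {
  x <- lab == side
  r <- rle(x)
  if (g > 0 && length(r$lengths) > 2) {
    # a FALSE run of length <= g flanked by TRUE runs becomes TRUE, but only
    # where the gap frames are not claimed by the other side
    for (j in seq_along(r$lengths)[-c(1, length(r$lengths))]) {
      if (!r$values[j] && r$lengths[j] <= g && r$values[j - 1] && r$values[j + 1]) {
        start <- sum(r$lengths[seq_len(j - 1)]) + 1L
        idx <- start:(start + r$lengths[j] - 1L)
        if (all(lab[idx] == 0L)) r$values[j] <- TRUE
      }
    }
    x <- inverse.rle(r)
    r <- rle(x)
  }
  if (b > 1) {
    r$values[r$values & r$lengths < b] <- FALSE
    x <- inverse.rle(r)
  }
  lab[lab == side] <- 0L
  lab[x] <- side
  lab
}

#' Segment an exploration series into bouts
#'
#' A bout is a maximal run of consecutive frames labelled exploratory on the
#' same side. Total bout duration equals the number of true frames times the
#' frame period.
#'
#' @param series an `exploration_series` data frame.
#' @return data frame with columns `side`, `start_s`, `end_s`, `duration_s`
#'   (end is exclusive: `end_s - start_s = duration_s`).
#' @export
segment_bouts <- function(series) {
  fr <- attr(series, "frame_rate") %||% infer_frame_rate(series$time_s)
  dt <- 1 / fr
  one_side <- function(flag, side) {
    r <- rle(flag)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    if (!length(keep))
      return(data.frame(side = character(0), start_s = numeric(0),
                        end_s = numeric(0), duration_s = numeric(0)))
    data.frame(side = side,
               start_s = series$time_s[starts[keep]],
               end_s = series$time_s[ends[keep]] + dt,
               duration_s = r$lengths[keep] * dt)
  }
  out <- rbind(one_side(series$explore_left, "left"),
               one_side(series$explore_right, "right"))
  out <- out[order(out$start_s), , drop = FALSE]
  rownames(out) <- NULL
  out
}
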