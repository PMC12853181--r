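#' Pairwise annotator overlap matrix
#'
#' Agreement between annotators' exploratory-frame sets, as the matrix
#' `M[A, B] = |A intersect B| / |A|`: the fraction of reference annotator A's
#' frames that annotator B also labelled. Rows are the reference annotator,
#' so the matrix is not symmetric, but `M[A,B] * |A| = M[B,A] * |B|` (both
#' equal the intersection count). Empty reference sets give a flagged
#' (all-`NA`) row.
#'
#' @param label_sets list of [annotator_labels()] objects (>= 2).
#' @return An object of class `overlap_matrix`: a numeric matrix with
#'   annotator ids as dimnames and attribute `set_sizes`.
#' @export
empirical_overlap_matrix <- function(label_sets) {
  if (length(label_sets) < 2) stop("need at least two annotator label sets")
  ids <- vapply(label_sets, `[[`, "", "annotator_id")
  if (anyDuplicated(ids)) stop("annotator ids must be unique")
  k <- length(label_sets)
  m <- matrix(NA_real_, k, k, dimnames = list(ids, ids))
  sizes <- vapply(label_sets, function(s) length(s$frames), 0L)
  for (a in seq_len(k)) {
    if (sizes[a] == 0) next  # flagged row
    for (b in seq_len(k)) {
      m[a, b] <- length(intersect(label_sets[[a]]$frames,
                                  label_sets[[b]]$frames)) / sizes[a]
    }
  }
  structure(m, set_sizes = setNames(sizes, ids), class = c("overlap_matrix", "matrix"))
}

#' Consensus counts across annotator label sets
#'
#' How many frames were labelled exploratory by at least one annotator
#' (union), by all annotators (full consensus), and what fraction of the
#' union the consensus represents. Optionally, how much of the consensus a
#' further label set (e.g. the automated classifier) captures.
#'
#' @param label_sets list of [annotator_labels()] (>= 2).
#' @param reference_set optional [annotator_labels()] checked against the
#'   consensus.
#' @return list `union_count`, `all_count`, `fraction_all`,
#'   `agreement_profile` (table of how many sets labelled each union frame),
#'   and, when `reference_set` is given, `captured_count` /
#'   `fraction_captured` (consensus frames also in the reference set) and
#'   `reference_within_union` (fraction of reference frames inside the union).
#' @export
consensus_counts <- function(label_sets, reference_set = NULL) {
  if (length(label_sets) < 2) stop("need at least two annotator label sets")
  all_frames <- lapply(label_sets, `[[`, "frames")
  u <- Reduce(union, all_frames)
  inter <- Reduce(intersect, all_frames)
  votes <- table(factor(
    rowSums(vapply(all_frames, function(f) u %in% f, logical(length(u)))),
    levels = seq_along(label_sets)))
  out <- list(union_count = length(u), all_count = length(inter),
              fraction_all = if (length(u)) length(inter) / length(u) else NA_real_,
              agreement_profile = votes)
  if (!is.null(reference_set)) {
    cap <- length(intersect(inter, reference_set$frames))
    out$captured_count <- cap
    out$fraction_captured <- if (length(inter)) cap / length(inter) else NA_real_
    out$reference_within_union <-
      if (length(reference_set$frames))
        length(intersect(reference_set$frames, u)) / length(reference_set$frames)
      else NA_real_
  }
  out
}

#' Expected overlap between two simulated annotators
#'
#' Under the agreement model, an annotator's sample holds
#' `Nexp = round(pef * ss * N)` of the `N` true exploratory frames, drawn
#' uniformly; false-positive frames never coincide between annotators. The
#' expected overlap between two independent annotators, normalized by the
#' sample size `ss * N`, is estimated by Monte Carlo as
#' `mean(|T1 intersect T2|) / (ss * N)`. Its closed form is `pef^2 * ss`
#' (hypergeometric expectation `Nexp^2 / N`, divided by `ss * N`).
#'
#' @param ss sample-size fraction.
#' @param pef proportion of truly exploratory frames in the sample.
#' @param N number of true exploratory instances.
#' @param reps Monte-Carlo replicates; the default keeps the standard error
#'   below half a percentage point even at N = 500.
#' @param seed integer seed.
#' @return numeric scalar in `[0, 1]`.
#' @export
expected_overlap <- function(ss, pef, N, reps = 200, seed = 1L) {
  if (N < 1) stop("N must be >= 1")
  if (reps < 1) stop("reps must be >= 1")
  n_exp <- round(pef * ss * N)
  if (n_exp > N) {
    warning("pef * ss exceeds 1; true-frame count capped at N")
    n_exp <- N
  }
  if (n_exp == 0) return(0)
  set.seed(as.integer(seed))
  ov <- vapply(seq_len(reps), function(r) {
    t1 <- sample.int(N, n_exp)
    t2 <- sample.int(N, n_exp)
    length(intersect(t1, t2))
  }, 0L)
  mean(ov) / (ss * N)
}

#' Expected-overlap grid over the (ss, pef) parameter space
#'
#' Evaluates [expected_overlap()] on a grid of sample-size fractions and
#' exploratory-frame proportions, for each assumed true instance count `N`.
#' The overlap depends on N only through rounding and the cap, so the maximum
#' absolute difference between the N-layers is reported; across the stated
#' N range (500 to 13,600 instances) it stays within a few percentage points.
#'
#' @param ss_grid,pef_grid numeric grids (defaults span 50-150% and 50-100%).
#' @param N_grid true-instance counts (default `c(500, 13600)`).
#' @param reps Monte-Carlo replicates per cell.
#' @param seed integer seed.
#' @return list `grid` (3-d array ss x pef x N, dimnames set),
#'   `max_between_N_diff`, and the grids used.
#' @export
overlap_grid <- function(ss_grid = seq(0.5, 1.5, by = 0.1),
                         pef_grid = seq(0.5, 1.0, by = 0.05),
                         N_grid = c(500, 13600),
                         reps = 200, seed = 1L) {
  seeds <- derive_seeds(seed, length(ss_grid) * length(pef_grid) * length(N_grid))
  arr <- array(NA_real_,
               dim = c(length(ss_grid), length(pef_grid), length(N_grid)),
               dimnames = list(ss = ss_grid, pef = pef_grid, N = N_grid))
  k <- 0L
  for (i in seq_along(ss_grid)) for (j in seq_along(pef_grid)) for (l in seq_along(N_grid)) {
    k <- k + 1L
    arr[i, j, l] <- suppressWarnings(
      expected_overlap(ss_grid[i], pef_grid[j], N_grid[l],
                       reps = reps, seed = seeds[k]))
  }
  max_diff <- if (length(N_grid) > 1) {
    combs <- utils::combn(length(N_grid), 2)
    max(apply(combs, 2, function(cc) max(abs(arr[, , cc[1]] - arr[, , cc[2]]))))
  } else 0
  list(grid = arr, max_between_N_diff = max_diff,
       ss_grid = ss_grid, pef_grid = pef_grid, N_grid = N_grid)
}

#' Admissible (ss, pef) region given empirically observed overlaps
#'
#' Marks the grid cells whose expected overlap falls within the range of the
#' observed pairwise overlaps, i.e. the model parameters consistent with the
#' measured annotator agreement.
#'
#' @param grid result of [overlap_grid()].
#' @param observed_overlaps numeric vector of observed pairwise overlap
#'   fractions in `[0, 1]` (e.g. off-diagonal entries of
#'   [empirical_overlap_matrix()]).
#' @param tol widening of the observed range, absorbing the Monte-Carlo noise
#'   of the grid cells; without it a single observed value would almost never
#'   coincide exactly with a simulated cell.
#' @return list `region` (logical ss x pef matrix, TRUE = admissible, using
#'   the mean over N layers), `lo`, `hi`, `empty` (flag).
#' @export
region_from_empirical <- function(grid, observed_overlaps, tol = 0.01) {
  observed_overlaps <- observed_overlaps[is.finite(observed_overlaps)]
  if (!length(observed_overlaps) || any(observed_overlaps < 0 | observed_overlaps > 1))
    stop("observed overlaps must be in [0, 1]")
  lo <- min(observed_overlaps); hi <- max(observed_overlaps)
  mean_grid <- apply(grid$grid, c(1, 2), mean)
  region <- mean_grid >= lo - tol & mean_grid <= hi + tol
  if (!any(region)) warning("no (ss, pef) cell matches the observed overlap range")
  list(region = region, lo = lo, hi = hi, empty = !any(region))
}

#' Surrogate discrimination-index distribution under annotation variability
#'
#' Models how annotator sampling variability propagates into the
#' discrimination index. Each surrogate draws two sample-size fractions
#' SS1, SS2 independently and uniformly from `ss_draw_range`; with the novel
#' side explored `f` times more, the surrogate DI is
#' \deqn{DI = (f \cdot SS_1 - SS_2) / (f \cdot SS_1 + SS_2)}
#' (the true instance count N cancels, as does pef). With SS1 = SS2 and
#' f = 1.67 the DI is (f-1)/(f+1) = 0.2509. The returned summaries include
#' the 1st percentile (an alpha = 0.01 bound) and the fraction of negative
#' surrogate DIs (false-negative recognition calls).
#'
#' @param ss_draw_range length-2 numeric, bounds of the uniform SS draw.
#' @param f novel:familiar exploration factor (default 1.67).
#' @param n_surrogates number of surrogates (default 1000).
#' @param seed integer seed.
#' @return list `di` (numeric vector), `percentile_1`, `fraction_negative`,
#'   `min_possible` (DI at SS1 = lower bound, SS2 = upper bound) and
#'   `analytic_fraction_negative` (exact probability that
#'   `f * SS1 < SS2` under the uniform draws).
#' @export
surrogate_di_distribution <- function(ss_draw_range = c(0.5, 1.5), f = 1.67,
                                      n_surrogates = 1000, seed = 1L) {
  if (length(ss_draw_range) != 2 || any(ss_draw_range <= 0) ||
      ss_draw_range[1] > ss_draw_range[2])
    stop("ss_draw_range must be positive and increasing")
  if (n_surrogates < 1) stop("n_surrogates must be >= 1")
  if (f <= 0) stop("f must be > 0")
  set.seed(as.integer(seed))
  ss1 <- runif(n_surrogates, ss_draw_range[1], ss_draw_range[2])
  ss2 <- runif(n_surrogates, ss_draw_range[1], ss_draw_range[2])
  di <- (f * ss1 - ss2) / (f * ss1 + ss2)
  list(di = di,
       percentile_1 = unname(quantile(di, 0.01, type = 7)),
       fraction_negative = mean(di < 0),
       min_possible = (f * ss_draw_range[1] - ss_draw_range[2]) /
         (f * ss_draw_range[1] + ss_draw_range[2]),
       analytic_fraction_negative =
         uniform_negative_fraction(ss_draw_range, f))
}

# P(f * SS1 < SS2) with SS1, SS2 ~ U(lo, hi), by exact integration of the
# triangular region above the line ss2 = f * ss1.
uniform_negative_fraction <- function(range, f) {
  lo <- range[1]; hi <- range[2]
  if (f * lo >= hi) return(0)
  if (f * hi <= lo) return(1)
  # integrate P(SS2 > f*s) over s in [lo, min(hi, hi/f)]
  upper <- min(hi, hi / f)
  lower <- max(lo, lo / f)
  # for s < lo/f, P = 1; for s in [lower, upper], P = (hi - f*s)/(hi - lo)
  width <- hi - lo
  part_full <- max(0, lower - lo) / width
  a <- lower; b <- upper
  part_lin <- (hi * (b - a) - f * (b^2 - a^2) / 2) / width^2
  part_full + part_lin
}
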