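#' Statistical test wrappers used across the pipeline
#'
#' Thin, uniformly-shaped wrappers around the standard tests the analyses
#' report: paired and one-sample t tests, Pearson correlation, exact binomial
#' test, Shapiro-Wilk normality, Benjamini-Hochberg adjustment, and a
#' three-way fixed-effects ANOVA (facility x object x side) with Type II sums
#' of squares so unbalanced cohorts are handled; in balanced designs the
#' types coincide. Degenerate inputs (n < 2, zero variance) are flagged
#' rather than raised.
#'
#' @param x,y numeric vectors.
#' @param mu null value for the one-sample test.
#' @return a one-row data frame: `test`, `statistic`, `df`, `p_value`,
#'   `flagged`.
#' @name stats_suite
NULL

flag_row <- function(test) data.frame(test = test, statistic = NA_real_,
                                      df = NA_real_, p_value = NA_real_,
                                      flagged = TRUE)

#' @rdname stats_suite
#' @export
paired_t <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2 || sd(x - y) == 0) return(flag_row("paired_t"))
  tt <- t.test(x, y, paired = TRUE)
  data.frame(test = "paired_t", statistic = unname(tt$statistic),
             df = unname(tt$parameter), p_value = tt$p.value, flagged = FALSE)
}

#' @rdname stats_suite
#' @export
one_sample_t <- function(x, mu = 0) {
  x <- x[is.finite(x)]
  if (length(x) < 2 || sd(x) == 0) return(flag_row("one_sample_t"))
  tt <- t.test(x, mu = mu)
  data.frame(test = "one_sample_t", statistic = unname(tt$statistic),
             df = unname(tt$parameter), p_value = tt$p.value, flagged = FALSE)
}

#' @rdname stats_suite
#' @export
two_sample_t <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2 || (sd(x) == 0 && sd(y) == 0))
    return(flag_row("two_sample_t"))
  tt <- t.test(x, y)
  data.frame(test = "two_sample_t", statistic = unname(tt$statistic),
             df = unname(tt$parameter), p_value = tt$p.value, flagged = FALSE)
}

#' @rdname stats_suite
#' @export
pearson_test <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3 || sd(x) == 0 || sd(y) == 0) return(flag_row("pearson"))
  ct <- cor.test(x, y, method = "pearson")
  out <- data.frame(test = "pearson", statistic = unname(ct$statistic),
                    df = unname(ct$parameter), p_value = ct$p.value,
                    flagged = FALSE)
  out$r <- unname(ct$estimate)
  out
}

#' @rdname stats_suite
#' @param n_success,n_trials counts for the exact binomial test.
#' @param alternative sidedness of the binomial test.
#' @export
exact_binomial <- function(n_success, n_trials, mu = 0.5,
                           alternative = "greater") {
  if (n_trials < 1) return(flag_row("binomial"))
  bt <- binom.test(n_success, n_trials, p = mu, alternative = alternative)
  data.frame(test = "binomial", statistic = n_success / n_trials,
             df = n_trials, p_value = bt$p.value, flagged = FALSE)
}

#' @rdname stats_suite
#' @export
shapiro_wilk <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3 || sd(x) == 0) return(flag_row("shapiro_wilk"))
  sw <- shapiro.test(x)
  data.frame(test = "shapiro_wilk", statistic = unname(sw$statistic),
             df = length(x), p_value = sw$p.value, flagged = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' The adjustment family is the set of p-values reported together in one
#' analysis table.
#'
#' @param p numeric vector of raw p-values.
#' @return adjusted p-values, same length.
#' @export
bh_adjust <- function(p) p.adjust(p, method = "BH")

#' Three-way fixed-effects ANOVA on exploration time
#'
#' Fits `value ~ facility * object * side` and returns the Type II ANOVA
#' table (car::Anova), the design used to check for object-preference and
#' side biases across facilities.
#'
#' @param data data frame with columns `value`, `facility`, `object`, `side`.
#' @return data frame with `term`, `sum_sq`, `df`, `F`, `p_value`.
#' @export
three_way_anova <- function(data) {
  needed <- c("value", "facility", "object", "side")
  if (!all(needed %in% names(data)))
    stop("data must have columns value, facility, object, side")
  data$facility <- factor(data$facility)
  data$object <- factor(data$object)
  data$side <- factor(data$side)
  fit <- lm(value ~ facility * object * side, data = data)
  tab <- car::Anova(fit, type = 2)
  data.frame(term = rownames(tab), sum_sq = tab[["Sum Sq"]],
             df = tab[["Df"]], F = tab[["F value"]], p_value = tab[["Pr(>F)"]],
             row.names = NULL)
}
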