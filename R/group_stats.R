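#' One-tailed Mann-Whitney comparison of abnormality indices
#'
#' Rank-based test of whether one group's indices tend to exceed the
#' other's. Uses the exact null distribution when the pooled sample is small
#' (n_a + n_b <= 12) and tie-free, and the tie-corrected normal
#' approximation with continuity correction otherwise.
#'
#' @param a,b Numeric index vectors for the two groups.
#' @param alternative `"a-greater"` (default) or `"b-greater"`.
#' @param labels Length-2 character vector naming the groups of `a` and `b`.
#' @return A `comparison_report`: list with `contrast`, `U` (Mann-Whitney
#'   statistic for the first sample), `p` (one-tailed), `medians`,
#'   `direction`, `n`.
#' @export
mann_whitney_one_tailed <- function(a, b,
                                    alternative = c("a-greater", "b-greater"),
                                    labels = c("a", "b")) {
  alternative <- match.arg(alternative)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L) stop("both groups must be nonempty")
  exact <- (length(a) + length(b) <= 12L) &&
    !anyDuplicated(c(a, b))
  wt <- suppressWarnings(stats::wilcox.test(
    a, b,
    alternative = if (alternative == "a-greater") "greater" else "less",
    exact = exact, correct = TRUE
  ))
  structure(list(
    contrast = sprintf("%s-vs-%s", labels[1], labels[2]),
    U = as.numeric(wt$statistic),
    p = as.numeric(wt$p.value),
    medians = c(stats::median(a), stats::median(b)),
    direction = alternative,
    n = c(length(a), length(b)),
    method = if (exact) "exact" else "normal-approximation"
  ), class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> %s (%s): U = %g, one-tailed p = %.4g\n",
              x$contrast, x$direction, x$U, x$p))
  cat(sprintf("  medians: %.4g vs %.4g (n = %d + %d, %s)\n",
              x$medians[1], x$medians[2], x$n[1], x$n[2], x$method))
  invisible(x)
}

#' Compare abnormality indices between the two groups of a protocol run
#'
#' Convenience wrapper: one-tailed Mann-Whitney with the case group (first
#' label) hypothesised to have the GREATER median index.
#'
#' @param results Data frame with `group` and `abnormality_index`.
#' @param groups Length-2 character vector, case group first; defaults to
#'   the order of appearance.
#' @return A `comparison_report`.
#' @export
compare_groups <- function(results, groups = NULL) {
  if (is.null(groups)) groups <- unique(results$group)
  stopifnot(length(groups) == 2L)
  a <- results$abnormality_index[results$group == groups[1]]
  b <- results$abnormality_index[results$group == groups[2]]
  mann_whitney_one_tailed(a, b, "a-greater", labels = groups)
}

#' Sex confound check on abnormality indices
#'
#' Two-tailed Mann-Whitney of the indices split by sex.
#'
#' @param results Data frame with `abnormality_index`.
#' @param manifest Data frame with `subject_id` and `sex`.
#' @return Two-tailed p-value.
#' @export
sex_effect_test <- function(results, manifest) {
  sex <- manifest$sex[match(results$subject_id, manifest$subject_id)]
  lev <- unique(stats::na.omit(sex))
  if (length(lev) < 2L) stop("both sexes must be present for the sex check")
  if (length(lev) > 2L) stop("more than two sex levels found")
  x <- results$abnormality_index[sex == lev[1]]
  y <- results$abnormality_index[sex == lev[2]]
  as.numeric(suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", correct = TRUE)
  )$p.value)
}

#' Quadratic age confound check on abnormality indices
#'
#' Least-squares fit of index = b0 + b1 age + b2 age^2 and the overall
#' F-test of (b1, b2) = 0. Invariant to centring or rescaling age.
#'
#' @param results Data frame with `abnormality_index`.
#' @param manifest Data frame with `subject_id` and `age`.
#' @return List with `p` (overall F-test p-value), `coefficients`, and the
#'   fitted `lm` object.
#' @export
age_effect_quadratic <- function(results, manifest) {
  age <- manifest$age[match(results$subject_id, manifest$subject_id)]
  idx <- results$abnormality_index
  if (length(idx) < 4L) stop("need at least 4 subjects for the quadratic fit")
  if (stats::var(age) == 0) stop("age has zero variance")
  if (length(unique(age)) < 3L) stop("quadratic design is degenerate (fewer than 3 distinct ages)")
  fit <- stats::lm(idx ~ age + I(age^2))
  fs <- summary(fit)$fstatistic
  p <- as.numeric(stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE))
  list(p = p, coefficients = stats::coef(fit), fit = fit)
}
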