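#' Time of divergence between two groups of traces
#'
#' The pooled per-cell values of the two groups are compared at each
#' timepoint with the two-sided Wilcoxon rank-sum test; the time of
#' divergence is the first timepoint after which ALL subsequent p-values
#' (including the final one) are less than or equal to `alpha`. The exact
#' null distribution is used for combined samples of up to
#' `exact_max_n` observations (small per-group cell counts dominate such
#' data); larger samples use the normal approximation with tie and
#' continuity correction.
#'
#' @param group_a,group_b matrices (cells x timepoints) on a common time
#'   grid, or long data.frames with columns `cell_id`, `time_s`, `value`.
#' @param times_s time grid (required for matrix input; ignored for long
#'   input, where the grids must match).
#' @param alpha significance level.
#' @param exact_max_n combined-sample cutoff for the exact test.
#' @return list of class `divergence_result`: `times_s`, `p_values`,
#'   `alpha`, `divergence_time_s` (`NA` if never), `diverged`, `test`.
#' @export
time_of_divergence <- function(group_a, group_b, times_s = NULL,
                               alpha = 0.05, exact_max_n = 16L) {
  ga <- .as_trace_matrix(group_a, times_s)
  gb <- .as_trace_matrix(group_b, times_s)
  if (!isTRUE(all.equal(ga$times_s, gb$times_s)))
    stop("groups must share a common time grid")
  times_s <- ga$times_s
  a <- ga$values; b <- gb$values
  if (nrow(a) < 2L || nrow(b) < 2L)
    stop("need at least 2 observations per group per timepoint")
  nt <- length(times_s)
  p <- vapply(seq_len(nt), function(j) {
    av <- a[, j][is.finite(a[, j])]; bv <- b[, j][is.finite(b[, j])]
    if (length(av) < 2L || length(bv) < 2L) return(NA_real_)
    suppressWarnings(stats::wilcox.test(
      av, bv, alternative = "two.sided",
      exact = (length(av) + length(bv)) <= exact_max_n,
      correct = TRUE)$p.value)
  }, numeric(1L))
  ok <- !is.na(p) & p <= alpha
  # first T such that every t >= T is significant
  all_after <- rev(cumprod(rev(ok))) > 0
  div_idx <- if (any(all_after)) which(all_after)[1L] else NA_integer_
  structure(list(times_s = times_s, p_values = p, alpha = alpha,
                 divergence_time_s = if (is.na(div_idx)) NA_real_
                   else times_s[div_idx],
                 diverged = !is.na(div_idx),
                 test = "two-sided Wilcoxon rank-sum per timepoint"),
            class = "divergence_result")
}

#' @export
print.divergence_result <- function(x, ...) {
  cat(sprintf("divergence_result (%s, alpha = %g)\n", x$test, x$alpha))
  if (x$diverged)
    cat(sprintf("  time of divergence: %g s\n", x$divergence_time_s))
  else cat("  no divergence: later p-values rise above alpha\n")
  invisible(x)
}

.as_trace_matrix <- function(g, times_s = NULL) {
  if (is.matrix(g)) {
    if (is.null(times_s)) stop("`times_s` required for matrix input")
    if (ncol(g) != length(times_s))
      stop("matrix columns must match the time grid")
    return(list(values = g, times_s = as.numeric(times_s)))
  }
  if (is.data.frame(g)) {
    stopifnot(all(c("cell_id", "time_s", "value") %in% names(g)))
    tt <- sort(unique(g$time_s))
    cells <- unique(g$cell_id)
    mat <- matrix(NA_real_, length(cells), length(tt),
                  dimnames = list(cells, NULL))
    mat[cbind(match(g$cell_id, cells), match(g$time_s, tt))] <- g$value
    return(list(values = mat, times_s = tt))
  }
  stop("groups must be matrices or long data.frames")
}

#' Test whether two groups' regression slopes differ
#'
#' Pooled linear model `y ~ t * group`; the two-sided p-value of the
#' group-by-time interaction term tests equality of slopes (the classic
#' equal-slopes ANCOVA test).
#'
#' @param points_a,points_b data.frames (or 2-column matrices) of `(t, y)`
#'   points, at least 3 per group.
#' @return list: `p_value`, `slope_difference`, `se`.
#' @export
compare_slopes <- function(points_a, points_b) {
  pa <- .as_ty(points_a); pb <- .as_ty(points_b)
  if (nrow(pa) < 3L || nrow(pb) < 3L) stop("need >= 3 points per group")
  df <- rbind(cbind(pa, g = 0), cbind(pb, g = 1))
  if (length(unique(df$t)) < 2L) stop("degenerate design: constant time")
  fit <- stats::lm(y ~ t * g, data = df)
  sm <- suppressWarnings(summary(fit))
  cf <- sm$coefficients
  if (!"t:g" %in% rownames(cf)) stop("degenerate design")
  est <- cf["t:g", "Estimate"]; se <- cf["t:g", "Std. Error"]
  p <- cf["t:g", "Pr(>|t|)"]
  y_scale <- max(stats::sd(df$y), 1e-300)
  if (!is.finite(p) || sm$sigma < 1e-10 * y_scale) {
    # (numerically) zero residual variance: identical groups give p = 1,
    # exactly separated slopes p -> 0
    slope_scale <- max(abs(stats::coef(fit)["t"]), y_scale)
    p <- if (abs(est) < 1e-10 * slope_scale) 1 else 0
  }
  list(p_value = p, slope_difference = est, se = se)
}

.as_ty <- function(p) {
  if (is.matrix(p)) p <- as.data.frame(p)
  if (!all(c("t", "y") %in% names(p))) {
    stopifnot(ncol(p) >= 2L)
    names(p)[1:2] <- c("t", "y")
  }
  data.frame(t = as.numeric(p$t), y = as.numeric(p$y))
}

#' One-sample t-test against a normalised mean of 100%
#'
#' Two-sided one-sample Student's t-test of percent values against
#' `mu0 = 100` - used for conditions normalised to a wild-type mean of
#' 100%.
#'
#' @param values numeric vector (n >= 2).
#' @param mu0 null mean (default 100).
#' @return list: `t`, `p_value`, `df`, `degenerate` (`TRUE` when the
#'   sample has zero variance away from `mu0`, where p collapses to 0).
#' @export
one_sample_t_norm100 <- function(values, mu0 = 100) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) stop("need n >= 2")
  s <- stats::sd(values)
  if (s == 0) {
    if (mean(values) == mu0)
      return(list(t = 0, p_value = 1, df = length(values) - 1L,
                  degenerate = FALSE))
    return(list(t = sign(mean(values) - mu0) * Inf, p_value = 0,
                df = length(values) - 1L, degenerate = TRUE))
  }
  ht <- stats::t.test(values, mu = mu0, alternative = "two.sided")
  list(t = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter), degenerate = FALSE)
}

#' Two-sample t-test of experiment means
#'
#' Two-sided unpaired Student's t-test (equal-variance form by default,
#' matching the convention of comparing per-experiment means; Welch and a
#' Mann-Whitney rank-sum alternative are available).
#'
#' @param means_a,means_b numeric vectors (n >= 2 each).
#' @param method `"student"` (default), `"welch"`, or `"mann-whitney"`.
#' @return list: `statistic`, `p_value`, `df` (`NA` for the rank test),
#'   `method`.
#' @export
two_sample_t <- function(means_a, means_b,
                         method = c("student", "welch", "mann-whitney")) {
  method <- match.arg(method)
  a <- means_a[is.finite(means_a)]; b <- means_b[is.finite(means_b)]
  if (length(a) < 2L || length(b) < 2L) stop("need n >= 2 per group")
  if (method == "mann-whitney") {
    ht <- suppressWarnings(stats::wilcox.test(a, b,
                                              alternative = "two.sided"))
    return(list(statistic = unname(ht$statistic), p_value = ht$p.value,
                df = NA_real_, method = method))
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    eq <- mean(a) == mean(b)
    return(list(statistic = if (eq) 0 else sign(mean(a) - mean(b)) * Inf,
                p_value = if (eq) 1 else 0, df = NA_real_, method = method))
  }
  ht <- stats::t.test(a, b, var.equal = (method == "student"),
                      alternative = "two.sided")
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter), method = method)
}

#' F-test comparing two variances
#'
#' `F = s^2_larger / s^2_smaller` with the two-sided p-value from the F
#' distribution at the corresponding degrees of freedom; invariant to the
#' group order.
#'
#' @param values_a,values_b numeric vectors (n >= 2 each).
#' @return list: `F`, `p_value`, `df` (numerator, denominator).
#' @export
variance_f_test <- function(values_a, values_b) {
  a <- values_a[is.finite(values_a)]; b <- values_b[is.finite(values_b)]
  if (length(a) < 2L || length(b) < 2L) stop("need n >= 2 per group")
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) stop("zero variance in both groups")
  if (va >= vb) {
    f <- va / vb; df <- c(length(a) - 1L, length(b) - 1L)
  } else {
    f <- vb / va; df <- c(length(b) - 1L, length(a) - 1L)
  }
  pr <- stats::pf(f, df[1L], df[2L])
  list(F = f, p_value = min(1, 2 * min(pr, 1 - pr)), df = df)
}
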