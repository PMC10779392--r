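#' Two-sample t-test
#'
#' Classic two-sample t on raw samples: pooled variance with
#' df = n_a + n_b - 2 by default (the convention of the MATLAB-style
#' two-sample test used throughout), or Welch-Satterthwaite. When the
#' larger sample variance exceeds the smaller by more than 4x under the
#' pooled mode a note is emitted, since the pooled assumption is then
#' doubtful.
#'
#' @param a,b numeric samples, each of length >= 2.
#' @param variance `"pooled"` (default) or `"welch"`.
#' @return List with `estimate` (mean difference a - b), `se`,
#'   `statistic` (t), `df`, `p` (two-sided), `n` (per-group sizes).
#' @export
two_sample_ttest <- function(a, b, variance = c("pooled", "welch")) {
  variance <- match.arg(variance)
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs at least 2 observations", call. = FALSE)
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("samples must be finite", call. = FALSE)
  va <- stats::var(a)
  vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b))
      return(list(estimate = 0, se = 0, statistic = 0,
                  df = length(a) + length(b) - 2, p = 1,
                  n = c(length(a), length(b))))
    stop("degenerate samples: zero variance with unequal means",
         call. = FALSE)
  }
  if (variance == "pooled" && min(va, vb) > 0 &&
      max(va, vb) / min(va, vb) > 4)
    message("note: sample variance ratio ",
            signif(max(va, vb) / min(va, vb), 3),
            " > 4; consider variance = 'welch'")
  ht <- stats::t.test(a, b, var.equal = (variance == "pooled"))
  list(estimate = mean(a) - mean(b),
       se = unname(ht$stderr),
       statistic = unname(ht$statistic),
       df = unname(ht$parameter),
       p = ht$p.value,
       n = c(length(a), length(b)))
}

#' Pearson correlation with t-transform p-value
#'
#' @param x,y numeric vectors of equal length >= 3, non-constant.
#' @return List with `estimate` (r), `r_squared`, `statistic` (t), `df`
#'   (n - 2), `p` (two-sided), `n`.
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) stop("lengths differ", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input", call. = FALSE)
  ht <- stats::cor.test(x, y)
  list(estimate = unname(ht$estimate),
       r_squared = unname(ht$estimate)^2,
       statistic = unname(ht$statistic),
       df = unname(ht$parameter), p = ht$p.value, n = length(x))
}

#' Pearson chi-square test on a 2x2 table
#'
#' No continuity correction (the default convention here); expected
#' counts are reported and a warning is emitted when any expected count
#' falls below 5.
#'
#' @param table 2x2 matrix of counts with positive margins.
#' @return List with `statistic` (chi-square), `df` (1), `p`,
#'   `expected` (2x2 matrix).
#' @export
chi_square_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)))
    stop("table must be 2x2", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero margin in 2x2 table", call. = FALSE)
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(expected < 5))
    warning("expected count below 5; chi-square approximation is weak",
            call. = FALSE)
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, expected = expected)
}

#' Percent reduction of a treated group relative to control
#'
#' Estimate `100 * (mean_control - mean_treated) / mean_control` with a
#' delta-method standard error for the ratio of independent sample
#' means, and a p-value from the two-sample t-test on the raw samples.
#'
#' @param control,treated numeric samples, each of length >= 2; the
#'   control mean must be nonzero.
#' @param variance passed to [two_sample_ttest()].
#' @return List with `percent_reduction`, `se_percent`, `statistic` (t),
#'   `df`, `p`, `n`.
#' @export
relative_reduction <- function(control, treated,
                               variance = c("pooled", "welch")) {
  mc <- mean(control)
  mt <- mean(treated)
  if (mc == 0) stop("zero control mean", call. = FALSE)
  # delta method for R = mt/mc with independent means:
  # var(R) ~ var(mt)/mc^2 + mt^2 var(mc)/mc^4
  var_mc <- stats::var(control) / length(control)
  var_mt <- stats::var(treated) / length(treated)
  se_ratio <- sqrt(var_mt / mc^2 + mt^2 * var_mc / mc^4)
  tt <- if (stats::var(control) == 0 && stats::var(treated) == 0 &&
            mc != mt) {
    # deterministic difference: the reduction is exact
    list(statistic = sign(mc - mt) * Inf,
         df = length(control) + length(treated) - 2, p = 0,
         n = c(length(control), length(treated)))
  } else {
    two_sample_ttest(control, treated, variance)
  }
  list(percent_reduction = 100 * (mc - mt) / mc,
       se_percent = 100 * se_ratio,
       statistic = tt$statistic, df = tt$df, p = tt$p, n = tt$n)
}
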