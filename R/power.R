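# A-priori power and sample size for a two-group comparison of mean
# damage percentages.

#' Power of the two-sided two-sample pooled-variance t-test
#'
#' Exact power via the noncentral t distribution: with `n` per group the
#' test statistic has `2n - 2` degrees of freedom and noncentrality
#' `delta / (sd * sqrt(2 / n))`; both rejection tails are included.
#'
#' @param n_per_group observations per group, `>= 2`.
#' @param delta true difference in group means (percentage points).
#' @param sd common within-group standard deviation, `> 0`.
#' @param alpha two-sided significance level, in (0, 1); default 0.05.
#' @return the power, in (0, 1).
#' @examples
#' t_test_power(n_per_group = 5, delta = 18, sd = 8.5)
#' @export
t_test_power <- function(n_per_group, delta, sd, alpha = 0.05) {
  if (!is.numeric(n_per_group) || n_per_group < 2 ||
      n_per_group != floor(n_per_group)) {
    stop("'n_per_group' must be an integer >= 2", call. = FALSE)
  }
  if (!is.numeric(sd) || sd <= 0) stop("'sd' must be positive", call. = FALSE)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("'alpha' must lie in (0, 1)", call. = FALSE)
  }
  df <- 2 * n_per_group - 2
  ncp <- delta / (sd * sqrt(2 / n_per_group))
  tcrit <- stats::qt(1 - alpha / 2, df)
  (1 - stats::pt(tcrit, df, ncp)) + stats::pt(-tcrit, df, ncp)
}

#' Smallest per-group sample size reaching a target power
#'
#' Increment search over `n` starting at 2; power is strictly increasing in
#' `n`, so the first `n` with power at or above the target is the minimum.
#'
#' @param target_power desired power, in `(alpha, 1)`.
#' @param delta true difference in group means; must be nonzero.
#' @param sd common within-group standard deviation.
#' @param alpha two-sided significance level (default 0.05).
#' @param n_max search cap; exceeding it raises an error.
#' @return the smallest integer `n_per_group` with
#'   `t_test_power(n, delta, sd, alpha) >= target_power`.
#' @examples
#' sample_size_for_power(0.80, delta = 18, sd = 8.5) # 5
#' @export
sample_size_for_power <- function(target_power, delta, sd, alpha = 0.05,
                                  n_max = 1e6L) {
  if (!is.numeric(target_power) || target_power <= alpha || target_power >= 1) {
    stop("'target_power' must lie in (alpha, 1)", call. = FALSE)
  }
  if (delta == 0) {
    stop("target power is unreachable with delta = 0 (power equals alpha)",
         call. = FALSE)
  }
  n <- 2L
  while (t_test_power(n, delta, sd, alpha) < target_power) {
    n <- n + 1L
    if (n > n_max) {
      stop("target power not reached within n_max per group", call. = FALSE)
    }
  }
  n
}
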