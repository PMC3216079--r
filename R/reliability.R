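# Inter-/intra-observer reliability of damage percentages.

#' Intraclass correlation, two-way random effects, absolute agreement,
#' single measure
#'
#' Computes ICC(2,1) from the closed-form two-way ANOVA decomposition of a
#' complete subjects x raters matrix:
#' \deqn{ICC(2,1) = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' with \eqn{MS_R} the between-subject, \eqn{MS_C} the between-rater and
#' \eqn{MS_E} the residual mean square, \eqn{n} subjects and \eqn{k} raters.
#' This variant treats raters as a random sample of interchangeable assessors
#' and penalizes systematic rater offsets (absolute agreement).
#'
#' Negative estimates are reported as computed, not truncated to zero. When
#' the matrix has zero total variance the raters agree exactly and the ICC is
#' defined as 1, with a warning; when the between-subject sum of squares is
#' zero but cells vary, the estimate is degenerate and flagged.
#'
#' @param ratings numeric matrix (or data frame) of damage percentages,
#'   subjects as rows and raters as columns; at least 2 x 2, no missing
#'   cells.
#' @return a list of class `"icc_result"` with elements `icc`, `ms` (the
#'   three mean squares), `n_subjects`, `n_raters`, `degenerate` and `model`.
#' @examples
#' m <- cbind(r1 = c(10, 20, 30, 40), r2 = c(12, 19, 33, 38))
#' icc_single_rater(m)$icc
#' @export
icc_single_rater <- function(ratings) {
  x <- as.matrix(ratings)
  if (!is.numeric(x)) stop("ratings must be numeric", call. = FALSE)
  if (anyNA(x)) stop("ratings must have no missing cells", call. = FALSE)
  n <- nrow(x); k <- ncol(x)
  if (n < 2L || k < 2L) {
    stop("need at least 2 subjects and 2 raters", call. = FALSE)
  }
  gm <- mean(x)
  ssr <- k * sum((rowMeans(x) - gm)^2)
  ssc <- n * sum((colMeans(x) - gm)^2)
  sst <- sum((x - gm)^2)
  sse <- max(0, sst - ssr - ssc)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))

  degenerate <- FALSE
  if (sst == 0) {
    warning("zero total variance: raters agree exactly; ICC defined as 1")
    icc <- 1
    degenerate <- TRUE
  } else if (ssr == 0) {
    warning("no between-subject variance: ICC estimate is degenerate")
    degenerate <- TRUE
    icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  } else {
    icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  }
  structure(list(icc = icc,
                 ms = list(subjects = msr, raters = msc, residual = mse),
                 n_subjects = n, n_raters = k, degenerate = degenerate,
                 model = "ICC(2,1): two-way random effects, absolute agreement, single measure"),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc_result> ICC(2,1) = %.4f  (%d subjects x %d raters%s)\n",
              x$icc, x$n_subjects, x$n_raters,
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' Simulate independent raters re-segmenting a set of slices
#'
#' Emulates independent assessors repeating the semi-automatic measurement:
#' each rater re-samples their own training regions on every fixture (with a
#' rater-specific seed) and re-runs the full segmentation. The resulting
#' subjects x raters matrix of damage percentages feeds
#' [icc_single_rater()].
#'
#' @param fixtures list of `"slice_fixture"` objects (the subjects).
#' @param rater_seeds integer vector, one seed per rater.
#' @param n_regions,region_size training-region sampling parameters
#'   (defaults: 10 regions of 10 x 10 pixels per class).
#' @param k SD multiplier for the class models (default 1.7).
#' @return numeric matrix of damage percentages, fixtures as rows and raters
#'   as columns.
#' @export
simulate_raters <- function(fixtures, rater_seeds, n_regions = 10L,
                            region_size = 10L, k = 1.7) {
  stopifnot(is.list(fixtures), length(fixtures) >= 1L,
            length(rater_seeds) >= 1L)
  out <- matrix(NA_real_, nrow = length(fixtures), ncol = length(rater_seeds),
                dimnames = list(paste0("slice", seq_along(fixtures)),
                                paste0("rater", seq_along(rater_seeds))))
  for (j in seq_along(rater_seeds)) {
    for (i in seq_along(fixtures)) {
      fx <- fixtures[[i]]
      seed_ij <- (as.numeric(rater_seeds[j]) * 1009 + i * 7919) %%
        .Machine$integer.max
      res <- tryCatch({
        rs <- generate_training_regions(fx, n_regions = n_regions,
                                        region_size = region_size,
                                        seed = seed_ij)
        segment_slice(fx$image, rs, fx$bbox, k = k)
      }, error = function(e) {
        stop(sprintf("fixture %d, rater %d: %s", i, j, conditionMessage(e)),
             call. = FALSE)
      })
      out[i, j] <- res$damage_pct
    }
  }
  out
}
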