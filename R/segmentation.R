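# Color-class segmentation of stained cross-section photographs.
#
# The damaged (yellow) and undamaged (blue) stains are each modelled by
# per-channel RGB means and standard deviations estimated from small
# training regions. A pixel belongs to a class when every channel lies
# within mean +/- k*SD of that class (k = 1.7 by default); the damage
# percentage is the yellow share of all colored pixels inside the
# segmentation bounding box.

#' Fit a per-channel RGB color-class model from training regions
#'
#' Pools the pixels of all supplied regions and computes the per-channel mean
#' and sample standard deviation (n - 1 denominator). The model is invariant
#' to how the same pixel multiset is split into regions.
#'
#' @param image 8-bit RGB array (height x width x 3, values 0..255).
#' @param regions non-empty list of [region()]s, all inside the image.
#' @param class_label `"yellow"` or `"blue"`.
#' @param k half-width of the acceptance interval in SD units (default 1.7).
#' @return a list of class `"color_class_model"` with elements `class_label`,
#'   `mean` and `sd` (RGB triples), `k` and `n_pixels`.
#' @export
fit_color_class <- function(image, regions, class_label = c("yellow", "blue"),
                            k = 1.7) {
  class_label <- match.arg(class_label)
  check_slice_image(image)
  if (!is.list(regions) || length(regions) == 0L) {
    stop("'regions' must be a non-empty list of regions", call. = FALSE)
  }
  if (!is.numeric(k) || k <= 0) stop("'k' must be positive", call. = FALSE)
  h <- dim(image)[1]; w <- dim(image)[2]
  pix <- do.call(rbind, lapply(regions, function(r) {
    stopifnot(inherits(r, "region"))
    check_region_inside(r, w, h, "training region")
    sub <- image[region_rows(r), region_cols(r), , drop = FALSE]
    matrix(sub, ncol = 3L)
  }))
  structure(list(class_label = class_label,
                 mean = colMeans(pix),
                 sd = apply(pix, 2L, stats::sd),
                 k = k,
                 n_pixels = nrow(pix)),
            class = "color_class_model")
}

#' @export
print.color_class_model <- function(x, ...) {
  cat(sprintf("<color_class_model> %s: mean (%.1f, %.1f, %.1f), sd (%.2f, %.2f, %.2f), k = %g, n = %d px\n",
              x$class_label, x$mean[1], x$mean[2], x$mean[3],
              x$sd[1], x$sd[2], x$sd[3], x$k, x$n_pixels))
  invisible(x)
}

# Squared sd-normalized distance of each pixel (rows of `pix`) to a class
# mean. Channels with zero SD contribute 0 when the pixel equals the mean
# exactly and Inf otherwise.
normalized_dist2 <- function(pix, model) {
  d <- numeric(nrow(pix))
  for (ch in 1:3) {
    m <- model$mean[ch]; s <- model$sd[ch]
    if (s > 0) {
      d <- d + ((pix[, ch] - m) / s)^2
    } else {
      d <- d + ifelse(pix[, ch] == m, 0, Inf)
    }
  }
  d
}

#' Classify pixels in a bounding box against two color-class models
#'
#' A pixel matches a class when every channel value lies in
#' `[mean - k*sd, mean + k*sd]` for that class (a channel with zero SD
#' matches only exact equality). Pixels matching exactly one class receive
#' that label; pixels matching both are assigned to the class with the
#' smaller sd-normalized Euclidean distance to the class mean, with ties
#' going to yellow and counted; pixels matching neither are uncolored.
#'
#' @param image 8-bit RGB array.
#' @param bbox [region()] to classify, inside the image.
#' @param yellow,blue fitted [fit_color_class()] models sharing the same `k`.
#' @return an integer matrix of class `"label_map"` over the bounding box
#'   (1 = yellow, 2 = blue, 0 = uncolored) with attributes `bbox`, `n_both`
#'   (pixels matching both class boxes) and `n_ties`.
#' @export
classify_pixels <- function(image, bbox, yellow, blue) {
  check_slice_image(image)
  stopifnot(inherits(yellow, "color_class_model"),
            inherits(blue, "color_class_model"))
  if (!isTRUE(all.equal(yellow$k, blue$k))) {
    stop("yellow and blue models must share the same k multiplier", call. = FALSE)
  }
  h <- dim(image)[1]; w <- dim(image)[2]
  stopifnot(inherits(bbox, "region"))
  check_region_inside(bbox, w, h, "bounding box")

  sub <- image[region_rows(bbox), region_cols(bbox), , drop = FALSE]
  pix <- matrix(sub, ncol = 3L)
  in_box <- function(model) {
    ok <- rep(TRUE, nrow(pix))
    for (ch in 1:3) {
      lo <- model$mean[ch] - model$k * model$sd[ch]
      hi <- model$mean[ch] + model$k * model$sd[ch]
      ok <- ok & pix[, ch] >= lo & pix[, ch] <= hi
    }
    ok
  }
  in_y <- in_box(yellow); in_b <- in_box(blue)
  both <- in_y & in_b
  lab <- integer(nrow(pix))
  lab[in_y & !in_b] <- 1L
  lab[in_b & !in_y] <- 2L
  n_ties <- 0L
  if (any(both)) {
    dy <- normalized_dist2(pix[both, , drop = FALSE], yellow)
    db <- normalized_dist2(pix[both, , drop = FALSE], blue)
    lab[both] <- ifelse(dy <= db, 1L, 2L)
    n_ties <- sum(dy == db)
  }
  structure(matrix(lab, nrow = bbox$h, ncol = bbox$w),
            class = "label_map", bbox = bbox,
            n_both = sum(both), n_ties = n_ties)
}

#' Damage percentage from a label map
#'
#' The damaged share of the cross-section is the percentage of yellow pixels
#' among all colored (yellow + blue) pixels; uncolored pixels are excluded
#' from the denominator and reported for quality control.
#'
#' @param labels a `"label_map"` from [classify_pixels()].
#' @return a list of class `"segmentation_result"` with pixel counts
#'   `n_yellow`, `n_blue`, `n_uncolored`, `n_both`, `n_ties`, the exact
#'   `damage_pct`, its integer-rounded `damage_pct_rounded`, and `bbox`.
#' @export
damage_percentage <- function(labels) {
  stopifnot(inherits(labels, "label_map"))
  n_yellow <- sum(labels == 1L)
  n_blue <- sum(labels == 2L)
  if (n_yellow + n_blue == 0L) {
    stop("no colored pixels in the bounding box: damage percentage is undefined",
         call. = FALSE)
  }
  pct <- 100 * n_yellow / (n_yellow + n_blue)
  structure(list(n_yellow = n_yellow, n_blue = n_blue,
                 n_uncolored = sum(labels == 0L),
                 n_both = attr(labels, "n_both"),
                 n_ties = attr(labels, "n_ties"),
                 damage_pct = pct,
                 damage_pct_rounded = round(pct),
                 bbox = attr(labels, "bbox")),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> damage %.2f%% (yellow %d / colored %d px; %d uncolored, %d both-class)\n",
              x$damage_pct, x$n_yellow, x$n_yellow + x$n_blue,
              x$n_uncolored, x$n_both))
  invisible(x)
}

#' Segment a stained slice end to end
#'
#' Composes the full measurement: fit the yellow and blue color-class models
#' from their training regions, classify every pixel in the bounding box, and
#' report the damage percentage together with the fitted models and
#' quality-control counts.
#'
#' @param image 8-bit RGB array.
#' @param regions a `"region_set"` (from [generate_training_regions()] or
#'   built manually) with `yellow_regions` and `blue_regions`.
#' @param bbox [region()] delimiting the cross-section.
#' @param k SD multiplier shared by both class models (default 1.7).
#' @return a `"segmentation_result"` (see [damage_percentage()]) with the
#'   fitted `models` attached.
#' @examples
#' fx <- generate_slice_image(simulation_params(
#'   width = 140, height = 140, semi_axes = c(60, 55),
#'   true_fraction = 0.35, noise_sd = 0, seed = 1))
#' rs <- generate_training_regions(fx, n_regions = 5, region_size = 8, seed = 2)
#' segment_slice(fx$image, rs, fx$bbox)
#' @export
segment_slice <- function(image, regions, bbox, k = 1.7) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  yellow <- stage("fit_color_class/yellow",
                  fit_color_class(image, regions$yellow_regions, "yellow", k))
  blue <- stage("fit_color_class/blue",
                fit_color_class(image, regions$blue_regions, "blue", k))
  labels <- stage("classify_pixels", classify_pixels(image, bbox, yellow, blue))
  res <- stage("damage_percentage", damage_percentage(labels))
  res$models <- list(yellow = yellow, blue = blue)
  res
}
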