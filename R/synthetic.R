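# Synthetic stained-slice fixtures with known ground truth.
#
# Real inputs are photographs of formalin-fixed muscle cross-sections in
# which damaged tissue was painted yellow and undamaged tissue blue. No such
# photographs are published, so every downstream stage is exercised on
# synthetic slices: a convex (elliptical) cross-section split into a
# contiguous damaged angular sector of known area fraction, with iid
# per-channel Gaussian color noise over flat base colors.

#' Parameters for a synthetic stained-slice image
#'
#' @param width,height canvas size in pixels.
#' @param center ellipse center `c(x, y)` in pixel coordinates (0-based).
#'   Defaults to the canvas center.
#' @param semi_axes ellipse semi-axes `c(a, b)` in pixels (a along x).
#' @param true_fraction target damaged fraction of the stained cross-section,
#'   in `[0, 1]`.
#' @param base_yellow,base_blue,base_background RGB triples in `[0, 255]` for
#'   the damaged stain, undamaged stain and background.
#' @param noise_sd per-channel Gaussian noise standard deviation in 8-bit
#'   intensity units; `>= 0`.
#' @param seed integer seed; fixtures are bit-identical for identical
#'   parameters and seed.
#' @return a list of class `"simulation_params"`.
#' @export
simulation_params <- function(width = 320L, height = 320L,
                              center = c((width - 1) / 2, (height - 1) / 2),
                              semi_axes = c(150, 130),
                              true_fraction = 0.35,
                              base_yellow = c(200, 180, 40),
                              base_blue = c(40, 60, 190),
                              base_background = c(245, 245, 245),
                              noise_sd = 8,
                              seed = 1L) {
  p <- list(width = as.integer(width), height = as.integer(height),
            center = as.numeric(center), semi_axes = as.numeric(semi_axes),
            true_fraction = true_fraction,
            base_yellow = as.numeric(base_yellow),
            base_blue = as.numeric(base_blue),
            base_background = as.numeric(base_background),
            noise_sd = noise_sd, seed = as.integer(seed))
  validate_simulation_params(p)
  structure(p, class = "simulation_params")
}

validate_simulation_params <- function(p) {
  if (p$width < 1L || p$height < 1L) stop("canvas must be non-empty", call. = FALSE)
  if (!is.numeric(p$true_fraction) || p$true_fraction < 0 || p$true_fraction > 1) {
    stop("true_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (p$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  for (nm in c("base_yellow", "base_blue", "base_background")) {
    v <- p[[nm]]
    if (length(v) != 3L || any(v < 0) || any(v > 255)) {
      stop(sprintf("%s must be an RGB triple in [0, 255]", nm), call. = FALSE)
    }
  }
  if (length(p$semi_axes) != 2L || any(p$semi_axes <= 0)) {
    stop("semi_axes must be two positive numbers", call. = FALSE)
  }
  # the ellipse must fit on the canvas
  if (p$center[1] - p$semi_axes[1] < 0 || p$center[1] + p$semi_axes[1] > p$width - 1 ||
      p$center[2] - p$semi_axes[2] < 0 || p$center[2] + p$semi_axes[2] > p$height - 1) {
    stop("ellipse does not fit inside the canvas", call. = FALSE)
  }
  invisible(TRUE)
}

#' Generate a synthetic stained cross-sectional slice
#'
#' Renders an elliptical muscle cross-section on a plain background. The
#' damaged region is a contiguous angular sector of the ellipse whose pixel
#' count is `round(true_fraction * n_stained)`, so the realized fraction is
#' within one pixel-quantization step of the target. Colors are the base RGB
#' triples plus iid per-channel Gaussian noise, clipped to `[0, 255]` and
#' rounded to 8-bit.
#'
#' @param params a [simulation_params()] object.
#' @return an object of class `"slice_fixture"`: a list with elements
#'   `image` (height x width x 3 integer array, 0..255), `truth`
#'   (height x width integer matrix: 0 background, 1 damaged, 2 undamaged),
#'   `true_fraction` (realized damaged fraction, an exact pixel-count ratio),
#'   `bbox` (tight [region()] around the stained cross-section) and `params`.
#' @examples
#' fx <- generate_slice_image(simulation_params(
#'   width = 80, height = 80, semi_axes = c(30, 25),
#'   true_fraction = 0.4, noise_sd = 0, seed = 1))
#' fx$true_fraction
#' @export
generate_slice_image <- function(params) {
  if (!inherits(params, "simulation_params")) params <- do.call(simulation_params, params)
  validate_simulation_params(params)
  w <- params$width; h <- params$height
  cx <- params$center[1]; cy <- params$center[2]
  a <- params$semi_axes[1]; b <- params$semi_axes[2]

  # pixel (x, y) = (col, row), 0-based
  xs <- matrix(rep(0:(w - 1L), each = h), nrow = h)
  ys <- matrix(rep(0:(h - 1L), times = w), nrow = h)
  inside <- ((xs - cx) / a)^2 + ((ys - cy) / b)^2 <= 1

  truth <- matrix(LABEL_BACKGROUND, nrow = h, ncol = w)
  idx <- which(inside)
  n_stained <- length(idx)
  if (n_stained == 0L) stop("ellipse covers no pixels", call. = FALSE)

  n_damaged <- round(params$true_fraction * n_stained)
  # contiguous angular sector: order stained pixels by angle about the center
  ang <- atan2(ys[idx] - cy, xs[idx] - cx)
  ord <- order(ang, idx)
  truth[idx] <- LABEL_UNDAMAGED
  if (n_damaged > 0L) truth[idx[ord[seq_len(n_damaged)]]] <- LABEL_DAMAGED

  img <- array(0, dim = c(h, w, 3L))
  base <- list(params$base_background, params$base_yellow, params$base_blue)
  for (ch in 1:3) {
    plane <- matrix(0, nrow = h, ncol = w)
    plane[truth == LABEL_BACKGROUND] <- base[[1]][ch]
    plane[truth == LABEL_DAMAGED] <- base[[2]][ch]
    plane[truth == LABEL_UNDAMAGED] <- base[[3]][ch]
    img[, , ch] <- plane
  }
  if (params$noise_sd > 0) {
    z <- with_seed(params$seed, stats::rnorm(length(img)))
    img <- img + params$noise_sd * array(z, dim = dim(img))
  }
  img <- array(as.integer(round(pmin(255, pmax(0, img)))), dim = dim(img))

  rows <- range(ys[idx]); cols <- range(xs[idx])
  bbox <- region(cols[1], rows[1], cols[2] - cols[1] + 1L, rows[2] - rows[1] + 1L)

  structure(list(image = img, truth = truth,
                 true_fraction = sum(truth == LABEL_DAMAGED) /
                   sum(truth != LABEL_BACKGROUND),
                 bbox = bbox, params = params),
            class = "slice_fixture")
}

#' @export
print.slice_fixture <- function(x, ...) {
  cat(sprintf("<slice_fixture> %dx%d px, stained %d px, damaged fraction %.4f\n",
              x$params$width, x$params$height,
              sum(x$truth != LABEL_BACKGROUND), x$true_fraction))
  invisible(x)
}

# Admissible top-left corners for a pure s x s window inside a binary mask,
# found with an integral image. Returns a 2-column matrix of 0-based (x, y).
admissible_corners <- function(mask, s) {
  h <- nrow(mask); w <- ncol(mask)
  if (h < s || w < s) return(matrix(integer(0), ncol = 2))
  # summed-area table padded with a leading zero row/column
  sat <- matrix(0, nrow = h + 1L, ncol = w + 1L)
  sat[-1L, -1L] <- apply(apply(mask, 2L, cumsum), 1L, cumsum) |> t()
  r0 <- 1L:(h - s + 1L); c0 <- 1L:(w - s + 1L)
  win <- sat[r0 + s, c0 + s, drop = FALSE] - sat[r0, c0 + s, drop = FALSE] -
    sat[r0 + s, c0, drop = FALSE] + sat[r0, c0, drop = FALSE]
  full <- which(win == s * s, arr.ind = TRUE)
  cbind(x = full[, 2L] - 1L, y = full[, 1L] - 1L)
}

#' Sample pure training regions from a fixture
#'
#' Mimics the manual step of picking small single-stain sample patches on a
#' photograph: for each stain class, square regions are drawn uniformly at
#' random among all placements that lie entirely inside that class's truth
#' area (so regions contain no pixels of the other class or background), and
#' kept only if they do not overlap a previously kept region of the same
#' class.
#'
#' @param fixture a `"slice_fixture"` from [generate_slice_image()].
#' @param n_regions regions per class (default 10).
#' @param region_size side length in pixels of each square region (default 10).
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return a list of class `"region_set"` with elements `yellow_regions` and
#'   `blue_regions` (lists of [region()]s) and `region_size`.
#' @export
generate_training_regions <- function(fixture, n_regions = 10L,
                                      region_size = 10L, seed = 1L) {
  stopifnot(inherits(fixture, "slice_fixture"))
  if (n_regions < 1L || region_size < 1L) {
    stop("n_regions and region_size must be positive", call. = FALSE)
  }
  sample_class <- function(label, class_name, offset) {
    corners <- admissible_corners(fixture$truth == label, region_size)
    if (nrow(corners) < n_regions) {
      stop(sprintf(
        "%s class area is too small: only %d admissible %dx%d placements for %d regions",
        class_name, nrow(corners), region_size, region_size, n_regions),
        call. = FALSE)
    }
    ord <- with_seed(seed + offset, sample.int(nrow(corners)))
    kept <- list()
    for (i in ord) {
      cand <- region(corners[i, "x"], corners[i, "y"], region_size, region_size)
      clash <- any(vapply(kept, function(r) {
        cand$x < r$x + r$w && r$x < cand$x + cand$w &&
          cand$y < r$y + r$h && r$y < cand$y + cand$h
      }, logical(1)))
      if (!clash) kept[[length(kept) + 1L]] <- cand
      if (length(kept) == n_regions) break
    }
    if (length(kept) < n_regions) {
      stop(sprintf("%s class area is too small: could not place %d non-overlapping regions",
                   class_name, n_regions), call. = FALSE)
    }
    kept
  }
  structure(list(
    yellow_regions = sample_class(LABEL_DAMAGED, "yellow (damaged)", 0L),
    blue_regions = sample_class(LABEL_UNDAMAGED, "blue (undamaged)", 1L),
    region_size = as.integer(region_size)),
    class = "region_set")
}

#' Simulate a study-level damage table
#'
#' Emulates the shape of a per-hip damage matrix (hips x approaches): each
#' group's values are drawn from a normal distribution centered on its stated
#' median, truncated to `[0, 100]` by rejection, and rounded to integer
#' percent.
#'
#' @param group_medians numeric vector of target group medians (percent).
#' @param spread common standard deviation of the draw (percentage points).
#' @param n_per_group observations per group (`>= 2`).
#' @param seed integer seed.
#' @param approaches optional character vector of group labels.
#' @return a [damage_table()].
#' @export
generate_study_table <- function(group_medians, spread, n_per_group, seed = 1L,
                                 approaches = NULL) {
  if (any(group_medians < 0 | group_medians > 100)) {
    stop("group medians must lie in [0, 100]", call. = FALSE)
  }
  if (spread < 0 || spread > 100) stop("spread must lie in [0, 100]", call. = FALSE)
  if (n_per_group < 2L) stop("n_per_group must be >= 2", call. = FALSE)
  if (is.null(approaches)) approaches <- paste0("group", seq_along(group_medians))
  draw_group <- function(m) {
    if (spread == 0) return(rep(round(m), n_per_group))
    out <- numeric(0)
    while (length(out) < n_per_group) {
      x <- stats::rnorm(2L * n_per_group, mean = m, sd = spread)
      out <- c(out, x[x >= 0 & x <= 100])
    }
    round(out[seq_len(n_per_group)])
  }
  values <- with_seed(seed, lapply(group_medians, draw_group))
  names(values) <- approaches
  damage_table(values)
}
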