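# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded fixture generation never
#' disturbs the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Axis-aligned pixel region
#'
#' Constructs a rectangular pixel region. Coordinates are 0-based and
#' half-open throughout the package: the region covers columns
#' `[x, x + w)` and rows `[y, y + h)`, with `x` the column and `y` the row.
#'
#' @param x,y top-left corner (0-based; `x` = column, `y` = row).
#' @param w,h width and height in pixels; both must be positive.
#' @return an object of class `"region"`.
#' @examples
#' region(5, 5, 10, 10)
#' @export
region <- function(x, y, w, h) {
  vals <- c(x = x, y = y, w = w, h = h)
  if (any(!is.finite(vals)) || any(vals != floor(vals))) {
    stop("region coordinates must be finite integers", call. = FALSE)
  }
  if (w <= 0 || h <= 0) stop("region extents must be positive", call. = FALSE)
  if (x < 0 || y < 0) stop("region corner must be non-negative", call. = FALSE)
  structure(list(x = as.integer(x), y = as.integer(y),
                 w = as.integer(w), h = as.integer(h)),
            class = "region")
}

#' @export
print.region <- function(x, ...) {
  cat(sprintf("<region> x=%d y=%d w=%d h=%d (0-based, half-open)\n",
              x$x, x$y, x$w, x$h))
  invisible(x)
}

# 1-based row/column index vectors covered by a region.
region_rows <- function(r) (r$y + 1L):(r$y + r$h)
region_cols <- function(r) (r$x + 1L):(r$x + r$w)

# Stop unless the region lies fully inside an image of the given size.
check_region_inside <- function(r, width, height, what = "region") {
  if (r$x + r$w > width || r$y + r$h > height) {
    stop(sprintf("%s (x=%d, y=%d, w=%d, h=%d) extends outside the %dx%d image",
                 what, r$x, r$y, r$w, r$h, width, height), call. = FALSE)
  }
  invisible(TRUE)
}

# Stop unless `img` is an 8-bit RGB array (height x width x 3, values 0..255).
check_slice_image <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L) {
    stop("image must be a height x width x 3 RGB array", call. = FALSE)
  }
  if (min(img) < 0 || max(img) > 255) {
    stop("image channel values must lie in [0, 255]", call. = FALSE)
  }
  invisible(TRUE)
}

# Truth-label codes used by the synthetic module.
LABEL_BACKGROUND <- 0L
LABEL_DAMAGED <- 1L
LABEL_UNDAMAGED <- 2L
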