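# Shared I/O: rasters, tables, fixture serialization and the top-level
# pipeline entry point.

#' Load a slice photograph as an 8-bit RGB array
#'
#' Reads PNG or TIFF rasters. Images are converted to 8-bit RGB: an alpha
#' channel is dropped, 16-bit TIFF samples are rescaled by integer division
#' by 256, and grayscale inputs are rejected because the stain classes live
#' in color space. Embedded ICC profiles / color management are deliberately
#' ignored; channel values are used as stored.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @return integer array, height x width x 3, values 0..255.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = round(png::readPNG(path) * 255),
    tif = ,
    tiff = {
      x <- tiff::readTIFF(path, info = TRUE)
      bits <- attr(x, "bits.per.sample")
      if (is.null(bits)) bits <- 8L
      # recover stored integer samples from the normalized [0, 1] values;
      # 16-bit samples are rescaled to 8-bit by integer division by 256
      n <- round(x * (2^bits - 1))
      if (bits > 8L) n %/% 2^(bits - 8L) else n
    },
    stop(sprintf("unsupported image format '.%s' (PNG and TIFF are supported)",
                 ext), call. = FALSE)
  )
  if (length(dim(img)) == 2L || dim(img)[3] < 3L) {
    stop("grayscale images are not supported: stain classes require RGB",
         call. = FALSE)
  }
  img <- img[, , 1:3, drop = FALSE] # drop alpha if present
  array(as.integer(img), dim = dim(img))
}

#' Write an 8-bit RGB array as PNG
#'
#' @param image integer array, height x width x 3, values 0..255.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  check_slice_image(image)
  png::writePNG(image / 255, path)
  invisible(path)
}

#' Load a per-hip damage table from CSV
#'
#' Expects a header row naming the approaches and one row per hip; an
#' optional leading `Hip` identifier column is dropped. Every cell must be a
#' number in `[0, 100]`; violations are reported with their row and column.
#'
#' @param path path to the CSV file.
#' @return a [damage_table()] with one group per approach column.
#' @export
load_damage_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (file.size(path) == 0L) stop("empty damage table", call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) == 0L || ncol(df) == 0L) stop("empty damage table", call. = FALSE)
  if (tolower(names(df)[1]) == "hip") df <- df[, -1L, drop = FALSE]
  for (j in seq_along(df)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v) | v < 0 | v > 100)
    if (length(bad)) {
      stop(sprintf("invalid damage value at row %d, column '%s': %s",
                   bad[1], names(df)[j], df[[j]][bad[1]]), call. = FALSE)
    }
    df[[j]] <- v
  }
  damage_table(as.list(df))
}

#' Load dichotomous structure records from CSV
#'
#' Reads a wide table (one row per structure, one count column per approach,
#' plus `structure` and optional `category`/`state` columns) into the long
#' record format used by [tabulate_dichotomous()].
#'
#' @param path path to the CSV file.
#' @return data frame with columns `structure`, `category` (if present),
#'   `state` (if present), `approach`, `count`.
#' @export
load_dichotomous_records <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  id_cols <- intersect(c("structure", "category", "state"), names(df))
  count_cols <- setdiff(names(df), id_cols)
  long <- do.call(rbind, lapply(count_cols, function(cc) {
    out <- df[id_cols]
    out$approach <- cc
    out$count <- as.numeric(df[[cc]])
    out
  }))
  rownames(long) <- NULL
  long
}

# Run-length encode an integer matrix column-major (for compact JSON truth).
rle_encode <- function(m) {
  r <- rle(as.integer(m))
  list(nrow = nrow(m), ncol = ncol(m),
       lengths = r$lengths, values = r$values)
}

rle_decode <- function(enc) {
  matrix(inverse.rle(list(lengths = enc$lengths, values = as.integer(enc$values))),
         nrow = enc$nrow, ncol = enc$ncol)
}

#' Write a slice fixture to a directory
#'
#' Serializes the fixture as plain files: `image.png`, run-length encoded
#' truth labels in `truth.json`, and `meta.json` holding the simulation
#' parameters, bounding box and realized damaged fraction.
#'
#' @param fixture a `"slice_fixture"`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  stopifnot(inherits(fixture, "slice_fixture"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_image(fixture$image, file.path(dir, "image.png"))
  jsonlite::write_json(rle_encode(fixture$truth), file.path(dir, "truth.json"))
  meta <- list(params = unclass(fixture$params),
               bbox = unclass(fixture$bbox),
               true_fraction = fixture$true_fraction)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a slice fixture written by [write_fixture()]
#'
#' @param dir fixture directory.
#' @return a `"slice_fixture"`.
#' @export
load_fixture <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  truth <- rle_decode(jsonlite::read_json(file.path(dir, "truth.json"),
                                          simplifyVector = TRUE))
  bb <- meta$bbox
  structure(list(image = load_image(file.path(dir, "image.png")),
                 truth = truth,
                 true_fraction = meta$true_fraction,
                 bbox = region(bb$x, bb$y, bb$w, bb$h),
                 params = structure(meta$params, class = "simulation_params")),
            class = "slice_fixture")
}

#' Path to a packaged data fixture
#'
#' @param name file name under the package's `extdata` directory, e.g.
#'   `"table1.csv"`.
#' @return absolute path to the installed fixture.
#' @export
stainseg_fixture <- function(name) {
  p <- system.file("extdata", name, package = "stainseg", mustWork = FALSE)
  if (!nzchar(p)) stop(sprintf("no packaged fixture named '%s'", name), call. = FALSE)
  p
}

#' Run the full demonstration pipeline
#'
#' Executes every stage on a single configuration: simulate a stained slice
#' and segment it; summarize a per-hip damage table (the packaged gluteus
#' medius table by default) with medians, ranges and the joint
#' Kruskal-Wallis test; compute the Bonferroni-adjusted threshold; and run
#' the a-priori power calculation. All intermediate numbers are returned in
#' one report, and the effective configuration is written next to the
#' outputs so any result can be regenerated from it.
#'
#' @param config list of settings; missing entries take the defaults of
#'   `list(seed = 1, true_fraction = 0.35, noise_sd = 8, k = 1.7,
#'   n_regions = 10, region_size = 10, table_path = NULL, alpha = 0.05,
#'   m = 5, power_n = 5, power_delta = 18, power_sd = 8.5, out_dir = NULL)`.
#'   With `out_dir` set, `report.json` and `config.json` are written there.
#' @return the report, a nested list, invisibly when written to disk.
#' @export
run_pipeline <- function(config = list()) {
  defaults <- list(seed = 1L, true_fraction = 0.35, noise_sd = 8, k = 1.7,
                   n_regions = 10L, region_size = 10L, table_path = NULL,
                   alpha = 0.05, m = 5L,
                   power_n = 5L, power_delta = 18, power_sd = 8.5,
                   out_dir = NULL)
  config <- utils::modifyList(defaults, config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  fx <- stage("simulate", generate_slice_image(simulation_params(
    true_fraction = config$true_fraction, noise_sd = config$noise_sd,
    seed = config$seed)))
  rs <- stage("regions", generate_training_regions(
    fx, n_regions = config$n_regions, region_size = config$region_size,
    seed = config$seed + 1L))
  seg <- stage("segment", segment_slice(fx$image, rs, fx$bbox, k = config$k))

  table_path <- if (is.null(config$table_path)) {
    stainseg_fixture("table1.csv")
  } else config$table_path
  tab <- stage("load_table", load_damage_table(table_path))
  summ <- stage("summarize", summarize_groups(tab))
  kw <- stage("kruskal_wallis", kruskal_wallis(tab))

  report <- list(
    segmentation = list(
      true_fraction = fx$true_fraction,
      damage_pct = seg$damage_pct,
      damage_pct_rounded = seg$damage_pct_rounded,
      n_yellow = seg$n_yellow, n_blue = seg$n_blue,
      n_uncolored = seg$n_uncolored, n_both = seg$n_both,
      models = lapply(seg$models, function(m)
        list(mean = m$mean, sd = m$sd, k = m$k, n_pixels = m$n_pixels))),
    group_summary = summ,
    kruskal_wallis = kw,
    bonferroni_threshold = bonferroni_threshold(config$alpha, config$m),
    power = list(
      n_per_group = config$power_n, delta = config$power_delta,
      sd = config$power_sd, alpha = config$alpha,
      power = t_test_power(config$power_n, config$power_delta,
                           config$power_sd, config$alpha),
      n_for_80pct = sample_size_for_power(0.80, config$power_delta,
                                          config$power_sd, config$alpha)))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    jsonlite::write_json(config[!vapply(config, is.null, logical(1))],
                         file.path(config$out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(report))
  }
  report
}
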