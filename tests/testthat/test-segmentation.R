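# Color-class fitting, the per-pixel rule, and end-to-end recovery.

test_that("a constant-color patch yields its color as mean with zero sd", {
  img <- array(0L, dim = c(40, 40, 3))
  img[, , 1] <- 200L; img[, , 2] <- 180L; img[, , 3] <- 40L
  m <- fit_color_class(img, list(region(5, 5, 10, 10)), "yellow")
  expect_equal(unname(m$mean), c(200, 180, 40))
  expect_equal(unname(m$sd), c(0, 0, 0))
  expect_identical(m$n_pixels, 100L)
})

test_that("model fitting pools pixels: two disjoint halves equal one covering region", {
  fx <- small_fixture(true_fraction = 0.5, noise_sd = 12, seed = 41)
  whole <- fit_color_class(fx$image, list(region(10, 10, 20, 10)), "blue")
  halves <- fit_color_class(fx$image, list(region(10, 10, 10, 10),
                                           region(20, 10, 10, 10)), "blue")
  expect_equal(whole$mean, halves$mean)
  expect_equal(whole$sd, halves$sd)
})

test_that("pooled-region sd estimates recover the generating noise level", {
  fx <- small_fixture(true_fraction = 0.5, noise_sd = 8, seed = 42)
  rs <- generate_training_regions(fx, n_regions = 10, region_size = 10, seed = 43)
  for (regions in list(rs$yellow_regions, rs$blue_regions)) {
    m <- fit_color_class(fx$image, regions, "yellow")
    # n = 1000 pooled pixels; chi-square spread of an SD estimate is well
    # under 25% there (rounding to 8-bit adds a little)
    expect_true(all(abs(m$sd - 8) / 8 < 0.25))
  }
})

test_that("fitting rejects empty region lists and out-of-image regions", {
  fx <- small_fixture()
  expect_error(fit_color_class(fx$image, list(), "yellow"), "non-empty")
  expect_error(fit_color_class(fx$image, list(region(115, 115, 10, 10)), "blue"),
               "outside")
})

test_that("classification agrees with the brute-force per-pixel oracle", {
  for (seed in c(51, 52)) {
    fx <- generate_slice_image(simulation_params(
      width = 60, height = 60, semi_axes = c(25, 22),
      true_fraction = 0.4, noise_sd = 15, seed = seed))
    rs <- generate_training_regions(fx, n_regions = 3, region_size = 6,
                                    seed = seed + 100)
    yellow <- fit_color_class(fx$image, rs$yellow_regions, "yellow")
    blue <- fit_color_class(fx$image, rs$blue_regions, "blue")
    got <- classify_pixels(fx$image, fx$bbox, yellow, blue)
    want <- oracle_classify(fx$image, fx$bbox, yellow, blue)
    expect_identical(unclass(got)[seq_along(want)], as.vector(want))
  }
})

test_that("class centers classify to their class; distant pixels are uncolored", {
  img <- array(128L, dim = c(20, 20, 3))
  img[1, 1, ] <- c(200L, 180L, 40L) # yellow mean
  img[1, 2, ] <- c(40L, 60L, 190L)  # blue mean
  img[1, 3, ] <- c(0L, 255L, 0L)    # far from both
  yellow <- structure(list(class_label = "yellow", mean = c(200, 180, 40),
                           sd = c(5, 5, 5), k = 1.7, n_pixels = 100L),
                      class = "color_class_model")
  blue <- structure(list(class_label = "blue", mean = c(40, 60, 190),
                         sd = c(5, 5, 5), k = 1.7, n_pixels = 100L),
                    class = "color_class_model")
  lab <- classify_pixels(img, region(0, 0, 20, 20), yellow, blue)
  expect_identical(lab[1, 1], 1L)
  expect_identical(lab[1, 2], 2L)
  expect_identical(lab[1, 3], 0L)
})

test_that("mismatched k between the two models is rejected", {
  fx <- small_fixture(noise_sd = 5, seed = 61)
  rs <- generate_training_regions(fx, n_regions = 4, region_size = 8, seed = 62)
  y <- fit_color_class(fx$image, rs$yellow_regions, "yellow", k = 1.7)
  b <- fit_color_class(fx$image, rs$blue_regions, "blue", k = 2.0)
  expect_error(classify_pixels(fx$image, fx$bbox, y, b), "same k")
})

test_that("damage percentage handles the trivial and degenerate label maps", {
  mk <- function(v) structure(matrix(v, 2, 2), class = "label_map",
                              bbox = region(0, 0, 2, 2), n_both = 0L, n_ties = 0L)
  expect_equal(damage_percentage(mk(c(1L, 1L, 1L, 1L)))$damage_pct, 100)
  expect_equal(damage_percentage(mk(c(1L, 1L, 2L, 2L)))$damage_pct, 50)
  expect_error(damage_percentage(mk(rep(0L, 4))), "no colored pixels")
})

test_that("counts are conserved over the bounding box", {
  fx <- small_fixture(true_fraction = 0.3, noise_sd = 10, seed = 71)
  rs <- generate_training_regions(fx, n_regions = 8, region_size = 8, seed = 72)
  seg <- segment_slice(fx$image, rs, fx$bbox)
  expect_identical(seg$n_yellow + seg$n_blue + seg$n_uncolored,
                   fx$bbox$w * fx$bbox$h)
})

test_that("noise-free fixtures are recovered exactly", {
  for (f in c(0.2, 0.35, 0.65)) {
    fx <- small_fixture(true_fraction = f, noise_sd = 0, seed = 81)
    rs <- generate_training_regions(fx, n_regions = 6, region_size = 8, seed = 82)
    seg <- segment_slice(fx$image, rs, fx$bbox)
    expect_equal(seg$damage_pct, 100 * fx$true_fraction)
    expect_identical(seg$n_uncolored + seg$n_yellow + seg$n_blue,
                     fx$bbox$w * fx$bbox$h)
  }
})

test_that("swapping the training-region classes mirrors the percentage", {
  fx <- small_fixture(true_fraction = 0.35, noise_sd = 0, seed = 91)
  rs <- generate_training_regions(fx, n_regions = 6, region_size = 8, seed = 92)
  seg <- segment_slice(fx$image, rs, fx$bbox)
  swapped <- structure(list(yellow_regions = rs$blue_regions,
                            blue_regions = rs$yellow_regions,
                            region_size = rs$region_size),
                       class = "region_set")
  seg_sw <- segment_slice(fx$image, swapped, fx$bbox)
  expect_equal(seg_sw$damage_pct, 100 - seg$damage_pct)
})

test_that("increasing k never shrinks a class's matched pixel set", {
  fx <- small_fixture(true_fraction = 0.4, noise_sd = 12, seed = 101)
  rs <- generate_training_regions(fx, n_regions = 6, region_size = 8, seed = 102)
  matched <- sapply(c(0.8, 1.2, 1.7, 2.5), function(k) {
    y <- fit_color_class(fx$image, rs$yellow_regions, "yellow", k = k)
    b <- fit_color_class(fx$image, rs$blue_regions, "blue", k = k)
    sub <- fx$image[(fx$bbox$y + 1):(fx$bbox$y + fx$bbox$h),
                    (fx$bbox$x + 1):(fx$bbox$x + fx$bbox$w), , drop = FALSE]
    pix <- matrix(sub, ncol = 3)
    inb <- function(m) {
      ok <- rep(TRUE, nrow(pix))
      for (ch in 1:3) ok <- ok & pix[, ch] >= m$mean[ch] - m$k * m$sd[ch] &
          pix[, ch] <= m$mean[ch] + m$k * m$sd[ch]
      sum(ok)
    }
    c(inb(y), inb(b))
  })
  expect_true(all(diff(matched[1, ]) >= 0))
  expect_true(all(diff(matched[2, ]) >= 0))
})

test_that("shuffling training-region order leaves the result unchanged", {
  fx <- small_fixture(true_fraction = 0.45, noise_sd = 9, seed = 111)
  rs <- generate_training_regions(fx, n_regions = 8, region_size = 8, seed = 112)
  perm <- structure(list(yellow_regions = rev(rs$yellow_regions),
                         blue_regions = rs$blue_regions[c(3, 1, 4, 2, 8, 6, 5, 7)],
                         region_size = rs$region_size),
                    class = "region_set")
  expect_equal(segment_slice(fx$image, rs, fx$bbox)$damage_pct,
               segment_slice(fx$image, perm, fx$bbox)$damage_pct)
})

test_that("stage failures are reported with the failing stage's name", {
  fx <- small_fixture()
  broken <- structure(list(yellow_regions = list(), blue_regions = list(),
                           region_size = 10L), class = "region_set")
  expect_error(segment_slice(fx$image, broken, fx$bbox),
               "fit_color_class/yellow")
})
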