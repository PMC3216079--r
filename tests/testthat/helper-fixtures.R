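# Small, fast fixtures shared across test files.

# Compact canvas: quick to generate and classify, still large enough to
# admit several pure training regions at mid-range fractions.
small_params <- function(true_fraction = 0.35, noise_sd = 0, seed = 1L,
                         width = 120L, height = 120L,
                         semi_axes = c(52, 45), ...) {
  simulation_params(width = width, height = height, semi_axes = semi_axes,
                    true_fraction = true_fraction, noise_sd = noise_sd,
                    seed = seed, ...)
}

small_fixture <- function(...) generate_slice_image(small_params(...))

# Per-hip gluteus medius damage percentages, five hips per approach.
table1_values <- list(
  "Lateral transgluteal" = c(6, 22, 16, 32, 40),
  "MIS anterior" = c(35, 0, 0, 0, 0),
  "MIS anterolateral" = c(27, 14, 6, 23, 18),
  "MIS 2-incision" = c(29, 24, 40, 26, 14),
  "MIS posterior" = c(22, 0, 18, 0, 22))

# Independent scalar-loop oracle for the per-pixel classification rule:
# a pixel matches a class iff every channel lies within mean +/- k*sd;
# both-match resolved by smaller sd-normalized distance, ties to yellow.
oracle_classify <- function(image, bbox, yellow, blue) {
  lab <- matrix(0L, nrow = bbox$h, ncol = bbox$w)
  match_class <- function(px, m) {
    for (ch in 1:3) {
      lo <- m$mean[ch] - m$k * m$sd[ch]
      hi <- m$mean[ch] + m$k * m$sd[ch]
      if (px[ch] < lo || px[ch] > hi) return(FALSE)
    }
    TRUE
  }
  dist2 <- function(px, m) {
    d <- 0
    for (ch in 1:3) {
      if (m$sd[ch] > 0) d <- d + ((px[ch] - m$mean[ch]) / m$sd[ch])^2
      else if (px[ch] != m$mean[ch]) d <- d + Inf
    }
    d
  }
  for (i in seq_len(bbox$h)) {
    for (j in seq_len(bbox$w)) {
      px <- image[bbox$y + i, bbox$x + j, ]
      my <- match_class(px, yellow); mb <- match_class(px, blue)
      lab[i, j] <- if (my && mb) {
        if (dist2(px, yellow) <= dist2(px, blue)) 1L else 2L
      } else if (my) 1L else if (mb) 2L else 0L
    }
  }
  lab
}

# Independent rank-and-sum evaluation of the ties-corrected Kruskal-Wallis
# statistic: H = [12 / (N(N+1))] * sum(R_j^2 / n_j) - 3(N+1), divided by
# 1 - sum(t^3 - t) / (N^3 - N) over tie groups.
oracle_kruskal_H <- function(groups) {
  values <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(values)
  r <- rank(values) # midranks
  H <- 12 / (N * (N + 1)) * sum(tapply(r, g, sum)^2 / lengths(groups)) -
    3 * (N + 1)
  ties <- table(values)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Brute-force two-way ANOVA decomposition for the ICC oracle: explicit
# sums of squares, no matrix shortcuts.
oracle_icc21 <- function(x) {
  n <- nrow(x); k <- ncol(x)
  gm <- sum(x) / (n * k)
  ssr <- 0; ssc <- 0; sst <- 0
  for (i in seq_len(n)) ssr <- ssr + k * (mean(x[i, ]) - gm)^2
  for (j in seq_len(k)) ssc <- ssc + n * (mean(x[, j]) - gm)^2
  for (i in seq_len(n)) for (j in seq_len(k)) sst <- sst + (x[i, j] - gm)^2
  msr <- ssr / (n - 1); msc <- ssc / (k - 1)
  mse <- (sst - ssr - ssc) / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}
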