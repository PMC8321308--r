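test_that("histogram_spec validates bins, bandwidths and window radius", {
  spec <- histogram_spec()
  expect_equal(spec$nb, 256L)
  expect_equal(spec$window_radius, 9L)   # ceil(3 * sigma_w) for sigma_w = 3
  expect_equal(spec$bin_centers[c(1, 256)], c(0, 1))

  expect_equal(histogram_spec(sigma_k = 0)$sigma_k, 1e-4)  # floored
  expect_error(histogram_spec(nb = 1), "at least 2")
  expect_error(histogram_spec(sigma_w = -1), "nonnegative")
  expect_error(histogram_spec(sigma_w = 3, window_radius = 2), "at least")
  expect_error(histogram_spec(nb = 4, bin_centers = c(0, 0.5, 0.4, 1)),
               "increasing")
})

test_that("smoothed local histogram of a constant patch is a single kernel bump", {
  img <- make_constant(9, 9, 0.4)
  spec <- histogram_spec(nb = 11, sigma_k = 0.05, sigma_w = 1,
                         window_radius = 3)
  f <- smoothed_local_histogram(img, c(5, 5), spec)
  # all neighbors identical: f(s_k) proportional to K(0.4 - s_k)
  bump <- dnorm(0.4 - spec$bin_centers, sd = spec$sigma_k)
  expect_equal(f / max(f), bump / max(bump), tolerance = 1e-12)
  expect_error(smoothed_local_histogram(img, c(0, 5), spec), "inside")
})

test_that("smoothed local histogram equals the hand-expanded double sum", {
  vals <- matrix(c(0.10, 0.20, 0.30,
                   0.40, 0.50, 0.60,
                   0.70, 0.80, 0.90), 3, 3, byrow = TRUE)
  img <- gray_image(vals)
  sw <- 1 / 3  # keeps the truncation radius at one pixel
  spec <- histogram_spec(nb = 5, sigma_k = 0.1, sigma_w = sw,
                         window_radius = 1)
  f <- smoothed_local_histogram(img, c(2, 2), spec)
  # independent scalar expansion over the 3x3 patch
  expected <- numeric(5)
  for (k in 1:5) {
    acc <- 0
    for (di in -1:1) for (dj in -1:1) {
      acc <- acc + dnorm(vals[2 + di, 2 + dj] - spec$bin_centers[k], sd = 0.1) *
        exp(-(di^2 + dj^2) / (2 * sw^2))
    }
    expected[k] <- acc
  }
  expect_equal(f, expected, tolerance = 1e-12)
})

test_that("degenerate kernels reduce the histogram to per-bin counts", {
  # values exactly on the bin grid; near-delta intensity kernel
  spec <- histogram_spec(nb = 5, sigma_k = 0, sigma_w = 0, window_radius = 1)
  vals <- matrix(spec$bin_centers[c(1, 2, 2, 3, 3, 3, 4, 5, 5)], 3, 3)
  img <- gray_image(vals)
  f <- smoothed_local_histogram(img, c(2, 2), spec)
  counts <- c(1, 2, 3, 1, 2)
  expect_equal(f / dnorm(0, sd = spec$sigma_k), counts, tolerance = 1e-8)
})

test_that("convolutional CDF field matches the direct double-sum oracle", {
  for (cfg in list(list(nb = 8L, sw = 0), list(nb = 16L, sw = 1),
                   list(nb = 8L, sw = 3))) {
    img <- rand_image(16, 16, 300 + cfg$nb + cfg$sw)
    spec <- histogram_spec(nb = cfg$nb, sigma_k = 0.05, sigma_w = cfg$sw)
    got <- smoothed_cdf_field(img, spec)
    expect_lt(max(abs(got$R - direct_cdf_field(img, spec))), 1e-6)
  }
})

test_that("CDF field is monotone in k, bounded, and a smooth step on constants", {
  img <- rand_image(12, 12, 77)
  spec <- histogram_spec(nb = 16, sigma_k = 0.08, sigma_w = 2)
  R <- smoothed_cdf_field(img, spec)$R
  expect_true(all(apply(R, c(1, 2), function(v) all(diff(v) >= -1e-12))))
  expect_true(all(R >= 0 & R <= 1))

  cimg <- make_constant(10, 10, 0.3)
  Rc <- smoothed_cdf_field(cimg, spec)$R
  expected <- 1 - pnorm(0.3 - spec$bin_centers, sd = spec$sigma_k)
  for (k in seq_len(spec$nb)) {
    expect_equal(Rc[, , k], matrix(expected[k], 10, 10), tolerance = 1e-9)
  }
  # top bin with a near-delta kernel saturates at 1
  spec0 <- histogram_spec(nb = 16, sigma_k = 0, sigma_w = 1)
  expect_equal(max(abs(smoothed_cdf_field(img, spec0)$R[, , 16] - 1)), 0)
})

test_that("quantile_lookup interpolates, clamps and rejects bad input", {
  R <- c(0, 0.25, 0.5, 0.75, 1)
  s <- seq(0, 1, 0.25)
  expect_equal(quantile_lookup(R, s, 0.5), 0.5)
  expect_equal(quantile_lookup(R, s, 0.375), 0.375)  # linear between bins 2, 3

  # exact hits return the bin center itself
  set.seed(21)
  Rr <- sort(runif(9))
  sr <- seq(0, 1, length.out = 9)
  for (j in c(2, 5, 8)) {
    expect_equal(quantile_lookup(Rr, sr, Rr[j]), sr[j])
  }
  expect_error(quantile_lookup(c(0.5, 0.2, 1), s[1:3], 0.5), "nondecreasing")
  expect_error(quantile_lookup(R, s, 1.5), "\\[0, 1\\]")
})

test_that("quantile_lookup is monotone in v and stays within the bin range", {
  set.seed(31)
  for (rep in 1:20) {
    nb <- sample(c(8, 16, 33), 1)
    R <- sort(runif(nb))
    s <- seq(0, 1, length.out = nb)
    v <- sort(runif(25))
    out <- quantile_lookup(R, s, v)
    expect_true(all(diff(out) >= -1e-12))
    expect_true(all(out >= 0 & out <= 1))
  }
})
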