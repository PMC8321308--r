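test_that("normalized Laplacian matches the stencil oracle and its bounds", {
  img <- rand_image(8, 8, 501)
  expect_equal(normalized_laplacian(img), loop_laplacian(img),
               tolerance = 1e-12)

  expect_equal(normalized_laplacian(make_constant(6, 6, 0.5)),
               matrix(0, 6, 6))

  spike <- matrix(0, 5, 5); spike[3, 3] <- 1
  expect_equal(normalized_laplacian(gray_image(spike))[3, 3], -1)
  expect_true(all(abs(normalized_laplacian(img)) <= 1))
})

test_that("shock level map deflects the quantile level by the Laplacian sign", {
  lap <- matrix(c(-1, -0.3, 0, 0.3, 1), 1, 5)
  expect_equal(shock_level_map(lap, 0.5)[1, ], c(1, 1, 0.5, 0, 0))
  expect_equal(shock_level_map(lap, 0)[1, ], rep(0.5, 5))
  expect_equal(shock_level_map(lap, 0.1)[1, ], c(0.6, 0.6, 0.5, 0.4, 0.4))
  # linear coupling scales with the magnitude instead
  expect_equal(shock_level_map(lap, 0.5, coupling = "linear")[1, ],
               c(1, 0.65, 0.5, 0.35, 0))
  # flipped convention mirrors the deflection
  expect_equal(shock_level_map(lap, 0.5, "dilate_on_positive")[1, ],
               c(0, 0, 0.5, 1, 1))
  expect_error(shock_level_map(lap, 0.6), "1/2")
})

test_that("rho = 0 collapses the shock filter to the iterated smoothed median", {
  img <- rand_image(16, 16, 88)
  spec <- histogram_spec(nb = 64, sigma_k = 0.05, sigma_w = 2)
  ss <- smoothed_shock_filter(img, shock_params(rho = 0, nit = 3, spec = spec))
  ref <- img
  for (i in 1:3) {
    ref <- smoothed_median(ref, spec)
    expect_identical(unclass(ss$iterates[[i + 1]]), unclass(ref))
  }
})

test_that("degenerate smoothed shock at rho = 1/2 equals classic shock", {
  # blurred and sharp steps plus a disk: one full-strength smoothed
  # erosion/dilation step must match the classic min/max switch to within
  # one bin
  fixtures <- list(
    make_step(32, 32, 16, 0.1, 0.9, blur_sigma = 2),
    make_step(32, 32, 16, 0.1, 0.9),
    make_disk(32, 32, radius = 9, fg = 0.9, bg = 0.1)
  )
  params <- shock_params(rho = 0.5, nit = 1, spec = degenerate_spec())
  for (img in fixtures) {
    expect_lt(max(abs(smoothed_shock_step(img, params) -
                      classic_shock_step(img))), 1 / 256)
  }
})

test_that("scale space records iterates and residuals deterministically", {
  img <- make_texture(24, 24, seed = 14)
  params <- shock_params(rho = 0.1, nit = 2,
                         spec = histogram_spec(nb = 64, sigma_w = 1))
  ss <- smoothed_shock_filter(img, params)

  expect_length(ss$iterates, 3)
  expect_identical(unclass(ss$iterates[[1]]), unclass(img))
  expect_identical(unclass(ss$iterates[[2]]),
                   unclass(smoothed_shock_step(img, params)))
  for (i in 1:3) {
    expect_equal(ss$residuals[[i]], residual(img, ss$iterates[[i]]))
  }
  ss2 <- smoothed_shock_filter(img, params)
  expect_identical(ss$iterates, ss2$iterates)

  cimg <- make_constant(16, 16, 0.5)
  ssc <- smoothed_shock_filter(cimg, params)
  for (it in ssc$iterates) expect_lt(max(abs(it - 0.5)), 3 / 64)
})

test_that("iterates stay within the input range at bin resolution", {
  set.seed(99)
  imgs <- fixture_set(32)
  for (rep in 1:10) {
    img <- imgs[[(rep %% length(imgs)) + 1]]
    spec <- histogram_spec(nb = sample(c(16, 64, 256), 1),
                           sigma_k = runif(1, 0, 0.1),
                           sigma_w = sample(0:2, 1))
    params <- shock_params(rho = runif(1, -0.5, 0.5), nit = 1, spec = spec)
    out <- smoothed_shock_step(img, params)
    expect_gte(min(out), min(img) - 1 / spec$nb)
    expect_lte(max(out), max(img) + 1 / spec$nb)
  }
})

test_that("stronger spatial smoothing gives smoother iterates", {
  # assessed on the median component (rho = 0): the full-strength shock
  # deflection deliberately re-adds contour-scale variation at wide
  # windows, so total variation isolates the smoothing effect only with
  # the Laplacian term off
  blob <- make_disk(32, 32, radius = 10, fg = 0.9, bg = 0.2)
  noisy <- add_gaussian_noise(blob, 15, seed = 8)
  tvs <- vapply(c(0, 1, 2, 3), function(sw) {
    ss <- smoothed_shock_filter(noisy,
      shock_params(rho = 0, nit = 3,
                   spec = histogram_spec(nb = 64, sigma_w = sw)))
    total_variation(ss$iterates[[4]])
  }, numeric(1))
  expect_true(all(diff(tvs) <= 0))
})
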