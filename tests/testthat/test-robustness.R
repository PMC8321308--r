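test_that("additive Gaussian noise has the stated moments and determinism", {
  img <- make_constant(64, 64, 0.5)
  expect_identical(unclass(add_gaussian_noise(img, 0, seed = 1)),
                   unclass(img))
  n1 <- add_gaussian_noise(img, 25, seed = 7)
  n2 <- add_gaussian_noise(img, 25, seed = 7)
  expect_identical(unclass(n1), unclass(n2))

  # sample std within 3 standard errors of 25/255 (clamping negligible
  # at 0.5 +/- 0.098)
  diffs <- as.vector(unclass(n1) - unclass(img))
  se <- (25 / 255) / sqrt(2 * (length(diffs) - 1))
  expect_lt(abs(sd(diffs) - 25 / 255), 3 * se)
})

test_that("SSIM is 1 on identity, symmetric, and matches references", {
  x <- make_texture(32, 32, seed = 5)
  y <- add_gaussian_noise(x, 15, seed = 2)
  expect_equal(ssim(x, x), 1)
  expect_equal(ssim(x, y), ssim(y, x))
  expect_true(ssim(x, y) < 1 && ssim(x, y) > -1)

  # constant images: contrast/structure terms are stabilizer-degenerate,
  # leaving the closed-form luminance term
  c1 <- 0.01^2
  expect_equal(ssim(make_constant(16, 16, 0.5), make_constant(16, 16, 0.6)),
               (2 * 0.5 * 0.6 + c1) / (0.5^2 + 0.6^2 + c1), tolerance = 1e-12)

  # frozen reference values computed with an independent SSIM
  # implementation (Gaussian 11x11 window, sigma 1.5, K1=0.01, K2=0.03,
  # data range 1) on deterministic sinusoid images
  h <- 32; w <- 48
  r <- matrix(seq_len(h) / h, h, w)
  co <- matrix(seq_len(w) / w, h, w, byrow = TRUE)
  a <- (sin(2 * pi * 3 * co) * cos(2 * pi * 2 * r) + 1) / 2
  b <- pmin(pmax(a + 0.1 * sin(2 * pi * 5 * (r + co)), 0), 1)
  d <- pmin(pmax(a + 0.2, 0), 1)
  expect_equal(ssim(gray_image(a), gray_image(b)), 0.926355214569684,
               tolerance = 1e-9)
  expect_equal(ssim(gray_image(a), gray_image(d)), 0.905064178499434,
               tolerance = 1e-9)

  expect_error(ssim(x, make_constant(10, 10, 0)), "dimensions")
  expect_error(ssim(make_constant(8, 8, 0), make_constant(8, 8, 0)),
               "at least")
})

test_that("noise ladder validates scales", {
  expect_error(noise_ladder(c(5)), "at least two")
  expect_error(noise_ladder(c(10, 5)), "increasing")
  expect_error(noise_ladder(c(-5, 5)), "nonnegative")
})

test_that("identity quality curve starts at 1 and decreases with noise", {
  imgs <- fixture_set(32)[c("blurred_step", "disk", "texture")]
  ladder <- noise_ladder(c(0, 5, 10, 15), seed = 3)
  qc <- quality_curve(identity, imgs, ladder, "identity")
  expect_equal(qc$mean_ssim[1], 1)
  expect_true(all(diff(qc$mean_ssim) < 0))

  qc2 <- quality_curve(identity, imgs, ladder, "identity")
  expect_identical(qc$mean_ssim, qc2$mean_ssim)
})

test_that("alpha_sigma matches the worked example and a brute-force scan", {
  worked <- tibble::tibble(filter = "toy", sigma = c(5, 10, 15, 20),
                           mean_ssim = c(0.9, 0.8, 0.6, 0.55))
  res <- alpha_sigma(worked)
  expect_equal(res$alpha, 0.04)
  expect_equal(res$sigma, 10)

  flat <- tibble::tibble(sigma = c(5, 10, 15), mean_ssim = rep(0.7, 3))
  expect_equal(alpha_sigma(flat)$alpha, 0)
  expect_equal(alpha_sigma(flat)$sigma, 5)

  rising <- tibble::tibble(sigma = c(5, 10, 15), mean_ssim = c(0.5, 0.6, 0.9))
  expect_lt(alpha_sigma(rising)$alpha, 0)

  set.seed(17)
  for (rep in 1:200) {
    m <- sample(3:8, 1)
    sg <- sort(5 * sample(1:20, m))
    q <- runif(m, -1, 1)
    res <- alpha_sigma(tibble::tibble(sigma = sg, mean_ssim = q))
    best <- -Inf; best_s <- NA
    for (k in seq_len(m - 1)) {
      rate <- (q[k] - q[k + 1]) / (sg[k + 1] - sg[k])
      if (rate > best) { best <- rate; best_s <- sg[k] }
    }
    expect_equal(res$alpha, best)
    expect_equal(res$sigma, best_s)
  }
  expect_error(alpha_sigma(tibble::tibble(sigma = 5, mean_ssim = 1)),
               "two points")
})

test_that("robustness experiment ranks filters and writes CSVs", {
  imgs <- fixture_set(32)[c("blurred_step", "texture")]
  ladder <- noise_ladder(c(10, 20), seed = 11)
  filters <- list(identity = function(img) img,
                  median = function(img) median_filter(img, 1))
  exp1 <- run_robustness_experiment(filters, imgs, ladder)

  expect_setequal(exp1$summary$filter, c("identity", "median"))
  expect_true(all(is.finite(exp1$summary$alpha)))
  expect_true(!is.unsorted(exp1$summary$alpha))

  dir <- withr::local_tempdir()
  write_robustness_csv(exp1, dir)
  curves <- read.csv(file.path(dir, "curves.csv"))
  summary <- read.csv(file.path(dir, "summary.csv"))
  expect_equal(nrow(curves), 4)  # 2 filters x 2 scales
  expect_equal(names(summary), c("filter", "alpha", "sigma_at_alpha"))

  expect_error(run_robustness_experiment(list(function(img) img), imgs, ladder),
               "named")
})

test_that("tidiers and autoplot methods produce well-formed output", {
  ss <- smoothed_shock_filter(make_texture(24, 24, seed = 2),
    shock_params(nit = 2, spec = histogram_spec(nb = 32, sigma_w = 1)))
  td <- tidy(ss)
  expect_equal(td$iteration, 0:2)
  expect_equal(td$rms_residual[1], 0)
  gl <- glance(ss)
  expect_equal(gl$nit, 2L)

  imgs <- fixture_set(32)["texture"]
  qc <- quality_curve(identity, imgs, noise_ladder(c(5, 10), seed = 1), "id")
  expect_s3_class(autoplot(qc), "ggplot")
  expect_s3_class(autoplot(ss), "ggplot")
  expect_s3_class(autoplot(imgs$texture), "ggplot")
  expect_s3_class(tidy(alpha_sigma(qc)), "tbl_df")
})
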