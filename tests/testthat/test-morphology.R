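test_that("density matches Otsu foreground fraction on canonical cases", {
  expect_equal(fiber_density(channel_image(matrix(0L, 64, 64), "collagen")), 0)
  # binary image with a quarter of pixels at max value
  px <- matrix(0L, 32, 32)
  px[1:16, 1:16] <- 255L
  expect_equal(fiber_density(channel_image(px, "collagen")), 0.25)
})

test_that("Otsu threshold equals the brute-force histogram search", {
  for (s in 1:20) {
    px <- withr::with_seed(s, {
      fg <- sample(140:220, 300, TRUE)
      bg <- sample(0:70, 724, TRUE)
      matrix(sample(c(fg, bg)), 32, 32)
    })
    img <- channel_image(px, "collagen")
    expect_identical(otsu_threshold(img), bf_otsu(px))
    expect_equal(fiber_density(img), mean(px > bf_otsu(px)))
  }
})

test_that("density is invariant to non-saturating intensity scaling", {
  p <- phantom_params(k = 2, seed = 9, n_fibers = 30)
  p$intensity_mean <- 80; p$intensity_sd <- 5
  img <- render_fiber_image(p, 128)
  scaled <- channel_image(img$pixels * 2L, "collagen")
  expect_equal(fiber_density(scaled), fiber_density(img), tolerance = 0.02)
})

test_that("orientation distribution is a unit-mass 180-bin distribution", {
  img <- render_fiber_image(phantom_params(k = 4, seed = 2), 128)
  d <- orientation_distribution(img)
  expect_length(d$mass, 180)
  expect_equal(sum(d$mass), 1, tolerance = 1e-9)
  expect_true(all(d$mass >= 0))
  expect_equal(d$angles_deg, seq(0.5, 179.5, 1))
  expect_error(orientation_distribution(
    channel_image(matrix(0L, 64, 96), "collagen")),
    class = "fibrotype_parameter_error")
})

test_that("horizontal stripes concentrate mass at the 0/180 wraparound", {
  n <- 128
  px <- matrix(as.integer(127 + 100 * sin(2 * pi * 10 * (1:n) / n)), n, n)
  d <- orientation_distribution(channel_image(px, "collagen"))
  wrap_mass <- sum(d$mass[c(1:5, 176:180)])
  expect_gt(wrap_mass, 0.9)
})

test_that("white noise gives an approximately uniform distribution", {
  ratios <- sapply(1:10, function(s) {
    px <- withr::with_seed(s, matrix(sample(0:255, 128^2, TRUE), 128, 128))
    d <- orientation_distribution(channel_image(px, "collagen"))
    max(d$mass) / mean(d$mass)
  })
  expect_lt(max(ratios), 3)
})

test_that("rotating the image by 90 degrees shifts the distribution", {
  img <- render_fiber_image(phantom_params(k = 20, seed = 12, mu = 30), 128)
  rot <- channel_image(t(img$pixels)[nrow(img$pixels):1, ], "collagen")
  mu1 <- fit_von_mises(orientation_distribution(img))$mu_deg
  mu2 <- fit_von_mises(orientation_distribution(rot))$mu_deg
  delta <- (mu2 - mu1) %% 180
  expect_true(abs(delta - 90) < 3)
})

test_that("fitting recovers a tabulated von Mises density", {
  theta <- seq(0.5, 179.5, 1) * pi / 180
  for (case in list(c(60, 4), c(10, 1.5), c(150, 12))) {
    mu <- case[1]; k <- case[2]
    mass <- exp(k * cos(2 * (theta - mu * pi / 180))) /
      (pi * besselI(k, 0)) * pi / 180
    mass <- mass / sum(mass)
    fit <- fit_von_mises(structure(
      list(angles_deg = seq(0.5, 179.5, 1), mass = mass),
      class = "orientation_distribution"))
    expect_equal(fit$mu_deg, mu, tolerance = 1 / mu)
    expect_true(abs(fit$mu_deg - mu) < 1)
    expect_true(abs(fit$k - k) < 0.05)
  }
})

test_that("a uniform distribution fits k = 0", {
  fit <- fit_von_mises(structure(
    list(angles_deg = seq(0.5, 179.5, 1), mass = rep(1 / 180, 180)),
    class = "orientation_distribution"))
  expect_lt(fit$k, 1e-3)
})

test_that("fitted mu respects the semicircular wraparound", {
  theta <- seq(0.5, 179.5, 1) * pi / 180
  mass <- exp(5 * cos(2 * (theta - 2 * pi / 180))) / (pi * besselI(5, 0))
  mass <- mass / sum(mass)
  fit <- fit_von_mises(structure(
    list(angles_deg = seq(0.5, 179.5, 1), mass = mass),
    class = "orientation_distribution"))
  d <- min(abs(fit$mu_deg - 2), abs(fit$mu_deg - 182), abs(fit$mu_deg + 178))
  expect_lt(d, 1)
})

test_that("fitted k is stable under image rotation", {
  img <- render_fiber_image(phantom_params(k = 6, seed = 21, mu = 20), 128)
  k0 <- fit_von_mises(orientation_distribution(img))$k
  rot90 <- channel_image(t(img$pixels)[nrow(img$pixels):1, ], "collagen")
  k90 <- fit_von_mises(orientation_distribution(rot90))$k
  expect_equal(k90, k0, tolerance = 0.05)
})

test_that("fiber tracing recovers bar geometry and component counts", {
  px <- matrix(0L, 128, 128)
  px[62:66, 15:114] <- 200L
  fib <- trace_fibers(channel_image(px, "collagen"))
  expect_equal(nrow(fib), 1)
  expect_true(fib$length_px >= 95 && fib$length_px <= 105)
  expect_true(fib$width_px >= 4 && fib$width_px <= 6)

  px2 <- matrix(0L, 128, 128)
  px2[30:34, 15:114] <- 200L
  px2[90:94, 15:114] <- 200L
  expect_equal(nrow(trace_fibers(channel_image(px2, "collagen"))), 2)

  expect_equal(nrow(trace_fibers(channel_image(matrix(0L, 64, 64),
                                               "collagen"))), 0)
})

test_that("morphology features degrade gracefully on empty images", {
  m <- morphology_features(channel_image(matrix(0L, 64, 64), "collagen"))
  expect_equal(unlist(m), c(density = 0, alignment_k = 0,
                            mean_width_px = 0, mean_length_px = 0))
})

test_that("end-to-end alignment recovery is accurate and monotone in k", {
  med <- sapply(c(1, 2, 4, 8), function(k) {
    fits <- sapply(1:5, function(s) {
      img <- render_fiber_image(phantom_params(k, seed = 31 + s,
                                               mu = (17 * s) %% 180), 192)
      fit_von_mises(orientation_distribution(img))$k
    })
    median(fits)
  })
  expect_true(all(abs(med - c(1, 2, 4, 8)) / c(1, 2, 4, 8) < 0.25))
  expect_true(all(diff(med) > 0))
})

test_that("traced length and fitted k order the tissue classes correctly", {
  pr <- small_presets()
  stats <- lapply(c("scar", "normal", "adjacent"), function(cl) {
    v <- sapply(1:4, function(s) {
      r <- render_region(pr[[cl]]$collagen, pr[[cl]]$elastin, 128,
                         region_seed = 900 + s * 13)
      m <- morphology_features(denoise(r$elastin))
      c(len = m$mean_length_px, k = m$alignment_k)
    })
    rowMeans(v)
  })
  names(stats) <- c("scar", "normal", "adjacent")
  expect_lt(stats$scar["len"], stats$normal["len"])
  expect_gt(stats$adjacent["k"], stats$scar["k"])
})
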