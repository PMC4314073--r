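test_that("Beer-Lambert transform matches hand-computed values", {
  maxval <- 255
  expect_equal(beer_lambert_transform(maxval), 0)
  expect_equal(beer_lambert_transform(0.1 * maxval), 68)
  expect_equal(beer_lambert_transform(0.5 * maxval), 68 * log10(2))
  expect_equal(round(beer_lambert_transform(0.5 * maxval), 2), 20.47)
  expect_error(beer_lambert_transform(-1), "negative")
  # zeros are clamped to half the least count, not -Inf
  expect_equal(beer_lambert_transform(0), 68 * log10(2 * maxval))
})

test_that("Beer-Lambert transform is strictly decreasing in intensity", {
  x <- seq(1, 255, by = 1)
  y <- beer_lambert_transform(x)
  expect_true(all(diff(y) < 0))
  expect_true(all(beer_lambert_transform(runif(50, 1, 255)) > 0))
})

test_that("cluster means equal the brute-force block mean", {
  # constant block
  g <- list(matrix(7, 5, 5), matrix(7, 5, 5))
  cc <- cluster_means(g)
  expect_equal(dim(cc$values), c(1, 1, 2))
  expect_equal(as.vector(cc$values), c(7, 7))
  # 10x10 -> 2x2 grid (floor division)
  g2 <- list(matrix(rnorm(100), 10, 10))
  expect_equal(dim(cluster_means(g2)$values)[1:2], c(2, 2))
  # remainder dropped: 13x17 -> 2x3
  g3 <- list(matrix(rnorm(13 * 17), 13, 17))
  expect_equal(dim(cluster_means(g3)$values)[1:2], c(2, 3))
  # random frame vs direct-summation oracle
  set.seed(31)
  m <- matrix(runif(225, 0, 40), 15, 15)
  got <- cluster_means(list(m))$values[, , 1]
  for (i in 1:3) for (j in 1:3) {
    block <- m[(5 * i - 4):(5 * i), (5 * j - 4):(5 * j)]
    expect_equal(got[i, j], sum(block) / 25)
  }
  expect_error(cluster_means(list(matrix(0, 4, 10))), "smaller")
})

test_that("harmonic regression recovers exact basis members", {
  b <- default_beats()
  s <- make_flat_stack(n = 75, fps = 25)
  ph <- compute_phase(s, b)
  phi <- ph$phase[ph$included]
  y <- rep(NA_real_, 75)
  y[ph$included] <- 3 + 2 * sin(2 * pi * phi)
  fit <- fit_harmonic(y, ph, b)
  expect_equal(fit$harmonics$b[1], 2, tolerance = 1e-8)
  expect_lt(abs(fit$harmonics$a[1]), 1e-8)
  expect_lt(abs(fit$harmonics$a[2]), 1e-8)
  expect_lt(abs(fit$harmonics$b[2]), 1e-8)
  expect_equal(amplitude_from_fit(fit), 4, tolerance = 1e-6)

  # constant series -> all harmonic coefficients ~ 0
  yc <- rep(5, 75)
  fitc <- fit_harmonic(yc, ph, b)
  expect_lt(max(abs(c(fitc$harmonics$a, fitc$harmonics$b))), 1e-10)
  expect_equal(amplitude_from_fit(fitc), 0)
})

test_that("the spline absorbs a linear-in-time drift", {
  b <- default_beats()
  s <- make_flat_stack(n = 75, fps = 25)
  ph <- compute_phase(s, b)
  phi <- ph$phase[ph$included]
  tt <- ph$time[ph$included]
  y <- rep(NA_real_, 75)
  y[ph$included] <- 2 * sin(2 * pi * phi) + 0.5 * tt
  fit <- fit_harmonic(y, ph, b)
  expect_equal(fit$harmonics$b[1], 2, tolerance = 0.05)
  expect_equal(amplitude_from_fit(fit), 4, tolerance = 0.05 * 4)
  # amplitude invariant to adding any linear trend (within 5%)
  y2 <- y; y2[ph$included] <- y2[ph$included] - 3.7 * tt + 1
  fit2 <- fit_harmonic(y2, ph, b)
  expect_equal(amplitude_from_fit(fit2), amplitude_from_fit(fit),
               tolerance = 0.05)
})

test_that("amplitude extraction matches a dense-grid oracle", {
  b <- default_beats()
  s <- make_flat_stack(n = 75, fps = 25)
  ph <- compute_phase(s, b)
  phi <- ph$phase[ph$included]
  y <- rep(NA_real_, 75)
  y[ph$included] <- sin(2 * pi * phi) + 0.3 * cos(4 * pi * phi)
  fit <- fit_harmonic(y, ph, b)
  # brute force max - min on a 1e6-point grid
  grid <- seq(0, 1, length.out = 1e6)
  cg <- sin(2 * pi * grid) + 0.3 * cos(4 * pi * grid)
  expect_equal(amplitude_from_fit(fit), max(cg) - min(cg), tolerance = 1e-6)
  # randomized harmonics vs the same oracle
  set.seed(77)
  for (rep in 1:5) {
    a <- rnorm(2); bb <- rnorm(2)
    yr <- rep(NA_real_, 75)
    yr[ph$included] <- a[1] * cos(2 * pi * phi) + bb[1] * sin(2 * pi * phi) +
      a[2] * cos(4 * pi * phi) + bb[2] * sin(4 * pi * phi)
    fr <- fit_harmonic(yr, ph, b)
    cg <- a[1] * cos(2 * pi * grid) + bb[1] * sin(2 * pi * grid) +
      a[2] * cos(4 * pi * grid) + bb[2] * sin(4 * pi * grid)
    expect_equal(amplitude_from_fit(fr), max(cg) - min(cg), tolerance = 1e-6)
  }
})

test_that("amplitude_map recovers simulator truth and matches grid shape", {
  sim <- generate(small_scene(seed = 2))
  ph <- compute_phase(sim$stack, sim$beats)
  tr <- lapply(extract_green(sim$stack), beer_lambert_transform)
  cube <- cluster_means(tr, phase = ph)
  map <- amplitude_map(cube, sim$beats)
  expect_equal(dim(map$amplitude), c(cube$n_rows, cube$n_cols))
  ta <- sim$truth$cluster_amplitude
  full <- abs(ta - 10) < 1e-9
  expect_gt(sum(full), 3)
  expect_true(all(abs(map$amplitude[full] - 10) < 1))
  expect_true(all(map$amplitude[ta == 0] < 1))
})

test_that("uniform non-pulsatile stack yields an all-zero map", {
  g <- replicate(75, matrix(55, 20, 20), simplify = FALSE)
  s <- stack_from_green(g)
  ph <- compute_phase(s, default_beats())
  cube <- cluster_means(lapply(g, beer_lambert_transform), phase = ph)
  map <- amplitude_map(cube, default_beats())
  expect_true(all(map$amplitude == 0))
})

test_that("amplitude_map is equivariant under frame flips", {
  sim <- generate(small_scene(seed = 6))
  ph <- compute_phase(sim$stack, sim$beats)
  tr <- lapply(extract_green(sim$stack), beer_lambert_transform)
  map <- amplitude_map(cluster_means(tr, phase = ph), sim$beats)
  # horizontal flip
  trh <- lapply(tr, function(m) m[, ncol(m):1])
  maph <- amplitude_map(cluster_means(trh, phase = ph), sim$beats)
  expect_equal(maph$amplitude, map$amplitude[, ncol(map$amplitude):1],
               tolerance = 1e-10)
  # vertical flip
  trv <- lapply(tr, function(m) m[nrow(m):1, ])
  mapv <- amplitude_map(cluster_means(trv, phase = ph), sim$beats)
  expect_equal(mapv$amplitude, map$amplitude[nrow(map$amplitude):1, ],
               tolerance = 1e-10)
})

test_that("noisy recovery stays within 15 percent", {
  sim <- generate(small_scene(noise_sd = 2, seed = 8))
  ph <- compute_phase(sim$stack, sim$beats)
  tr <- lapply(extract_green(sim$stack), beer_lambert_transform)
  map <- amplitude_map(cluster_means(tr, phase = ph), sim$beats)
  ta <- sim$truth$cluster_amplitude
  full <- abs(ta - 10) < 1e-9
  expect_true(all(abs(map$amplitude[full] / 10 - 1) < 0.15))
})

test_that("illumination index: hand arithmetic and drift monotonicity", {
  g <- list(matrix(10, 6, 6), matrix(12, 6, 6), matrix(14, 6, 6))
  s <- stack_from_green(g)
  idx <- illumination_index(s)
  expect_equal(idx$mean_intensity, 12)
  expect_equal(idx$sd_intensity, 2)
  # constant stack -> sd 0
  s0 <- make_flat_stack(n = 4, value = 100)
  expect_equal(illumination_index(s0)$sd_intensity, 0)
  # increasing drift amplitude strictly increases the measured sd
  sds <- vapply(c(0.005, 0.02, 0.05), function(da) {
    sim <- generate(small_scene(drift_amp = da, seed = 3))
    illumination_index(sim$stack)$sd_intensity
  }, 0)
  expect_true(all(diff(sds) > 0))
})

test_that("amplitude CSV and heat-map renderer write well-formed output", {
  sim <- generate(small_scene(seed = 2))
  ph <- compute_phase(sim$stack, sim$beats)
  tr <- lapply(extract_green(sim$stack), beer_lambert_transform)
  map <- amplitude_map(cluster_means(tr, phase = ph), sim$beats)
  p <- tempfile(fileext = ".csv")
  write_amplitude_csv(map, p)
  df <- read.csv(p)
  expect_equal(nrow(df), map$n_rows * map$n_cols)
  expect_equal(df$amplitude[df$row == 2 & df$col == 3],
               map$amplitude[3, 4])
  p2 <- tempfile(fileext = ".png")
  write_heatmap_png(map, p2)
  img <- png::readPNG(p2)
  expect_equal(dim(img)[1:2], c(map$n_rows, map$n_cols))
})
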