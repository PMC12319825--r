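test_that("band-pass gain matches an FFT oracle at key frequencies", {
  n <- 200
  tr <- 2
  t <- seq_len(n) * tr
  st <- filter_settings(band_hz = c(0.01, 0.1))
  gain_at <- function(f_hz) {
    x <- sin(2 * pi * f_hz * t)
    run <- make_run(cbind(x), tr = tr)
    y <- bandpass(run, st)$data[, 1]
    # FFT amplitude at the probe frequency, before vs after
    bin <- which.min(abs(seq(0, n - 1) / (n * tr) - f_hz))
    Mod(fft(y))[bin] / Mod(fft(x))[bin]
  }
  expect_gte(gain_at(0.05), 0.9)   # passband centre
  expect_lte(gain_at(0.05), 1.1)
  expect_lt(gain_at(0.2), 0.1)     # stopband
  expect_lt(gain_at(0.002), 0.1)   # below the low edge
})

test_that("band-pass removes DC and preserves shape", {
  run <- make_run(matrix(5, 96, 3))
  out <- bandpass(run, filter_settings())
  expect_equal(dim(out$data), c(96, 3))
  expect_equal(max(abs(out$data)), 0) # constant in, exactly zero out
  run2 <- tiny_run()
  out2 <- bandpass(scrub(run2, filter_settings()), filter_settings())
  expect_lt(max(abs(colMeans(out2$data))), 1e-8)
})

test_that("band-pass agrees with a DFT mask filter at interior frequencies", {
  # compare against an ideal DFT band mask on band-limited content away
  # from the filter edges; the Butterworth response is ~1 there
  set.seed(4)
  n <- 256
  tr <- 2
  x <- band_limited_signals(n, 4, tr, c(0.03, 0.07)) # interior of the band
  run <- make_run(x, tr = tr)
  y <- bandpass(run, filter_settings(band_hz = c(0.01, 0.1)))$data
  # compare away from the series ends, where the finite-length filter's
  # edge transient (absent from the circular DFT oracle) lives
  int <- 33:(n - 32)
  rel_rms <- sqrt(colSums((y[int, ] - x[int, ])^2) / colSums(x[int, ]^2))
  expect_true(all(rel_rms < 0.05))
})

test_that("band-pass refuses short series and invalid bands", {
  run <- make_run(matrix(rnorm(40 * 2), 40))
  expect_error(bandpass(run, filter_settings()), "64")
  expect_error(filter_settings(band_hz = c(0, 0.1)), "positive")
  run96 <- make_run(matrix(rnorm(96 * 2), 96), tr = 2)
  expect_error(bandpass(run96, filter_settings(band_hz = c(0.01, 0.3))),
               "Nyquist")
})

test_that("nuisance regression removes regressors exactly", {
  set.seed(5)
  n <- 96
  wm <- rnorm(n)
  noise <- rnorm(n)
  run <- make_run(cbind(3 * wm + noise, 2 * wm), wm = wm)
  out <- nuisance_regress(run, regressors = cbind(wm))
  # residuals orthogonal to the regressor
  expect_lt(abs(sum(out$data[, 1] * wm)) / sqrt(sum(wm^2)), 1e-8)
  # a voxel that is exactly a multiple of wm is annihilated
  expect_lt(max(abs(out$data[, 2])), 1e-10)
})

test_that("empty regressor set reduces to demeaning", {
  x <- matrix(rnorm(96 * 3), 96)
  run <- make_run(x)
  out <- nuisance_regress(run, regressors = matrix(nrow = 96, ncol = 0))
  expect_equal(out$data, sweep(x, 2, colMeans(x)), tolerance = 1e-12)
})

test_that("duplicate regressor columns collapse to the same projection", {
  set.seed(6)
  wm <- rnorm(96)
  x <- matrix(rnorm(96 * 4), 96)
  run <- make_run(x)
  r1 <- nuisance_regress(run, regressors = cbind(wm))
  expect_warning(r2 <- nuisance_regress(run, regressors = cbind(wm, wm)),
                 "collinear")
  # oracle: residuals equal the explicit projection-matrix residual
  X <- cbind(1, wm)
  P <- diag(96) - X %*% solve(crossprod(X)) %*% t(X)
  expect_equal(r1$data, P %*% x, tolerance = 1e-10)
  expect_equal(r2$data, r1$data, tolerance = 1e-10)
})

test_that("nuisance regression is linear in the data", {
  set.seed(7)
  wm <- rnorm(96)
  csf <- rnorm(96)
  x <- matrix(rnorm(96 * 2), 96)
  y <- matrix(rnorm(96 * 2), 96)
  reg <- cbind(wm, csf)
  f <- function(d) nuisance_regress(make_run(d), regressors = reg)$data
  expect_equal(f(2 * x + 3 * y), 2 * f(x) + 3 * f(y), tolerance = 1e-10)
})

test_that("scrubbing censors exactly the high-motion frames, idempotently", {
  st <- filter_settings(fd_threshold_mm = 0.5)
  fd <- rep(0, 96)
  run <- make_run(matrix(rnorm(96 * 2), 96), fd = fd)
  expect_true(all(scrub(run, st)$censor))
  fd[c(10, 20)] <- 0.5 + 1e-6
  run2 <- make_run(matrix(rnorm(96 * 2), 96), fd = fd)
  s1 <- scrub(run2, st)
  expect_identical(which(!s1$censor), c(10L, 20L))
  expect_identical(scrub(s1, st)$censor, s1$censor)
  # boundary: fd exactly at the threshold is kept
  fd3 <- rep(0.5, 96)
  expect_true(all(scrub(make_run(matrix(0, 96, 1), fd = fd3), st)$censor))
})

test_that("scrubbing censors the planted spike frames exactly", {
  spec <- tiny_spec(spike_prob = 0.05)
  run <- simulate_run(spec, tiny_geom(), plant_design(spec, tiny_geom()), 1, 2)
  out <- scrub(run, filter_settings())
  expect_identical(which(!out$censor), run$spike_frames)
})

test_that("runs losing over half their frames are flagged for exclusion", {
  fd <- rep(2, 96)
  fd[1:40] <- 0
  run <- make_run(matrix(rnorm(96), 96), fd = fd)
  expect_warning(out <- scrub(run, filter_settings()), "exclusion")
  expect_true(attr(out, "excluded"))
  expect_null(suppressWarnings(preprocess_run(run, filter_settings())))
})

test_that("smoothing preserves constants and is an identity at fwhm 0", {
  g <- tiny_geom()
  st <- filter_settings(fwhm_mm = 1.5, voxel_mm = 1.25)
  const <- rep(3.7, g$n_voxels)
  expect_equal(smooth_volume(const, g, st), const, tolerance = 1e-12)
  x <- rnorm(g$n_voxels)
  expect_identical(smooth_volume(x, g, filter_settings(fwhm_mm = 0)), x)
})

test_that("smoothing an impulse reproduces the discrete Gaussian kernel", {
  g <- tiny_geom()
  st <- filter_settings(fwhm_mm = 1.5, voxel_mm = 1.25)
  sigma <- 1.5 / (2 * sqrt(2 * log(2))) / 1.25
  radius <- ceiling(3 * sigma)
  k1 <- dnorm(seq(-radius, radius), sd = sigma)
  k1 <- k1 / sum(k1)
  # put the impulse well inside the volume
  vox <- g$voxels
  centre <- which(vox$i == 6 & vox$j == 7 & vox$k == 4)
  x <- rep(0, g$n_voxels)
  x[centre] <- 1
  y <- smooth_volume(x, g, st)
  # centre value = product of the three central 1D weights
  expect_equal(y[centre], k1[radius + 1]^3, tolerance = 1e-10)
  # an axis neighbour gets k0^2 * k1
  nb <- which(vox$i == 7 & vox$j == 7 & vox$k == 4)
  expect_equal(y[nb], k1[radius + 1]^2 * k1[radius + 2], tolerance = 1e-10)
  # total mass preserved (kernel fully inside the mask)
  expect_equal(sum(y), 1, tolerance = 1e-6)
})

test_that("preprocessing pipeline runs scrub -> bandpass -> regression", {
  run <- tiny_run_pre()
  expect_s3_class(run, "run_ts")
  # censored spike frames are gone and the censor vector is all-true
  expect_true(all(run$censor))
  expect_equal(nrow(run$data), 96 - length(tiny_run()$spike_frames))
  # residuals orthogonal to the (filtered) nuisance traces
  ip <- crossprod(run$data, as.matrix(run$nuisance[, c("wm", "csf")]))
  expect_lt(max(abs(ip)) / nrow(run$data), 1e-6)
})
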