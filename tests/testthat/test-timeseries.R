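# Area-series analyses: regression, spectra, dominant frequency, forces.

test_that("area_series validates its invariants", {
  s <- area_series(c(10, 12, 11), fs_hz = 30)
  expect_equal(s$time_s, c(0, 1, 2) / 30)
  expect_error(area_series(c(-1, 2, 3)), ">= 0")
  expect_error(area_series(1:5, fs_hz = 0), "fs_hz")
  expect_error(area_series(1:3, fs_hz = 30, time_s = c(0, 2, 1)),
               "increasing")
  expect_error(area_series(1:3, fs_hz = 30, time_s = c(0, 0.5, 1)),
               "inconsistent")
})

test_that("linear_fit recovers an exact linear relation", {
  x <- seq(1, 50)
  fit <- linear_fit(x, 2 * x + 1)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("r_squared equals the squared Pearson correlation", {
  for (s in 1:5) {
    set.seed(s)
    x <- rnorm(1000, 5000, 400)
    y <- rnorm(1000, 4000, 300)
    fit <- linear_fit(x, y)
    expect_equal(fit$r_squared, cor(x, y)^2, tolerance = 1e-12)
    expect_gte(fit$r_squared, 0)
    expect_lte(fit$r_squared, 1)
  }
})

test_that("degenerate regressions behave as documented", {
  expect_error(linear_fit(rep(3, 10), rnorm(10)), "constant")
  expect_warning(fit <- linear_fit(1:10, rep(5, 10)), "constant")
  expect_identical(fit$r_squared, 0)
  expect_error(linear_fit(1:2, 1:2), "at least 3")
  expect_error(linear_fit(1:4, 1:5), "equal length")
})

test_that("r_squared is invariant under affine transforms of x", {
  set.seed(99)
  x <- rnorm(200, 100, 20)
  y <- 0.3 * x + rnorm(200, 0, 5)
  base <- linear_fit(x, y)
  shifted <- linear_fit(3.7 * x - 250, y)
  expect_equal(shifted$r_squared, base$r_squared, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(shifted$slope, base$slope)))
})

test_that("spectrum of a constant series is numerically zero", {
  s <- area_series(rep(5000, 64), fs_hz = 30)
  spec <- compute_spectrum(s, pad_factor = 4)
  expect_true(all(spec$magnitude < 1e-9 * 5000))
})

test_that("a pure sinusoid yields a single peak at its frequency", {
  fs <- 30; t <- (0:(60 * fs - 1)) / fs
  s <- area_series(5000 + 300 * sin(2 * pi * 0.5 * t), fs_hz = fs)
  spec <- compute_spectrum(s, pad_factor = 8)
  pk <- dominant_frequency(spec)
  bin <- fs / (8 * length(t))
  expect_lt(abs(pk["frequency_hz"] - 0.5), bin + 1e-12)
  expect_equal(unname(pk["magnitude"]), 300, tolerance = 0.01)
  expect_lte(max(spec$frequency_hz), fs / 2)
  expect_lt(max(abs(diff(spec$frequency_hz) - bin)), 1e-12)
})

test_that("two-tone amplitudes keep their 3:1 ratio", {
  fs <- 30; t <- (0:(60 * fs - 1)) / fs
  x <- 3 * sin(2 * pi * 0.47 * t) + 1 * sin(2 * pi * 1.3 * t)
  spec <- compute_spectrum(area_series(x + 10, fs_hz = fs), pad_factor = 8)
  m047 <- max(spec$magnitude[abs(spec$frequency_hz - 0.47) < 0.05])
  m13 <- max(spec$magnitude[abs(spec$frequency_hz - 1.3) < 0.05])
  expect_equal(m047 / m13, 3, tolerance = 0.05)
})

test_that("spectral energy matches time-domain energy (Parseval)", {
  set.seed(5)
  x <- rnorm(256, 0, 2)
  x <- x - mean(x)
  n <- length(x)
  spec <- compute_spectrum(area_series(x + 100, fs_hz = 30), pad_factor = 1)
  m <- spec$magnitude
  # undo the single-sided 2/n scaling (DC and Nyquist counted once)
  full <- (m[1] * n)^2 + (m[n / 2 + 1] * n)^2 +
    sum((m[2:(n / 2)] * n / 2)^2) * 2
  expect_equal(full / n, sum(x^2), tolerance = 1e-9)
})

test_that("dominant_frequency honours min_hz, ties and degenerate input", {
  fs <- 30; t <- (0:599) / fs
  # equal-amplitude tones: the lower frequency wins the tie
  x <- sin(2 * pi * 0.5 * t) + sin(2 * pi * 1.5 * t)
  spec <- compute_spectrum(area_series(x + 10, fs_hz = fs), pad_factor = 4)
  pk <- dominant_frequency(spec)
  expect_lt(abs(pk["frequency_hz"] - 0.5), fs / (4 * 600) + 1e-12)

  const <- compute_spectrum(area_series(rep(3, 64), fs_hz = fs))
  expect_error(dominant_frequency(const), "no periodicity")
  expect_error(compute_spectrum(area_series(rep(3, 4), fs_hz = fs)),
               "at least 8")
})

test_that("seeded oscillations are recovered within one padded bin", {
  fs <- 30; n <- 600; pad <- 8
  t <- (0:(n - 1)) / fs
  bin <- fs / (pad * n)
  set.seed(123)
  freqs <- runif(50, 0.3, 1.0)
  for (f0 in freqs) {
    x <- 5000 + 400 * sin(2 * pi * f0 * t + runif(1, 0, 2 * pi)) +
      rnorm(n, 0, 20)
    pk <- dominant_frequency(compute_spectrum(area_series(pmax(x, 0),
                                                          fs_hz = fs),
                                              pad_factor = pad))
    expect_lt(abs(pk["frequency_hz"] - f0), bin + 1e-12)
  }
})

test_that("resistive force follows the quadratic drag law", {
  p <- drag_params(c_r = 0.3, rho = 1000)
  expect_equal(resistive_force(p, 0.1, 2), 60)
  expect_equal(resistive_force(p, 0.25, 0), 0)
  # v -> 2v quadruples the force, exactly
  expect_identical(resistive_force(p, 0.17, 2.6),
                   resistive_force(p, 0.17, 1.3) * 4)
  # homogeneous in area (power-of-two factor scales exactly)
  expect_identical(resistive_force(p, 4 * 0.08, 1.7),
                   4 * resistive_force(p, 0.08, 1.7))
  expect_error(resistive_force(p, -0.1, 1), ">= 0")
  expect_error(drag_params(0.3, rho = -1), "rho")
})

test_that("pixel-to-metric conversion is exact unit bookkeeping", {
  expect_equal(pixels_to_m2(0, 6.23), 0)
  expect_equal(pixels_to_m2(1, 6.23), 6.23e-6)
  expect_equal(pixels_to_m2(10000, 1), 0.01)
  expect_error(pixels_to_m2(10, 0), "> 0")
})

test_that("force balance gives zero acceleration at constant speed", {
  expect_equal(net_force_acceleration(68, 150, -150), 0)
  expect_equal(net_force_acceleration(68, 68, 0), 1)
  expect_equal(net_force_acceleration(70, 0, 0), 0)
  expect_error(net_force_acceleration(0, 1, 1), "> 0")
})
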