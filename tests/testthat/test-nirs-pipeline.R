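test_that("Beer-Lambert inversion is the exact linear inverse of the forward map", {
  p <- mbll_params()
  z <- mbll_inverse(rep(0, 10), rep(0, 10), p)
  expect_identical(z$hbo, rep(0, 10))
  expect_identical(z$hbr, rep(0, 10))

  # forward-composed constant concentrations recover exactly
  od <- mbll_forward(rep(0.01, 5), rep(-0.004, 5), p)
  back <- mbll_inverse(od$od1, od$od2, p)
  expect_lt(max(abs(back$hbo - 0.01)), 1e-12)
  expect_lt(max(abs(back$hbr + 0.004)), 1e-12)

  # linearity: doubling OD doubles concentrations
  a <- mbll_inverse(od$od1, od$od2, p)
  b <- mbll_inverse(2 * od$od1, 2 * od$od2, p)
  expect_equal(b$hbo, 2 * a$hbo, tolerance = 1e-12)

  # rho enters linearly in the forward map
  p2 <- mbll_params(rho = 6)
  od2 <- mbll_forward(rep(0.01, 5), rep(-0.004, 5), p2)
  expect_equal(od2$od1, 2 * od$od1, tolerance = 1e-12)
})

test_that("random-series Beer-Lambert round trips hold for several parameter sets", {
  set.seed(1)
  params <- list(mbll_params(),
                 mbll_params(dpf = c(5.5, 4.9), rho = 2.5),
                 mbll_params(eps = matrix(c(0.7, 1.2, 1.4, 0.6), 2,
                                          byrow = TRUE), dpf = c(6.2, 5.8)))
  for (p in params) {
    hbo <- rnorm(200, sd = 0.01)
    hbr <- rnorm(200, sd = 0.004)
    od <- mbll_forward(hbo, hbr, p)
    back <- mbll_inverse(od$od1, od$od2, p)
    expect_lt(max(abs(back$hbo - hbo)) / max(abs(hbo)), 1e-12)
    expect_lt(max(abs(back$hbr - hbr)) / max(abs(hbr)), 1e-12)
  }
})

test_that("degenerate Beer-Lambert parameters are rejected", {
  expect_error(mbll_params(eps = matrix(c(1, 1, 1, 1), 2)), "singular")
  expect_error(mbll_params(rho = 0), "rho")
  expect_error(mbll_inverse(1:5, 1:4), "length")
})

test_that("band-pass rejects DC, keeps 0.05 Hz and removes 1 Hz", {
  fs <- 10
  t <- seq(0, 4000, by = 1 / fs)

  const <- rep(3.5, length(t))
  expect_lt(max(abs(bandpass(const, fs))), 1e-6 * 3.5)

  cen <- seq(length(t) %/% 4, 3 * length(t) %/% 4)
  inband <- sin(2 * pi * 0.05 * t)
  y <- bandpass(inband, fs)
  expect_gt(max(abs(y[cen])), 0.95)
  expect_lt(max(abs(y[cen])), 1.05)

  out <- sin(2 * pi * 1 * t)
  expect_lt(max(abs(bandpass(out, fs)[cen])), 0.1)
})

test_that("band-pass is linear and zero-phase", {
  fs <- 10
  set.seed(2)
  x <- rnorm(2000); y <- rnorm(2000)
  lhs <- bandpass(2.5 * x - 1.3 * y, fs)
  rhs <- 2.5 * bandpass(x, fs) - 1.3 * bandpass(y, fs)
  expect_lt(max(abs(lhs - rhs)), 1e-9)

  # cross-correlation between an in-band input and its output peaks at lag 0
  t <- seq(0, 4000, by = 1 / fs)
  s <- sin(2 * pi * 0.05 * t)
  f <- bandpass(s, fs)
  lags <- -10:10
  cc <- vapply(lags, function(L) {
    idx <- seq(500, length(s) - 500)
    sum(s[idx] * f[idx + L])
  }, numeric(1))
  expect_identical(lags[which.max(cc)], 0L)

  expect_error(bandpass(x, fs, low = 0.09, high = 0.01), "band edges")
  expect_error(bandpass(x, fs, low = 0.01, high = 6), "band edges")
})

test_that("polyphase resampling preserves constants, lengths and slow sinusoids", {
  const <- rep(3.7, 1000)
  r <- resample_ts(const, 12.5, 10)
  expect_length(r, 800)
  expect_lt(max(abs(r[4:797] - 3.7)), 1e-9)

  # 0.05 Hz sinusoid lands on the analytic values of the new grid
  n <- 10000
  x <- sin(2 * pi * 0.05 * (0:(n - 1)) / 12.5)
  y <- resample_ts(x, 12.5, 10)
  ref <- sin(2 * pi * 0.05 * (0:(length(y) - 1)) / 10)
  cen <- seq(length(y) %/% 4, 3 * length(y) %/% 4)
  expect_lt(max(abs(y[cen] - ref[cen])), 0.01)

  # 1000 -> 200 Hz (single-branch path)
  z <- resample_ts(sin(2 * pi * 5 * (0:9999) / 1000), 1000, 200)
  expect_length(z, 2000)
  refz <- sin(2 * pi * 5 * (0:1999) / 200)
  cz <- seq(500, 1500)
  expect_lt(max(abs(z[cz] - refz[cz])), 0.01)

  expect_error(resample_ts(const, 10, 12.5), "upsampling")
})

test_that("in-band energy survives resampling within 2%", {
  for (f0 in c(0.5, 1.5, 3.5)) {  # all < 0.4 * fs_out = 4 Hz
    x <- sin(2 * pi * f0 * (0:19999) / 12.5)
    y <- resample_ts(x, 12.5, 10)
    cen_in <- seq(5000, 15000)
    cen_out <- seq(4000, 12000)
    e_in <- mean(x[cen_in]^2)
    e_out <- mean(y[cen_out]^2)
    expect_lt(abs(e_out - e_in) / e_in, 0.02)
  }
})

test_that("recording-level wrappers track markers across rate changes", {
  cfg <- tiny_cfg(n_subjects = 1, trials_per_session = 5)
  rec <- generate_dataset(cfg, modalities = "od")[[1]]$od
  hemo <- od_to_hemo(rec)
  down <- resample_recording(hemo$hbo, 10)
  expect_equal(down$fs, 10)
  expect_equal(down$markers$onset_sample,
               as.integer(round((rec$markers$onset_sample - 1) * 10 / 12.5)) + 1L)
  expect_equal(ncol(down$data), round(ncol(rec$data) * 10 / 12.5))
})
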