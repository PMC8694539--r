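test_that("downsampling: length arithmetic, passband preservation, stopband rejection", {
  fs_in <- 20000
  x <- sin(2 * pi * 100 * (0:19999) / fs_in)
  y <- downsample_signal(x, fs_in, 4000)
  expect_length(y, 4000L)
  core <- 200:3800  # away from edge transients
  expect_equal(sqrt(mean(y[core]^2)) / sqrt(mean(x^2)), 1, tolerance = 0.01)

  x2 <- sin(2 * pi * 2500 * (0:19999) / fs_in)
  y2 <- downsample_signal(x2, fs_in, 4000)
  atten_db <- 10 * log10(mean(x2^2) / max(mean(y2^2), 1e-30))
  expect_gt(atten_db, 40)

  expect_error(downsample_signal(x, 4000, 20000), "exceeds")
  expect_identical(downsample_signal(x, 4000, 4000), x)
})

test_that("AR fitting: white noise selects order 0, AR(2) parameters recovered", {
  ok <- 0L
  for (i in 1:20) {
    set.seed(i)
    m <- fit_ar_noise_model(rnorm(1e5), max_order = 10)
    if (m$order == 0L || all(abs(m$coefficients) < 0.05)) ok <- ok + 1L
  }
  expect_gte(ok, 18L)

  a <- c(0.5, -0.25)
  x <- simulate_sensor_noise(ar_noise_model(a, 1), 1e5, seed = 4)
  m2 <- fit_ar_noise_model(x, max_order = 10)
  expect_equal(m2$order, 2L)
  expect_equal(m2$coefficients, a, tolerance = 0.02)

  m0 <- fit_ar_noise_model(rnorm(500), max_order = 0)
  expect_equal(m0$order, 0L)
  expect_error(fit_ar_noise_model(rnorm(100), max_order = 10), "too short")
})

test_that("whitening: identity at order 0, hand convolution, flattens AR noise", {
  x <- rnorm(50)
  expect_identical(whiten(x, ar_noise_model(numeric(0), 1)), x)

  imp <- c(1, rep(0, 9))
  expect_equal(whiten(imp, ar_noise_model(0.5, 1)),
               c(1, -0.5, rep(0, 8)))

  mod <- ar_noise_model(c(0.5, -0.25), 1)
  pass <- 0L
  for (i in 1:50) {
    z <- whiten(simulate_sensor_noise(mod, 4000, seed = i), mod)
    if (stats::Box.test(z, lag = 10, type = "Ljung-Box")$p.value > 0.05) {
      pass <- pass + 1L
    }
  }
  expect_gte(pass, 45L)  # >= 90% portmanteau pass rate at alpha = 0.05
})

test_that("spline detrending annihilates cubic polynomials and preserves bursts", {
  fs <- 4000
  tt <- (0:11999) / fs
  poly <- 2 + 3 * tt - 1.5 * tt^2 + 0.7 * tt^3
  res <- remove_motion_spline(poly, fs)
  expect_lt(max(abs(res)), 1e-6 * max(abs(poly)))
  expect_lt(abs(mean(res)), 1e-8)
  expect_identical(max(abs(remove_motion_spline(numeric(8000), fs))), 0)

  ## 500 Hz burst riding on a large 0.2 Hz drift
  burst <- sin(2 * pi * 500 * tt) * exp(-0.5 * ((tt - 1.5) / 0.1)^2)
  drift <- 10 * sin(2 * pi * 0.2 * tt)
  cleaned <- remove_motion_spline(burst + drift, fs)
  bp <- function(x, lo, hi) {
    psd <- welch_psd(x, fs, nperseg = 4096L)
    sum(psd$power[psd$freq >= lo & psd$freq <= hi])
  }
  expect_lt(bp(cleaned, 0, 1) / bp(burst + drift, 0, 1), 0.10)
  expect_gt(bp(cleaned, 400, 600) / bp(burst + drift, 400, 600), 0.95)

  expect_error(remove_motion_spline(rnorm(100), fs), "knot intervals")
})

test_that("wavelet denoising: identity without threshold, never adds energy, recovers bursts", {
  set.seed(41)
  x <- rnorm(5000)
  ident <- wavelet_denoise(x, preprocess_config(threshold_scale = 0))
  expect_equal(ident, x, tolerance = 1e-4)

  cfg <- preprocess_config()
  expect_identical(wavelet_denoise(numeric(4096), cfg), numeric(4096))
  expect_error(wavelet_denoise(c(1, NA, 3), cfg), "non-finite")
  for (i in 1:5) {
    set.seed(i)
    z <- rnorm(3000)
    expect_lte(sum(wavelet_denoise(z, cfg)^2), sum(z^2) * (1 + 1e-6))
  }

  ## transient burst + white noise at 0 dB: output SNR improves by >= 5 dB
  fs <- 4000
  bm <- list(n_bursts = 1L, band = c(300, 600), width_range_s = c(0.01, 0.01),
             amplitude = 0.3, amplitude_jitter_sd = 0, centers = 1.0,
             widths = 0.01)
  clean <- simulate_swallow_burst(bm, 2.0, fs, seed = 3)
  set.seed(9)
  noise <- rnorm(length(clean))
  noise <- noise * sqrt(mean(clean^2) / mean(noise^2))
  den <- wavelet_denoise(clean + noise, cfg)
  snr_out <- 10 * log10(mean(clean^2) / mean((den - clean)^2))
  expect_gt(snr_out, 5)
})

test_that("full chain: zero in, zero out; target rate; drift suppressed", {
  zero_seg <- make_test_segment(seed = 1)
  zero_seg$channels <- lapply(zero_seg$channels, function(x) x * 0)
  zero_seg$fs <- 20000
  out <- preprocess_segment(zero_seg, preprocess_config())
  expect_true(all(vapply(out$channels, function(x) all(x == 0), logical(1))))
  expect_equal(out$fs, 4000)

  cfg <- cohort_config(n_participants = 2,
                       swallows_per_material = c(barium = 2, water = 2),
                       seed = 55, baseline_duration_s = 1,
                       motion_drift = list(amplitude = 0.2, cutoff_hz = 0.5))
  co <- generate_cohort(cfg)
  models <- fit_baseline_models(co$baselines[["P01"]])
  seg <- co$segments[[2]]
  out <- preprocess_segment(seg, preprocess_config(), models)
  expect_equal(out$fs, 4000)
  expect_identical(out$processing$ar_source, "baseline")

  ## compare low-band power at a common rate and resolution: chain output
  ## vs the merely-downsampled raw channel
  bp <- function(x, fs, lo, hi) {
    psd <- welch_psd(x, fs, nperseg = 8192L)
    sum(psd$power[psd$freq >= lo & psd$freq <= hi])
  }
  raw_low <- bp(downsample_signal(seg$channels$SI, seg$fs, out$fs), out$fs, 0, 1)
  out_low <- bp(out$channels$SI, out$fs, 0, 1)
  expect_lt(out_low / raw_low, 0.10)

  ## determinism of the chain
  out2 <- preprocess_segment(seg, preprocess_config(), models)
  expect_identical(out$channels, out2$channels)
})
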