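test_that("time features: symmetry, Gaussian kurtosis, scale behavior, degenerate input", {
  alt <- rep(c(1, -1), 50)
  expect_equal(unname(time_features(alt)["skewness"]), 0)

  set.seed(3)
  g <- rnorm(1e6)
  expect_equal(unname(time_features(g)["kurtosis"]), 3, tolerance = 0.02)

  x <- rnorm(500)
  f1 <- time_features(x)
  f2 <- time_features(-2.5 * x)
  expect_equal(unname(f2["std_dev"]), unname(2.5 * f1["std_dev"]))
  expect_equal(unname(f2["skewness"]), unname(-f1["skewness"]))
  expect_equal(unname(f2["kurtosis"]), unname(f1["kurtosis"]))

  cst <- time_features(rep(4, 100))
  expect_equal(unname(cst["std_dev"]), 0)
  expect_true(is.nan(cst["skewness"]) && is.nan(cst["kurtosis"]))
})

test_that("spectral features: line spectrum, flat spectrum, two-tone centroid", {
  fs <- 4000
  tone <- sin(2 * pi * 250 * (0:7999) / fs)  # exactly bin-centered at 256-pt Welch
  sf <- spectral_features(tone, fs)
  expect_equal(unname(sf["peak_frequency"]), 250)
  expect_equal(unname(sf["spectral_centroid"]), 250, tolerance = 1)
  expect_lt(unname(sf["bandwidth"]), fs / 256)  # within one resolution bin

  set.seed(11)
  wn <- rnorm(2e4)
  expect_equal(unname(spectral_features(wn, fs)["spectral_centroid"]),
               fs / 4, tolerance = 0.05 * fs / 4)

  tt <- (0:19999) / fs
  two <- sin(2 * pi * 200 * tt) + sin(2 * pi * 600 * tt)
  expect_equal(unname(spectral_features(two, fs)["spectral_centroid"]),
               400, tolerance = 10)

  expect_error(spectral_features(numeric(1000), fs), "all-zero")
  expect_error(spectral_features(rnorm(10), fs), "64")
})

test_that("wavelet entropy: degenerate band, equal-energy bands, scale invariance", {
  fs <- 4000
  tone <- sin(2 * pi * 350 * (0:8191) / fs)
  expect_lt(wavelet_entropy(tone), 0.15)

  ## equal energy in k subbands, built through the inverse transform
  blank <- hrca_dwt(numeric(1024), 5L)
  for (k in c(2L, 4L)) {
    d <- blank
    set.seed(k)
    for (j in seq_len(k)) {
      v <- rnorm(length(d$details[[j]]))
      d$details[[j]] <- v / sqrt(sum(v^2))
    }
    expect_equal(wavelet_entropy(hrca_idwt(d), 5L), log(k), tolerance = 1e-6)
  }

  set.seed(6)
  x <- rnorm(4096)
  expect_equal(wavelet_entropy(17 * x), wavelet_entropy(x), tolerance = 1e-10)
  expect_error(wavelet_entropy(numeric(1024)), "zero-energy")
})

test_that("LZ76: hand-parsed example, constants, asymptotic normalization", {
  bits <- as.integer(strsplit("0001101001000101", "")[[1]])
  expect_equal(lz76_count(bits), 6L)
  expect_equal(lz76_oracle(bits), 6L)

  ## a constant sequence parses into first symbol + reproducible remainder
  expect_equal(lz76_count(rep(0L, 64)), 2L)
  expect_equal(lz76_oracle(rep(0L, 64)), 2L)

  set.seed(14)
  expect_equal(lz_complexity(rnorm(1e5)), 1.0, tolerance = 0.05)

  ## scale invariance through the median binarization
  x <- rnorm(2000)
  expect_equal(lz_complexity(3 * x), lz_complexity(x))
})

test_that("LZ76 fast parser agrees with the brute-force oracle on short strings", {
  set.seed(8)
  for (len in c(3L, 5L, 8L, 12L)) {
    for (rep in 1:40) {
      bits <- sample(0:1, len, replace = TRUE)
      expect_equal(lz76_count(bits), lz76_oracle(bits),
                   info = paste(bits, collapse = ""))
    }
  }
})

test_that("entropy rate: periodic signals regular, i.i.d. noise irregular, bounded", {
  per <- sin(2 * pi * (0:3999) / 40)
  expect_gte(entropy_rate(per), 0.9)

  set.seed(15)
  expect_lte(entropy_rate(runif(1e4)), 0.2)

  for (i in 1:5) {
    set.seed(i)
    r <- entropy_rate(rnorm(1500))
    expect_gte(r, 0)
    expect_lte(r, 1)
  }
  expect_equal(entropy_rate(rep(2, 1200)), 1)
  expect_error(entropy_rate(rnorm(500)), "1000")
})

test_that("word entropies match the naive dictionary-counting oracle", {
  set.seed(20)
  for (L in c(1L, 2L, 4L)) {
    symbols <- sample(0:9, 400, replace = TRUE)
    fast <- hrcascreen:::word_entropy(symbols, L)
    slow <- word_entropy_oracle(symbols, L)
    expect_equal(fast$entropy, slow$entropy, tolerance = 1e-12)
    expect_equal(fast$frac_single, slow$frac_single, tolerance = 1e-12)
  }
})

test_that("a swallow yields exactly 36 named features, deterministically", {
  seg <- make_test_segment(seed = 7)
  fv <- extract_features(seg)
  expect_length(fv, 36L)
  expect_identical(names(fv), feature_column_names())
  expect_true(all(is.finite(fv)))
  expect_identical(fv, extract_features(seg))

  ## swapping channel contents moves the values with the channel labels
  seg2 <- seg
  seg2$channels$MIC <- seg$channels$AP
  seg2$channels$AP <- seg$channels$MIC
  fv2 <- extract_features(seg2)
  expect_equal(unname(fv2["std_dev_AP"]), unname(fv["std_dev_MIC"]))
  expect_equal(unname(fv2["lz_complexity_MIC"]), unname(fv["lz_complexity_AP"]))
})

test_that("degenerate channels yield NA features rather than errors", {
  seg <- make_test_segment(seed = 9)
  seg$channels$ML <- numeric(length(seg$channels$ML))
  fv <- extract_features(seg)
  expect_true(is.na(fv["spectral_centroid_ML"]))
  expect_true(is.na(fv["wavelet_entropy_ML"]))
  expect_equal(unname(fv["std_dev_ML"]), 0)
  expect_true(all(is.finite(fv[grep("_MIC$", names(fv))])))
})

test_that("amplitude-scale invariance holds across the feature set", {
  seg <- make_test_segment(seed = 12)
  fv <- extract_features(seg)
  seg2 <- seg
  seg2$channels <- lapply(seg$channels, function(x) 5 * x)
  fv2 <- extract_features(seg2)
  inv <- c("skewness", "kurtosis", "wavelet_entropy", "lz_complexity",
           "entropy_rate", "peak_frequency", "spectral_centroid", "bandwidth")
  for (feat in inv) {
    cols <- paste(feat, c("MIC", "AP", "SI", "ML"), sep = "_")
    expect_equal(fv2[cols], fv[cols], tolerance = 1e-8)
  }
  expect_equal(unname(fv2["std_dev_MIC"]), unname(5 * fv["std_dev_MIC"]))
})

test_that("null padding around a fixed burst lowers LZC and raises entropy rate", {
  fs <- 4000
  bm <- list(n_bursts = 2L, band = c(100, 800), width_range_s = c(0.03, 0.06),
             amplitude = 0.2, amplitude_jitter_sd = 0,
             centers = c(0.3, 0.7), widths = c(0.05, 0.05))
  burst <- simulate_swallow_burst(bm, 1.0, fs, seed = 30)
  pads <- c(0, 4000, 12000)
  lzc <- er <- numeric(length(pads))
  for (i in seq_along(pads)) {
    x <- c(numeric(pads[i]), burst, numeric(pads[i]))
    lzc[i] <- lz_complexity(x)
    er[i] <- entropy_rate(x)
  }
  expect_true(all(diff(lzc) < 0))
  expect_true(all(diff(er) > 0))
})
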