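test_that("default study-replica design: 185 swallows, 90/95, 19 participants", {
  cfg <- cohort_config()
  counts_b <- hrcascreen:::allocate_counts(cfg$swallows_per_material[["barium"]],
                                           cfg$n_participants)
  counts_w <- hrcascreen:::allocate_counts(cfg$swallows_per_material[["water"]],
                                           cfg$n_participants)
  expect_equal(sum(counts_b), 90)
  expect_equal(sum(counts_w), 95)
  expect_true(all(abs(counts_b - mean(counts_b)) <= 1))
})

test_that("cohort generation is deterministic for a fixed seed", {
  cfg <- cohort_config(n_participants = 2,
                       swallows_per_material = c(barium = 2, water = 2),
                       seed = 99, baseline_duration_s = 1)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$segments[[3]]$channels, b$segments[[3]]$channels)
  expect_identical(a$baselines[["P01"]]$channels, b$baselines[["P01"]]$channels)
})

test_that("segmentation regimes: barium frame-accurate, water padded", {
  cfg <- cohort_config(n_participants = 3,
                       swallows_per_material = c(barium = 6, water = 6),
                       seed = 5, baseline_duration_s = 1)
  co <- generate_cohort(cfg)
  m <- co$manifest
  b <- m[m$material == "barium", ]
  w <- m[m$material == "water", ]
  expect_true(all(b$onset_sample == b$true_onset_sample))
  expect_true(all(b$offset_sample == b$true_offset_sample))
  expect_true(all(w$true_onset_sample > w$onset_sample))
  expect_true(all(w$true_offset_sample < w$offset_sample))
  ## padding model mean 1.5 s at both ends -> ~3 s extra relative to the
  ## true swallow recorded in the manifest
  pad <- with(w, (true_onset_sample - onset_sample) +
                   (offset_sample - true_offset_sample)) / w$fs
  expect_equal(mean(pad), 3.0, tolerance = 0.35)
})

test_that("water padding shifts mean segment duration by ~2 x padding mean", {
  cfg <- cohort_config(n_participants = 4,
                       swallows_per_material = c(barium = 40, water = 40),
                       duration_model = list(barium = c(mean = 1.0, sd = 0.1),
                                             water = c(mean = 1.0, sd = 0.1)),
                       water_padding_model = c(mean = 1.5, sd = 0.3),
                       seed = 21, baseline_duration_s = 1)
  co <- generate_cohort(cfg)
  d <- summarize_durations(co$manifest)
  expect_equal(d$mean_s[d$material == "water"] - d$mean_s[d$material == "barium"],
               3.0, tolerance = 0.35)
})

test_that("sensor noise: degenerate order matches white noise, AR(2) matches Yule-Walker", {
  m0 <- ar_noise_model(numeric(0), 2.5)
  x0 <- simulate_sensor_noise(m0, 5e4, seed = 3)
  expect_equal(var(x0), 2.5, tolerance = 0.1)

  a <- c(0.5, -0.25)
  x2 <- simulate_sensor_noise(ar_noise_model(a, 1), 2e5, seed = 4)
  emp <- stats::acf(x2, lag.max = 2, plot = FALSE)$acf[2:3]
  expect_equal(as.numeric(emp), ar2_acf(a[1], a[2]), tolerance = 0.02)

  expect_error(simulate_sensor_noise(m0, 0), "n must be")
  expect_error(ar_noise_model(c(1.2), 1), "unstable")
})

test_that("swallow bursts concentrate energy in time and band", {
  fs <- 20000
  bm <- list(n_bursts = 3L, band = c(100, 800), width_range_s = c(0.03, 0.08),
             amplitude = 0.1, amplitude_jitter_sd = 0.2,
             centers = NULL, widths = NULL)
  x <- simulate_swallow_burst(bm, 1.0, fs, seed = 8)
  expect_length(x, fs)
  psd <- welch_psd(x, fs, nperseg = 2048L)
  inband <- psd$freq >= 50 & psd$freq <= 1000
  expect_gt(sum(psd$power[inband]) / sum(psd$power), 0.90)

  bm$amplitude <- 0
  expect_identical(simulate_swallow_burst(bm, 1.0, fs, seed = 8), numeric(fs))

  bm$band <- c(100, 12000)
  expect_error(simulate_swallow_burst(bm, 1.0, fs), "fs/2")
  bm$band <- c(100, 800)
  expect_error(simulate_swallow_burst(bm, 0, fs), "duration")
})

test_that("two disjoint bursts produce a bimodal amplitude envelope", {
  fs <- 4000
  bm <- list(n_bursts = 2L, band = c(100, 800), width_range_s = c(0.03, 0.03),
             amplitude = 0.2, amplitude_jitter_sd = 0,
             centers = c(0.5, 1.5), widths = c(0.04, 0.04))
  x <- simulate_swallow_burst(bm, 2.0, fs, seed = 2)
  env <- stats::filter(abs(x), rep(1 / 201, 201), sides = 2)
  env[is.na(env)] <- 0
  thr <- max(env) * 0.5
  above <- env > thr
  runs <- rle(as.vector(above))
  expect_equal(sum(runs$values), 2L)
})

test_that("feature-level generator: null tables show no material difference", {
  cfg <- cohort_config(n_participants = 30,
                       swallows_per_material = c(barium = 300, water = 300),
                       seed = 77, effect_spec = NULL)
  ft <- generate_feature_table(cfg)
  for (fc in sample(feature_column_names(), 8)) {
    d <- abs(mean(ft[[fc]][ft$material == "water"]) -
               mean(ft[[fc]][ft$material == "barium"])) / sd(ft[[fc]])
    expect_lt(d, 0.1)
  }
})

test_that("feature-level generator recovers a planted standardized shift", {
  spec <- data.frame(feature = "lz_complexity", channel = "MIC", shift = 1.5)
  cfg <- cohort_config(n_participants = 50,
                       swallows_per_material = c(barium = 1000, water = 1000),
                       seed = 13, effect_spec = spec)
  ft <- generate_feature_table(cfg)
  gt <- attr(ft, "ground_truth")
  expect_equal(unname(gt$beta1["lz_complexity_MIC"]), 1.5)
  ## materials are balanced within participant, so the raw group difference
  ## estimates the planted shift directly
  y <- ft$lz_complexity_MIC
  dd <- mean(y[ft$material == "water"]) - mean(y[ft$material == "barium"])
  expect_equal(dd / gt$sigma, 1.5, tolerance = 0.15)
})

test_that("feature-level generator recovers the configured variance split", {
  cfg <- cohort_config(n_participants = 40,
                       swallows_per_material = c(barium = 400, water = 400),
                       seed = 19, effect_spec = NULL,
                       feature_model = list(sigma = 1, sigma_u = 0.5,
                                            n_factors = 8L, factor_share = 0.995))
  ft <- generate_feature_table(cfg)
  icc_target <- 0.25 / 1.25
  iccs <- vapply(feature_column_names(), function(fc) {
    fit <- stats::aov(ft[[fc]] ~ factor(ft$participant_id))
    ms <- summary(fit)[[1]]$`Mean Sq`
    nper <- nrow(ft) / 40
    vb <- max((ms[1] - ms[2]) / nper, 0)
    vb / (vb + ms[2])
  }, numeric(1))
  expect_lt(abs(mean(iccs) - icc_target), 0.06)
})

test_that("config validation rejects bad inputs", {
  expect_error(cohort_config(n_participants = 1), ">= 2")
  expect_error(cohort_config(min_duration = 0), "min_duration")
  expect_error(
    cohort_config(effect_spec = data.frame(feature = "nope", channel = "MIC",
                                           shift = 1)),
    "unknown feature")
  expect_error(
    cohort_config(effect_spec = data.frame(feature = c("std_dev", "std_dev"),
                                           channel = c("MIC", "MIC"),
                                           shift = c(1, 2))),
    "duplicated")
})
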