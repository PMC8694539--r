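## Signal-conditioning chain: anti-aliased downsampling to 4 kHz, AR-based
## FIR whitening of sensor noise, least-squares spline detrending of the
## accelerometer channels, and discrete Meyer wavelet denoising.

#' Preprocessing configuration
#'
#' @param fs_target Target sampling rate in Hz after downsampling.
#' @param ar_max_order Maximum order searched when fitting sensor-noise AR
#'   models.
#' @param spline_order Spline order for motion detrending (order 4 = cubic
#'   pieces).
#' @param spline_knot_spacing Uniform interior-knot spacing in seconds;
#'   0.5 s keeps sub-2 Hz head movement in the fitted trend while leaving
#'   swallow transients untouched.
#' @param wavelet_levels Decomposition depth of the Meyer denoiser.
#' @param wavelet_taps FIR length of the Meyer filter.
#' @param threshold_scale Multiplier on the universal threshold; 0 disables
#'   thresholding (identity reconstruction).
#' @return An object of class `hrca_preprocess_config`.
#' @export
preprocess_config <- function(fs_target = 4000,
                              ar_max_order = 10L,
                              spline_order = 4L,
                              spline_knot_spacing = 0.5,
                              wavelet_levels = 10L,
                              wavelet_taps = 102L,
                              threshold_scale = 1) {
  if (fs_target <= 0) stopf("fs_target must be > 0")
  if (spline_knot_spacing <= 0) stopf("spline_knot_spacing must be > 0")
  if (wavelet_levels < 1L) stopf("wavelet_levels must be >= 1")
  structure(
    list(fs_target = fs_target, ar_max_order = as.integer(ar_max_order),
         spline_order = as.integer(spline_order),
         spline_knot_spacing = spline_knot_spacing,
         wavelet_levels = as.integer(wavelet_levels),
         wavelet_taps = as.integer(wavelet_taps),
         threshold_scale = threshold_scale),
    class = "hrca_preprocess_config"
  )
}

#' Anti-aliased downsampling
#'
#' Polyphase FIR resampling from `fs_in` to `fs_target`. The output length is
#' `floor(n * fs_target / fs_in)` (the resampler's ragged tail sample, when
#' present, is dropped).
#'
#' @param x Numeric signal.
#' @param fs_in Input sampling rate (>= `fs_target`).
#' @param fs_target Output sampling rate (> 0).
#' @return Downsampled signal.
#' @export
downsample_signal <- function(x, fs_in, fs_target) {
  if (fs_target > fs_in) stopf("fs_target (%g) exceeds fs_in (%g)", fs_target, fs_in)
  if (fs_target <= 0) stopf("fs_target must be > 0")
  if (fs_target == fs_in) return(x)
  g <- gcd_int(round(fs_target), round(fs_in))
  p <- round(fs_target) / g
  q <- round(fs_in) / g
  n_out <- floor(length(x) * fs_target / fs_in)
  if (p > 1L) {
    ## rational rate: zero-stuff by p first, then treat as integer decimation
    u <- numeric(length(x) * p)
    u[seq.int(1L, length(u), by = p)] <- x * p
    x <- u
  }
  ## windowed-sinc anti-aliasing lowpass at 90% of the output Nyquist
  ntaps <- 20L * q + 1L
  h <- signal::fir1(ntaps - 1L, 0.9 / q, type = "low")
  delay <- (ntaps - 1L) %/% 2L
  v <- as.numeric(stats::filter(c(x, numeric(delay)), h,
                                method = "convolution", sides = 1L))
  v <- v[(delay + 1L):length(v)]
  y <- v[seq.int(1L, length(v), by = q)]
  length(y) <- n_out
  y[is.na(y)] <- 0
  y
}

gcd_int <- function(a, b) {
  while (b != 0) {
    r <- a %% b
    a <- b
    b <- r
  }
  a
}

#' Fit an AR model to a sensor baseline recording
#'
#' Yule-Walker fits for every order `0..max_order`; the returned order
#' minimizes BIC (`n log sigma2 + p log n`). The baseline must be at least
#' 50 times longer than `max_order`.
#'
#' @param baseline Numeric baseline (zero-input) recording.
#' @param max_order Largest candidate order.
#' @param channel Optional channel label stored in the model.
#' @return An [ar_noise_model()].
#' @export
fit_ar_noise_model <- function(baseline, max_order = 10L, channel = NA_character_) {
  n <- length(baseline)
  if (n < max(200L, 50L * max(1L, max_order))) {
    stopf("baseline too short (%d samples) for max_order %d", n, max_order)
  }
  v0 <- mean((baseline - mean(baseline))^2)
  if (v0 < .Machine$double.xmin) {
    ## degenerate (constant) baseline: order-0 model, zero variance
    return(ar_noise_model(numeric(0), 0, channel))
  }
  best <- NULL
  best_bic <- Inf
  for (p in 0:max_order) {
    if (p == 0L) {
      s2 <- mean((baseline - mean(baseline))^2)
      coefs <- numeric(0)
    } else {
      fit <- ar.yw(baseline, aic = FALSE, order.max = p, demean = TRUE)
      s2 <- fit$var.pred
      coefs <- as.numeric(fit$ar)
    }
    bic <- n * log(s2) + p * log(n)
    if (bic < best_bic) {
      best_bic <- bic
      best <- list(coefs = coefs, s2 = s2)
    }
  }
  ar_noise_model(best$coefs, best$s2, channel)
}

#' Whiten a signal with an AR prediction-error filter
#'
#' Applies the FIR inverse filter `[1, -a_1, ..., -a_p]` of the baseline AR
#' model (samples before the signal start are taken as zero), so that pure
#' model noise becomes white.
#'
#' @param x Numeric signal.
#' @param model An [ar_noise_model()].
#' @return Filtered signal, same length as `x`.
#' @export
whiten <- function(x, model) {
  stopifnot(inherits(model, "ar_noise_model"))
  if (model$order == 0L) return(x)
  y <- x
  n <- length(x)
  for (k in seq_len(model$order)) {
    if (k >= n) break
    idx <- (k + 1L):n
    y[idx] <- y[idx] - model$coefficients[k] * x[idx - k]
  }
  y
}

#' Remove low-frequency motion by least-squares spline detrending
#'
#' Fits a least-squares spline of the given order with uniform interior
#' knots to the signal and returns the residual. With order 4 (cubic
#' pieces) the fit reproduces polynomials up to degree 3 exactly, so
#' polynomial drift is annihilated to machine precision.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param order Spline order (polynomial degree + 1).
#' @param knot_spacing Interior-knot spacing in seconds.
#' @return Detrended signal (residual from the spline fit).
#' @export
remove_motion_spline <- function(x, fs, order = 4L, knot_spacing = 0.5) {
  n <- length(x)
  duration <- n / fs
  if (duration < 2 * knot_spacing) {
    stopf("signal (%.3f s) must span at least two knot intervals (%.3f s each)",
          duration, knot_spacing)
  }
  tt <- (seq_len(n) - 1) / fs
  degree <- order - 1L
  interior <- seq(knot_spacing, duration - knot_spacing / 2, by = knot_spacing)
  interior <- interior[interior < max(tt)]
  basis <- splines::bs(tt, knots = interior, degree = degree, intercept = TRUE)
  fit <- stats::lm.fit(basis, x)
  as.numeric(fit$residuals)
}

## Soft threshold: shrink magnitudes toward zero.
soft_threshold <- function(w, thr) {
  sign(w) * pmax(abs(w) - thr, 0)
}

#' Wavelet denoising with the discrete Meyer wavelet
#'
#' Multilevel periodized discrete Meyer decomposition (zero-padded up to a
#' dyadic-compatible length, levels reduced when the signal is short),
#' soft thresholding of all detail levels with the universal threshold
#' `sigma_hat * sqrt(2 log N)` where `sigma_hat` is the median absolute
#' deviation of the finest detail level, and reconstruction. Soft
#' thresholding contracts coefficients, so output energy never exceeds
#' input energy.
#'
#' @param x Numeric signal (finite values only).
#' @param config An [preprocess_config()]; `threshold_scale = 0` gives the
#'   identity reconstruction.
#' @return Denoised signal, same length as `x`.
#' @export
wavelet_denoise <- function(x, config = preprocess_config()) {
  if (!all(is.finite(x))) stopf("signal contains non-finite samples")
  n <- length(x)
  if (n < 2L) return(x)
  if (all(x == 0)) return(x)
  dec <- dwt_padded(x, config$wavelet_levels, config$wavelet_taps)
  if (config$threshold_scale > 0) {
    sigma_hat <- mad(dec$details[[1L]], center = 0)
    thr <- config$threshold_scale * sigma_hat * sqrt(2 * log(length(x)))
    dec$details <- lapply(dec$details, soft_threshold, thr = thr)
  }
  y <- hrca_idwt(dec)
  y[seq_len(n)]
}

#' Run the full conditioning chain on one segment
#'
#' Per channel: downsample to the target rate, whiten with the channel's AR
#' model, spline-detrend (accelerometer channels AP/SI/ML only), and
#' wavelet-denoise (all four channels). Sample indices in the segment
#' metadata are rescaled to the new rate. If `ar_models` is `NULL` the AR
#' models are fitted to the segment's own channels (flagged as `self_fit` in
#' the attached provenance); the intended route fits them on a baseline
#' recording at the target rate (see [fit_baseline_models()]).
#'
#' @param segment An `hrca_segment`.
#' @param config An [preprocess_config()].
#' @param ar_models Optional named list (MIC/AP/SI/ML) of [ar_noise_model()]s
#'   fitted at `fs_target`.
#' @return The processed segment; provenance is stored in its `processing`
#'   field.
#' @export
preprocess_segment <- function(segment, config = preprocess_config(),
                               ar_models = NULL) {
  stopifnot(inherits(segment, "hrca_segment"))
  fs_in <- segment$fs
  r <- config$fs_target / fs_in
  self_fit <- is.null(ar_models)
  out <- segment
  ar_orders <- integer(0)
  for (ch in names(segment$channels)) {
    x <- downsample_signal(segment$channels[[ch]], fs_in, config$fs_target)
    model <- if (self_fit) {
      fit_ar_noise_model(x, min(config$ar_max_order,
                                max(0L, length(x) %/% 50L)), ch)
    } else {
      ar_models[[ch]]
    }
    ar_orders[ch] <- model$order
    x <- whiten(x, model)
    if (ch != "MIC" && length(x) / config$fs_target >= 2 * config$spline_knot_spacing) {
      x <- remove_motion_spline(x, config$fs_target, config$spline_order,
                                config$spline_knot_spacing)
    }
    x <- wavelet_denoise(x, config)
    out$channels[[ch]] <- x
  }
  out$fs <- config$fs_target
  out$onset_sample <- as.integer(floor(segment$onset_sample * r))
  out$offset_sample <- length(out$channels[[1L]])
  out$true_onset_sample <- as.integer(floor(segment$true_onset_sample * r))
  out$true_offset_sample <- as.integer(min(ceiling(segment$true_offset_sample * r),
                                           out$offset_sample))
  out$processing <- list(
    fs_in = fs_in, fs_target = config$fs_target,
    steps = c("downsample", "whiten",
              "spline_detrend (AP/SI/ML)", "wavelet_denoise"),
    ar_source = if (self_fit) "self_fit" else "baseline",
    ar_orders = ar_orders,
    wavelet_levels = config$wavelet_levels,
    threshold_scale = config$threshold_scale
  )
  out
}

#' Fit per-channel AR models from a baseline recording
#'
#' Downsamples each channel of a participant's sensor-baseline (zero-input)
#' recording to the target rate and fits the whitening AR model by
#' BIC-selected Yule-Walker.
#'
#' @param baseline List with `channels` (named list of signals) and `fs`.
#' @param config An [preprocess_config()].
#' @return Named list of [ar_noise_model()]s.
#' @export
fit_baseline_models <- function(baseline, config = preprocess_config()) {
  models <- lapply(names(baseline$channels), function(ch) {
    x <- downsample_signal(baseline$channels[[ch]], baseline$fs, config$fs_target)
    fit_ar_noise_model(x, config$ar_max_order, ch)
  })
  names(models) <- names(baseline$channels)
  models
}
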