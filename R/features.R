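## Feature extraction: nine features per channel across four domains.
##
## Time: standard deviation, skewness, kurtosis (non-excess; Gaussian -> 3).
## Frequency: peak frequency, spectral centroid, bandwidth, all from a Welch
## power spectral density. Time-frequency: wavelet entropy of the discrete
## Meyer subband energy distribution. Information-theoretic: normalized
## Lempel-Ziv (LZ76) complexity of the median-binarized signal, and a
## normalized regularity index derived from the corrected conditional
## entropy of the 10-level amplitude-quantized signal.

#' Time-domain features
#'
#' Sample standard deviation (n-1 denominator) plus standardized third and
#' fourth central moments. Kurtosis follows the non-excess convention (a
#' Gaussian sample gives ~3). For a constant signal the SD is 0 and skewness
#' and kurtosis are undefined, returned as `NaN`.
#'
#' @param x Numeric signal of length >= 3.
#' @return Named vector `c(std_dev, skewness, kurtosis)`.
#' @export
time_features <- function(x) {
  if (length(x) < 3L) stopf("need at least 3 samples")
  m <- mean(x)
  d <- x - m
  m2 <- mean(d^2)
  if (m2 < .Machine$double.xmin) {
    return(c(std_dev = 0, skewness = NaN, kurtosis = NaN))
  }
  c(std_dev = sd(x),
    skewness = mean(d^3) / m2^1.5,
    kurtosis = mean(d^4) / m2^2)
}

#' Welch power spectral density
#'
#' Mean of modified periodograms over Hann-windowed segments with 50%
#' overlap; each segment is mean-detrended before windowing. When the signal
#' is shorter than `nperseg` a single full-length segment is used.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param nperseg Segment length (default 256, ~15.6 Hz resolution at 4 kHz).
#' @param overlap Fractional overlap between segments.
#' @return List with `freq` (Hz, one-sided) and `power`.
#' @export
welch_psd <- function(x, fs, nperseg = 256L, overlap = 0.5) {
  n <- length(x)
  nper <- min(nperseg, n)
  step <- max(1L, floor(nper * (1 - overlap)))
  starts <- seq.int(1L, n - nper + 1L, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seqceil(nper))
  u <- sum(win^2)
  nf <- nper %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nper - 1L)]
    seg <- (seg - mean(seg)) * win
    p <- Mod(fft(seg))^2
    acc <- acc + p[seq_len(nf)]
  }
  power <- acc / (length(starts) * u * fs)
  ## one-sided scaling: double everything except DC (and Nyquist when even)
  dbl <- rep(2, nf)
  dbl[1L] <- 1
  if (nper %% 2L == 0L) dbl[nf] <- 1
  list(freq = (seq_len(nf) - 1L) * fs / nper, power = power * dbl)
}

seqceil <- function(n) (seq_len(n) - 1L) / n

#' Frequency-domain features
#'
#' From the Welch PSD `P(f)`: `peak_frequency = argmax P`,
#' `spectral_centroid = sum(f P) / sum(P)`, and `bandwidth`, the PSD-weighted
#' standard deviation of frequency around the centroid.
#'
#' @param x Numeric signal of length >= 64.
#' @param fs Sampling rate in Hz.
#' @param nperseg Welch segment length.
#' @return Named vector `c(peak_frequency, spectral_centroid, bandwidth)`.
#' @export
spectral_features <- function(x, fs, nperseg = 256L) {
  if (length(x) < 64L) stopf("need at least 64 samples")
  if (all(x == 0)) stopf("spectrum undefined for an all-zero signal")
  psd <- welch_psd(x, fs, nperseg)
  P <- psd$power
  f <- psd$freq
  tot <- sum(P)
  centroid <- sum(f * P) / tot
  c(peak_frequency = f[which.max(P)],
    spectral_centroid = centroid,
    bandwidth = sqrt(sum((f - centroid)^2 * P) / tot))
}

#' Wavelet entropy
#'
#' Shannon entropy (nats) of the relative energy distribution over the
#' discrete Meyer subbands (all detail levels plus the final approximation).
#' Near zero when the energy concentrates in one subband; invariant under
#' amplitude scaling.
#'
#' @param x Numeric signal with non-zero energy.
#' @param levels Decomposition depth (reduced automatically for short
#'   signals).
#' @return Wavelet entropy in nats.
#' @export
wavelet_entropy <- function(x, levels = 10L) {
  if (sum(x^2) < .Machine$double.xmin) stopf("zero-energy signal")
  dec <- dwt_padded(x, levels)
  e <- c(vapply(dec$details, function(d) sum(d^2), numeric(1)),
         sum(dec$approximation^2))
  p <- e / sum(e)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' LZ76 phrase count of a binary sequence
#'
#' Exhaustive-history Lempel-Ziv (1976) parsing: the sequence is scanned
#' left to right and a new phrase is opened each time the upcoming symbol
#' extends beyond the longest substring reproducible from the extended
#' history.
#'
#' @param bits Integer/logical vector of 0s and 1s (length >= 1).
#' @return The parsing count `c(n)`.
#' @export
lz76_count <- function(bits) {
  s <- as.integer(bits)
  if (length(s) == 0L) stopf("empty sequence")
  .lz76_count_cpp(s)
}

#' Normalized Lempel-Ziv complexity
#'
#' Binarizes the signal at its median (ties, `x >= median`, map to 1), runs
#' the LZ76 exhaustive-history parser, and normalizes:
#' `C = c(n) * log2(n) / n`, which approaches 1 for an i.i.d. random binary
#' sequence.
#'
#' @param x Numeric signal of length >= 2, or an already-binary 0/1 vector
#'   with `binarize = FALSE`.
#' @param binarize Binarize at the median first (default `TRUE`).
#' @return Normalized complexity (dimensionless, >= 0).
#' @export
lz_complexity <- function(x, binarize = TRUE) {
  n <- length(x)
  if (n < 2L) stopf("need at least 2 samples")
  bits <- if (binarize) as.integer(x >= median(x)) else as.integer(x)
  lz76_count(bits) * log2(n) / n
}

## Shannon entropy (nats) of words of length L in a symbol sequence,
## together with the fraction of words observed exactly once.
word_entropy <- function(symbols, L) {
  n <- length(symbols) - L + 1L
  if (n < 1L) stopf("sequence shorter than word length")
  if (L == 1L) {
    codes <- as.numeric(symbols)
  } else {
    mat <- stats::embed(symbols, L)
    codes <- as.vector(mat %*% 10^(seq_len(L) - 1))
  }
  cs <- sort(codes)
  bounds <- c(0L, which(cs[-1L] != cs[-n]), n)
  counts <- diff(bounds)
  pr <- counts / n
  list(entropy = -sum(pr * log(pr)),
       frac_single = sum(counts == 1L) / n)
}

#' Normalized regularity index from corrected conditional entropy
#'
#' The de-meaned signal is quantized into 10 uniform amplitude bins over its
#' range. For word lengths `L = 1..L_max` the corrected conditional entropy
#' is `CCE(L) = E(L) - E(L-1) + perc(L) * E(1)` (with `E(0) = 0`), where
#' `perc(L)` is the fraction of length-`L` words observed exactly once --
#' the correction that prevents the conditional entropy from artificially
#' vanishing once words become unique. The index is
#' `rho = 1 - min_L CCE(L) / E(1)`, clamped to `[0, 1]`: higher values mean
#' a more regular, predictable signal. A constant signal returns 1 by
#' convention (quantization is degenerate, the signal is maximally regular).
#'
#' @param x Numeric signal; at least 1000 samples are required for a stable
#'   estimate with 10 quantization levels.
#' @param n_bins Number of uniform amplitude bins.
#' @param L_max Longest conditioning word length.
#' @return Regularity index in `[0, 1]`.
#' @export
entropy_rate <- function(x, n_bins = 10L, L_max = 10L) {
  n <- length(x)
  if (n < 1000L) stopf("need at least 1000 samples (documented minimum)")
  x <- x - mean(x)
  rng <- range(x)
  if (diff(rng) < .Machine$double.xmin) return(1)
  ## bin index 0..n_bins-1; the top edge is closed
  symbols <- pmin(floor((x - rng[1]) / diff(rng) * n_bins), n_bins - 1L)
  e1 <- word_entropy(symbols, 1L)$entropy
  if (e1 < .Machine$double.xmin) return(1)
  prev <- 0
  min_ncce <- Inf
  for (L in seq_len(L_max)) {
    we <- word_entropy(symbols, L)
    cce <- we$entropy - prev + we$frac_single * e1
    min_ncce <- min(min_ncce, cce / e1)
    prev <- we$entropy
  }
  min(max(1 - min_ncce, 0), 1)
}

## Compute the nine features for one channel; degenerate channels yield NA
## for the undefined features rather than an error.
channel_features <- function(x, fs) {
  tf <- time_features(x)
  sf <- tryCatch(spectral_features(x, fs),
                 error = function(e) c(peak_frequency = NA_real_,
                                       spectral_centroid = NA_real_,
                                       bandwidth = NA_real_))
  we <- tryCatch(wavelet_entropy(x), error = function(e) NA_real_)
  lz <- tryCatch(lz_complexity(x), error = function(e) NA_real_)
  er <- tryCatch(entropy_rate(x), error = function(e) NA_real_)
  out <- c(tf, sf, wavelet_entropy = we, lz_complexity = lz, entropy_rate = er)
  out[is.nan(out)] <- NA_real_
  out[HRCA_FEATURES]
}

#' Extract the 36-feature representation of one swallow segment
#'
#' Computes the nine per-channel features on each of the four channels of a
#' (preprocessed) segment. Features that are undefined on a degenerate
#' channel (e.g. spectral features of an all-zero channel, skewness of a
#' constant channel) are recorded as `NA`.
#'
#' @param segment An `hrca_segment`.
#' @return Named numeric vector of length 36 (`<feature>_<channel>`).
#' @export
extract_features <- function(segment) {
  stopifnot(inherits(segment, "hrca_segment"))
  out <- unlist(lapply(HRCA_CHANNELS, function(ch) {
    v <- channel_features(segment$channels[[ch]], segment$fs)
    names(v) <- paste(names(v), ch, sep = "_")
    v
  }))
  out[feature_column_names()]
}

#' Build a cohort feature table from segments
#'
#' @param segments List of (preprocessed) `hrca_segment`s.
#' @return Data frame with key columns and the 36 feature columns.
#' @export
extract_feature_table <- function(segments) {
  rows <- lapply(segments, function(seg) {
    cbind(data.frame(participant_id = seg$participant_id,
                     swallow_index = seg$swallow_index,
                     material = seg$material,
                     stringsAsFactors = FALSE),
          as.data.frame(t(extract_features(seg))))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
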