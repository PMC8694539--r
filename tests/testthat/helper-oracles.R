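# Independent oracles and fixture builders used across the suite.

# Definition-based LZ76 oracle: scan left to right; a phrase grows while its
# content occurs as a substring of the extended history (everything before
# the phrase's last symbol); the phrase closes on the first symbol that
# breaks reproducibility. A trailing reproducible run still counts as one
# phrase.
lz76_oracle <- function(bits) {
  s <- paste(as.integer(bits), collapse = "")
  n <- nchar(s)
  count <- 0L
  p <- 1L
  while (p <= n) {
    k <- 0L
    while (p + k <= n) {
      candidate <- substr(s, p, p + k)
      history <- substr(s, 1L, p + k - 1L)
      if (grepl(candidate, history, fixed = TRUE)) k <- k + 1L else break
    }
    count <- count + 1L
    p <- p + k + 1L
  }
  count
}

# Naive dictionary-counting word entropy: paste explicit word strings and
# tabulate them.
word_entropy_oracle <- function(symbols, L) {
  n <- length(symbols) - L + 1L
  words <- vapply(seq_len(n), function(i) {
    paste(symbols[i:(i + L - 1L)], collapse = ",")
  }, character(1))
  counts <- table(words)
  pr <- as.numeric(counts) / n
  list(entropy = -sum(pr * log(pr)),
       frac_single = sum(counts == 1L) / n)
}

# Theoretical AR(2) autocorrelations from the Yule-Walker equations.
ar2_acf <- function(a1, a2) {
  rho1 <- a1 / (1 - a2)
  rho2 <- a1 * rho1 + a2
  c(rho1, rho2)
}

# Small 4-channel segment built directly at the analysis rate: sensor noise
# everywhere plus a band-limited burst in the middle of each channel.
make_test_segment <- function(seed = 1, fs = 4000, duration_s = 1.5,
                              participant = "P01", material = "barium") {
  withr::with_seed(seed, {
    n <- round(duration_s * fs)
    bm <- list(n_bursts = 2L, band = c(100, 800),
               width_range_s = c(0.03, 0.08), amplitude = 0.1,
               amplitude_jitter_sd = 0.2, centers = NULL, widths = NULL)
    channels <- lapply(setNames(nm = c("MIC", "AP", "SI", "ML")), function(ch) {
      0.01 * rnorm(n) + simulate_swallow_burst(bm, duration_s, fs)
    })
    seg <- list(participant_id = participant, material = material,
                swallow_index = 1L, channels = channels, fs = fs,
                onset_sample = 0L, offset_sample = n,
                true_onset_sample = 0L, true_offset_sample = n)
    class(seg) <- "hrca_segment"
    seg
  })
}

# Feature table with i.i.d. rows used where the generator itself is under
# test elsewhere: balanced participants, optional mean shift on chosen
# columns.
make_iid_table <- function(n_participants, per_material, shift_cols = NULL,
                           shift = 0, seed = 1) {
  withr::with_seed(seed, {
    cols <- feature_column_names()
    key <- expand.grid(swallow_index = seq_len(per_material),
                       material = c("barium", "water"),
                       participant_id = sprintf("P%02d", seq_len(n_participants)),
                       stringsAsFactors = FALSE)
    n <- nrow(key)
    Y <- matrix(rnorm(n * length(cols)), n, length(cols),
                dimnames = list(NULL, cols))
    if (!is.null(shift_cols)) {
      Y[key$material == "water", shift_cols] <-
        Y[key$material == "water", shift_cols] + shift
    }
    cbind(key[c("participant_id", "swallow_index", "material")],
          as.data.frame(Y))
  })
}
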