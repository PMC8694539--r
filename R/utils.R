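## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `expr` under a local RNG seed, restoring the caller's RNG state.
## seed = NULL means "use the RNG stream as-is" (no restoration either).
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

## Deterministic per-stage seed derivation from one global seed.
## Keeps results independent across stage indexes while staying inside the
## 32-bit signed range accepted by set.seed().
derive_seed <- function(seed, stage) {
  (as.double(seed) * 48271 + 7919 * stage) %% 2147483647
}

## Normal samples truncated below at `lower` (rejection sampling).
rnorm_trunc <- function(n, mean, sd, lower) {
  out <- rnorm(n, mean, sd)
  bad <- which(out < lower)
  guard <- 0L
  while (length(bad) > 0L) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower]
    guard <- guard + 1L
    if (guard > 1000L) {
      out[bad] <- lower
      break
    }
  }
  out
}

## Spread `total` items over `n` units as evenly as possible; the first
## `total %% n` units receive one extra.
allocate_counts <- function(total, n) {
  base <- total %/% n
  extra <- total %% n
  counts <- rep.int(base, n)
  if (extra > 0L) counts[seq_len(extra)] <- base + 1L
  counts
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

## Single ARMA filtering pass (direct form) on stats::filter's C paths;
## start-up state is zero.
iir_pass <- function(b, a, x) {
  nb <- length(b)
  v <- stats::filter(c(rep.int(0, nb - 1L), x), b,
                     method = "convolution", sides = 1L)
  v <- as.numeric(v[nb:(nb - 1L + length(x))])
  if (length(a) > 1L) {
    v <- as.numeric(stats::filter(v, -a[-1L] / a[1L], method = "recursive"))
    if (a[1L] != 1) v <- v / a[1L]
  }
  v
}

## Zero-phase (forward-backward) IIR filtering with odd-reflection edge
## padding; `filt` is a signal::butter-style list with b and a.
zero_phase_filter <- function(filt, x) {
  n <- length(x)
  if (n < 2L) return(x)
  b <- filt$b
  a <- filt$a
  np <- min(3L * (max(length(b), length(a)) - 1L), n - 1L)
  xp <- if (np > 0L) {
    c(2 * x[1L] - x[(np + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - np)])
  } else {
    x
  }
  y <- iir_pass(b, a, xp)
  y <- rev(iir_pass(b, a, rev(y)))
  y[(np + 1L):(np + n)]
}
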