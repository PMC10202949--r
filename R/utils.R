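# Internal numeric helpers shared across modules.

.check_scalar <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (strict && x <= lower)
    stop(sprintf("`%s` must be > %g", name, lower), call. = FALSE)
  if (!strict && x < lower)
    stop(sprintf("`%s` must be >= %g", name, lower), call. = FALSE)
  invisible(x)
}

# (1 - exp(-r*s)) / r, with the r -> 0 limit s.
.expm1_ratio <- function(r, s) {
  ifelse(abs(r * s) < 1e-12, s, -expm1(-r * s) / r)
}

# (exp(-r1*s) - exp(-r2*s)) / (r2 - r1), with the r2 -> r1 limit s*exp(-r1*s).
.exp_diff <- function(r1, r2, s) {
  d <- r2 - r1
  ifelse(abs(d * s) < 1e-9, s * exp(-r1 * s),
         (exp(-r1 * s) - exp(-r2 * s)) / d)
}

.shift_idx <- function(n) {
  if (n %% 2L != 0L) stop("fftshift requires an even length", call. = FALSE)
  c((n / 2L + 1L):n, 1L:(n / 2L))
}

.fftshift1 <- function(x) x[.shift_idx(length(x))]

# Circular shift of the first two dimensions so the DC component sits at
# index n/2 + 1 (even sizes only; the shift is then its own inverse).
.fftshift2 <- function(x) {
  d <- dim(x)
  i <- .shift_idx(d[1L])
  j <- .shift_idx(d[2L])
  switch(as.character(length(d)),
    "2" = x[i, j, drop = FALSE],
    "3" = x[i, j, , drop = FALSE],
    "4" = x[i, j, , , drop = FALSE],
    stop("arrays with more than four dimensions are not supported",
         call. = FALSE))
}

.fft_along1 <- function(arr, inverse = FALSE) {
  d <- dim(arr)
  m <- matrix(arr, nrow = d[1L])
  array(stats::mvfft(m, inverse = inverse), dim = d)
}

# Unnormalized 2D DFT over dims 1 and 2, batched over any trailing dims.
.fft2 <- function(arr, inverse = FALSE) {
  d <- dim(arr)
  if (is.null(d) || length(d) < 2L)
    stop("expected an array with at least two dimensions", call. = FALSE)
  arr <- .fft_along1(arr, inverse)
  perm <- seq_along(d)
  perm[1:2] <- c(2L, 1L)
  arr <- aperm(arr, perm)
  arr <- .fft_along1(arr, inverse)
  aperm(arr, perm)
}

# Derive a child RNG seed from a base seed, kept inside 32-bit integer range.
.derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(offset)) %% 2147483629)
}
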