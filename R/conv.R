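# FFT-based 2-D convolution used for focal (moving-window) statistics and for
# smoothing white noise into spatially autocorrelated random fields.

# smallest 5-smooth integer >= n (fast FFT length)
next_fast_len <- function(n) {
  n <- as.integer(n)
  repeat {
    m <- n
    for (p in c(2L, 3L, 5L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(n)
    n <- n + 1L
  }
}

# 2-D linear convolution, "same" output size, zero-padded borders.
# k must have odd dimensions. Not exported; callers handle NA themselves.
conv2_same <- function(x, k) {
  nr <- nrow(x); nc <- ncol(x)
  kr <- nrow(k); kc <- ncol(k)
  stopifnot(kr %% 2 == 1, kc %% 2 == 1)
  pr <- next_fast_len(nr + kr - 1L)
  pc <- next_fast_len(nc + kc - 1L)
  X <- matrix(0, pr, pc); X[seq_len(nr), seq_len(nc)] <- x
  K <- matrix(0, pr, pc); K[seq_len(kr), seq_len(kc)] <- k
  Y <- Re(stats::fft(stats::fft(X) * stats::fft(K), inverse = TRUE)) / (pr * pc)
  ro <- (kr - 1L) %/% 2L
  co <- (kc - 1L) %/% 2L
  Y[ro + seq_len(nr), co + seq_len(nc)]
}

# 0/1 disc kernel: cell centers within radius_m (inclusive) of the focal center
disc_kernel <- function(radius_m, cellsize) {
  rc <- floor(radius_m / cellsize)
  d <- (-rc):rc
  k <- outer(d, d, function(i, j) {
    (i * cellsize)^2 + (j * cellsize)^2 <= radius_m^2 + 1e-9
  })
  storage.mode(k) <- "double"
  k
}

gauss_kernel <- function(sigma_m, cellsize) {
  rc <- max(1L, ceiling(3 * sigma_m / cellsize))
  d <- (-rc):rc
  k <- outer(d, d, function(i, j) {
    exp(-((i * cellsize)^2 + (j * cellsize)^2) / (2 * sigma_m^2))
  })
  k / sum(k)
}

# Smoothed standardized Gaussian random field (mean 0, sd 1 empirically).
# smooth_m = 0 gives plain white noise. Consumes the current RNG stream.
smooth_field <- function(nr, nc, cellsize, smooth_m) {
  f <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (smooth_m > 0) f <- conv2_same(f, gauss_kernel(smooth_m, cellsize))
  (f - mean(f)) / stats::sd(f)
}

# Focal counts of several 0/1 masks under a shared kernel. Convolutions of
# indicator matrices are integer counts; rounding removes FFT noise exactly.
focal_counts <- function(mask_list, kernel) {
  lapply(mask_list, function(m) {
    storage.mode(m) <- "double"
    round(conv2_same(m, kernel))
  })
}
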