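# Shared fixtures and independent brute-force oracles used across tests.

rand_image <- function(n, m = n, seed = 1, lo = 0, hi = 255) {
  set.seed(seed)
  matrix(runif(n * m, lo, hi), n, m)
}

# Brute-force 2D convolution with separable kernel and symmetric
# (half-sample mirror) border extension; direct quadruple loop.
conv2_oracle <- function(x, k1d) {
  r <- (length(k1d) - 1L) %/% 2L
  K <- outer(k1d, k1d)
  M <- nrow(x); N <- ncol(x)
  reflect <- function(i, n) {
    m <- (i - 1L) %% (2L * n)
    if (m < n) m + 1L else 2L * n - m
  }
  out <- matrix(0, M, N)
  for (i in seq_len(M)) {
    for (j in seq_len(N)) {
      acc <- 0
      for (a in -r:r) {
        for (b in -r:r) {
          acc <- acc + K[a + r + 1L, b + r + 1L] *
            x[reflect(i + a, M), reflect(j + b, N)]
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

# Literal transcription of the multiplicative update pair (guarded).
lee_seung_oracle <- function(V, W, H, eps = 1e-9) {
  H2 <- H * crossprod(W, V) / (crossprod(W) %*% H + eps)
  W2 <- W * tcrossprod(V, H2) / (W %*% tcrossprod(H2) + eps)
  list(W = W2, H = H2)
}

# Double-loop neighborhood energy with symmetric padding.
energy_oracle <- function(band, row, col, window) {
  r <- (window - 1L) %/% 2L
  M <- nrow(band); N <- ncol(band)
  reflect <- function(i, n) {
    m <- (i - 1L) %% (2L * n)
    if (m < n) m + 1L else 2L * n - m
  }
  acc <- 0
  for (a in -r:r) for (b in -r:r) {
    acc <- acc + band[reflect(row + a, M), reflect(col + b, N)]^2
  }
  acc
}

# Double-loop NHM at one position.
nhm_oracle <- function(A, B, row, col, window) {
  r <- (window - 1L) %/% 2L
  M <- nrow(A); N <- ncol(A)
  reflect <- function(i, n) {
    m <- (i - 1L) %% (2L * n)
    if (m < n) m + 1L else 2L * n - m
  }
  s <- 0
  for (a in -r:r) for (b in -r:r) {
    i <- reflect(row + a, M); j <- reflect(col + b, N)
    s <- s + abs(A[i, j]) * abs(B[i, j])
  }
  ea <- energy_oracle(A, row, col, window)
  eb <- energy_oracle(B, row, col, window)
  if (ea + eb == 0) 1 else 2 * s / (ea + eb)
}

psnr_to <- function(F, X) {
  mse <- mean((F - X)^2)
  if (mse == 0) 100 else 10 * log10(255^2 / mse)
}
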