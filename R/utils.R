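# Internal helpers shared across modules.

# Validate a grayscale image matrix: finite numeric matrix.
assert_image <- function(x, arg = deparse(substitute(x)), min_dim = 1L) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  }
  if (!all(is.finite(x))) {
    stop(sprintf("`%s` contains non-finite values", arg), call. = FALSE)
  }
  if (nrow(x) < min_dim || ncol(x) < min_dim) {
    stop(sprintf("`%s` must be at least %d x %d", arg, min_dim, min_dim),
         call. = FALSE)
  }
  invisible(x)
}

assert_same_shape <- function(a, b, what = "images") {
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("%s must have identical dimensions (registration): %s vs %s",
                 what, paste(dim(a), collapse = "x"),
                 paste(dim(b), collapse = "x")),
         call. = FALSE)
  }
  invisible(NULL)
}

# Border-extension index map: positions (1-r)..(n+r) -> 1..n.
# mode "symmetric": half-sample mirror (... 2 1 | 1 2 ... n | n n-1 ...);
# mode "periodic": wraparound.
pad_index <- function(n, r, mode = c("symmetric", "periodic")) {
  mode <- match.arg(mode)
  p <- seq.int(1L - r, n + r)
  if (mode == "periodic") {
    return(((p - 1L) %% n) + 1L)
  }
  m <- (p - 1L) %% (2L * n)
  ifelse(m < n, m + 1L, 2L * n - m)
}

# Separable 2D convolution with a (possibly sparse, odd-length) 1D tap vector
# applied along both axes. Zero taps are skipped (a trous kernels are mostly
# zeros). Output has the input's shape.
conv_separable <- function(x, taps, mode = "symmetric") {
  r <- (length(taps) - 1L) %/% 2L
  nz <- which(taps != 0)
  # vertical pass
  if (r > 0L) {
    idx <- pad_index(nrow(x), r, mode)
    xp <- x[idx, , drop = FALSE]
    out <- matrix(0, nrow(x), ncol(x))
    for (t in nz) {
      out <- out + taps[t] * xp[t:(t + nrow(x) - 1L), , drop = FALSE]
    }
    x <- out
    # horizontal pass
    idx <- pad_index(ncol(x), r, mode)
    xp <- x[, idx, drop = FALSE]
    out <- matrix(0, nrow(x), ncol(x))
    for (t in nz) {
      out <- out + taps[t] * xp[, t:(t + ncol(x) - 1L), drop = FALSE]
    }
    x <- out
  }
  x
}

# Box sum over an odd square window with symmetric border padding.
box_sum <- function(x, window) {
  stopifnot(window %% 2L == 1L, window >= 1L)
  r <- (window - 1L) %/% 2L
  if (r == 0L) return(x)
  idx <- pad_index(nrow(x), r, "symmetric")
  xp <- x[idx, , drop = FALSE]
  out <- matrix(0, nrow(x), ncol(x))
  for (t in seq_len(window)) {
    out <- out + xp[t:(t + nrow(x) - 1L), , drop = FALSE]
  }
  xp <- out[, pad_index(ncol(x), r, "symmetric"), drop = FALSE]
  out <- matrix(0, nrow(x), ncol(x))
  for (t in seq_len(window)) {
    out <- out + xp[, t:(t + ncol(x) - 1L), drop = FALSE]
  }
  out
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Gaussian blur, separable kernel truncated at 4 sigma.
gaussian_blur <- function(x, sigma, mode = "symmetric") {
  stopifnot(sigma > 0)
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-0.5 * ((-r):r / sigma)^2)
  conv_separable(x, k / sum(k), mode = mode)
}
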