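# Non-subsampled contourlet transform: an undecimated (a trous) pyramid for
# the multi-scale split and frequency-domain directional fan windows for the
# multi-direction split. Every band keeps the source image's size and the
# inverse is an exact sum, so the transform is shift-invariant and perfectly
# reconstructing by construction.

#' Pyramid specification for the non-subsampled multi-scale decomposition
#'
#' The pyramid is the additive a trous scheme: at scale `j` the running
#' approximation is smoothed with the base kernel upsampled by zero insertion
#' (sampling matrix `2 * I`), and the band-pass image is the difference of
#' successive approximations. Reconstruction is therefore a telescoping sum.
#'
#' @param scales Number of pyramid scales `J >= 1`.
#' @param kernel Odd-length 1D section of the separable low-pass kernel.
#'   Must sum to 1 (DC preservation). Default is the B3-spline
#'   `c(1, 4, 6, 4, 1) / 16`.
#' @return An object of class `pyramid_spec`.
#' @export
pyramid_spec <- function(scales = 3L, kernel = c(1, 4, 6, 4, 1) / 16) {
  scales <- as.integer(scales)
  if (is.na(scales) || scales < 1L) stop("`scales` must be >= 1", call. = FALSE)
  if (length(kernel) %% 2L != 1L) stop("`kernel` must have odd length", call. = FALSE)
  if (abs(sum(kernel) - 1) > 1e-12) stop("`kernel` taps must sum to 1", call. = FALSE)
  structure(list(scales = scales, kernel = kernel), class = "pyramid_spec")
}

#' Directional specification for the non-subsampled directional filter bank
#'
#' Scale `j` of the pyramid is split into `2^levels[j]` directional bands by
#' multiplying its 2D spectrum with smooth wedge windows over undirected
#' orientation. The windows use raised-cosine (`cos^2`/`sin^2`) cross-fades
#' and form a partition of unity, so the directional bands sum back to the
#' band they came from.
#'
#' @param levels Integer vector of direction levels, one per pyramid scale;
#'   level `l` yields `2^l` bands (`l = 0` leaves the scale unsplit).
#' @return An object of class `directional_spec`.
#' @export
directional_spec <- function(levels = c(2L, 3L, 3L)) {
  levels <- as.integer(levels)
  if (any(is.na(levels)) || any(levels < 0L)) {
    stop("`levels` must be non-negative integers", call. = FALSE)
  }
  structure(list(levels = levels), class = "directional_spec")
}

#' Upsample a kernel by zero insertion (a trous)
#'
#' Inserts `2^level - 1` zeros between adjacent taps, the kernel dilation
#' used at successive pyramid scales (sampling matrix `2 * I` per level).
#' The tap sum is unchanged.
#'
#' @param h0 Numeric 1D kernel (odd length) or 2D kernel (odd side lengths).
#' @param level Dilation level, integer `>= 0`.
#' @return The dilated kernel, same number of dimensions as `h0`.
#' @export
#' @examples
#' atrous_upsample_kernel(c(1, 4, 6, 4, 1) / 16, 1)
atrous_upsample_kernel <- function(h0, level) {
  level <- as.integer(level)
  if (is.na(level) || level < 0L) stop("`level` must be >= 0", call. = FALSE)
  if (!all(is.finite(h0))) stop("`h0` must be finite", call. = FALSE)
  step <- 2L^level
  up1 <- function(v) {
    if (length(v) %% 2L != 1L) stop("kernel length must be odd", call. = FALSE)
    if (step == 1L) return(v)
    out <- numeric(step * (length(v) - 1L) + 1L)
    out[seq(1L, length(out), by = step)] <- v
    out
  }
  if (is.matrix(h0)) {
    nr <- step * (nrow(h0) - 1L) + 1L
    nc <- step * (ncol(h0) - 1L) + 1L
    if (nrow(h0) %% 2L != 1L || ncol(h0) %% 2L != 1L) {
      stop("kernel side lengths must be odd", call. = FALSE)
    }
    out <- matrix(0, nr, nc)
    out[seq(1L, nr, by = step), seq(1L, nc, by = step)] <- h0
    out
  } else {
    up1(h0)
  }
}

#' Non-subsampled pyramid decomposition
#'
#' Additive a trous scheme: `a_0 = image`; `a_j` is `a_{j-1}` convolved with
#' the level-`(j-1)` dilated kernel; band-pass `b_j = a_{j-1} - a_j`. Returns
#' the coarsest approximation and the `J` band-pass images, all input-sized;
#' `a_J + sum(b_j)` reproduces the input exactly.
#'
#' @param image Numeric matrix of finite intensities.
#' @param spec A [pyramid_spec()].
#' @param mode Border extension for the convolutions: `"symmetric"` (mirror,
#'   default) or `"periodic"` (used by shift-covariance checks).
#' @return `list(lowpass = <matrix>, bandpass = <list of J matrices>)`.
#' @export
nsp_decompose <- function(image, spec = pyramid_spec(), mode = "symmetric") {
  assert_image(image)
  J <- spec$scales
  support <- 2L^(J - 1L) * (length(spec$kernel) - 1L) + 1L
  if (min(dim(image)) < support) {
    stop(sprintf("image (%dx%d) smaller than the level-%d kernel support (%d)",
                 nrow(image), ncol(image), J, support), call. = FALSE)
  }
  a <- image
  bands <- vector("list", J)
  for (j in seq_len(J)) {
    k <- atrous_upsample_kernel(spec$kernel, j - 1L)
    a_next <- conv_separable(a, k, mode = mode)
    bands[[j]] <- a - a_next
    a <- a_next
  }
  list(lowpass = a, bandpass = bands)
}

# Orientation fan windows on the (nr x nc) DFT grid: 2^l windows over the
# undirected orientation phi = atan2(fy, fx) mod pi, band k centered at
# phi = k * pi / 2^l, cos^2 cross-fade over half the band spacing. The
# windows sum to 1 at every frequency sample and are symmetric under
# (fx, fy) -> (-fx, -fy), so real inputs give real bands.
nsdfb_windows <- function(nr, nc, l) {
  K <- 2L^l
  fy <- ((seq_len(nr) - 1L + nr %/% 2L) %% nr - nr %/% 2L) / nr
  fx <- ((seq_len(nc) - 1L + nc %/% 2L) %% nc - nc %/% 2L) / nc
  FY <- matrix(fy, nr, nc)
  FX <- matrix(fx, nr, nc, byrow = TRUE)
  phi <- atan2(FY, FX) %% pi
  x <- phi * K / pi                       # orientation in band units, [0, K)
  lapply(seq_len(K) - 1L, function(k) {
    y <- abs(((x - k + K / 2) %% K) - K / 2)   # wrapped distance to center k
    s <- clamp((y - 0.25) / 0.5, 0, 1)         # transition: 0.25 < y < 0.75
    cos(pi / 2 * s)^2
  })
}

#' Directional split of a band-pass image
#'
#' Multiplies the band's 2D spectrum by each of `2^l` smooth orientation fan
#' windows and inverse-transforms. The windows partition unity, so the
#' directional bands sum back to the input exactly (to float tolerance).
#'
#' @param band Numeric matrix (one pyramid band-pass image).
#' @param l Direction level; `l = 0` returns the band unsplit.
#' @return List of `2^l` matrices, each `band`-sized.
#' @export
nsdfb_decompose <- function(band, l) {
  assert_image(band)
  l <- as.integer(l)
  if (is.na(l) || l < 0L) stop("`l` must be >= 0", call. = FALSE)
  if (l == 0L) return(list(band))
  Fb <- stats::fft(band)
  win <- nsdfb_windows(nrow(band), ncol(band), l)
  lapply(win, function(w) {
    Re(stats::fft(Fb * w, inverse = TRUE)) / length(band)
  })
}

#' Forward non-subsampled contourlet transform
#'
#' Pyramid decomposition followed by a directional split of each band-pass
#' scale. All bands retain the source image's size (shift invariance); the
#' transform is inverted exactly by [nsct_inverse()].
#'
#' @inheritParams nsp_decompose
#' @param dspec A [directional_spec()] with one direction level per scale.
#' @return An object of class `nsct_coeffs`: fields `lowpass` (matrix),
#'   `bands` (list over scales of lists of directional band matrices),
#'   `spec`, `dspec`, `mode`.
#' @export
nsct_forward <- function(image, spec = pyramid_spec(),
                         dspec = directional_spec(), mode = "symmetric") {
  if (length(dspec$levels) != spec$scales) {
    stop("`dspec` must supply one direction level per pyramid scale",
         call. = FALSE)
  }
  pyr <- nsp_decompose(image, spec, mode = mode)
  bands <- lapply(seq_len(spec$scales), function(j) {
    nsdfb_decompose(pyr$bandpass[[j]], dspec$levels[j])
  })
  structure(list(lowpass = pyr$lowpass, bands = bands,
                 spec = spec, dspec = dspec, mode = mode),
            class = "nsct_coeffs")
}

#' Inverse non-subsampled contourlet transform
#'
#' The transform is additive, so synthesis is the plain sum of the low-pass
#' band and every directional band at every scale.
#'
#' @param coeffs An `nsct_coeffs` object (from [nsct_forward()], possibly
#'   with modified bands).
#' @return The reconstructed image matrix.
#' @export
nsct_inverse <- function(coeffs) {
  if (!inherits(coeffs, "nsct_coeffs")) {
    stop("`coeffs` must be an `nsct_coeffs` object", call. = FALSE)
  }
  out <- coeffs$lowpass
  for (scale in coeffs$bands) {
    for (band in scale) {
      if (!identical(dim(band), dim(out))) {
        stop("coefficient bands have mismatched shapes", call. = FALSE)
      }
      out <- out + band
    }
  }
  out
}

#' @export
print.nsct_coeffs <- function(x, ...) {
  nb <- vapply(x$bands, length, integer(1))
  cat(sprintf("<nsct_coeffs> %d x %d, %d scales, directional bands: %s\n",
              nrow(x$lowpass), ncol(x$lowpass), x$spec$scales,
              paste(nb, collapse = " + ")))
  invisible(x)
}
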