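# Fusion quality statistics: information entropy, standard deviation,
# average gradient, PSNR against the sources, the edge-information-transfer
# Q index, mutual information, and the windowed spectral-angle (ESAM)
# average. All operate on grayscale matrices with nominal range 0-255.

# 256-bin histogram of floor-binned intensities.
hist256 <- function(img) {
  b <- floor(clamp(img, 0, 255))
  tabulate(as.integer(b) + 1L, nbins = 256L)
}

#' Information entropy of an image
#'
#' Shannon entropy (bits) of the 256-bin intensity histogram; empty bins
#' contribute nothing. Ranges from 0 (constant image) to 8 (uniform
#' histogram).
#'
#' @param img Grayscale matrix, values in [0, 255].
#' @return Entropy in bits.
#' @export
information_entropy <- function(img) {
  assert_image(img)
  p <- hist256(img)
  p <- p[p > 0] / length(img)
  -sum(p * log2(p))
}

#' Population standard deviation of an image
#'
#' @param img Grayscale matrix.
#' @return Standard deviation (intensity units), divisor `n`.
#' @export
standard_deviation <- function(img) {
  assert_image(img)
  sqrt(mean((img - mean(img))^2))
}

#' Average gradient (sharpness proxy)
#'
#' Mean over the interior `(M-1) x (N-1)` grid of
#' `sqrt((dx^2 + dy^2) / 2)`, with `dx`, `dy` forward differences.
#'
#' @param img Grayscale matrix, at least 2 x 2.
#' @return Average gradient (intensity per pixel).
#' @export
average_gradient <- function(img) {
  assert_image(img, min_dim = 2L)
  M <- nrow(img); N <- ncol(img)
  core <- img[-M, -N]
  dx <- img[-M, -1L] - core
  dy <- img[-1L, -N] - core
  mean(sqrt((dx^2 + dy^2) / 2))
}

# PSNR of one pair; MSE of 0 is capped at 100 dB.
psnr_one <- function(F, X) {
  mse <- mean((F - X)^2)
  if (mse == 0) return(100)
  min(10 * log10(255^2 / mse), 100)
}

#' Peak signal-to-noise ratio of a fused image against both sources
#'
#' Mean of the two PSNRs (dB) of the fused image against each source;
#' a zero-MSE pair contributes the 100 dB cap.
#'
#' @param A,B Source image matrices.
#' @param F Fused image matrix.
#' @return PSNR in dB.
#' @export
psnr_pair <- function(A, B, F) {
  assert_image(A); assert_image(B); assert_image(F)
  assert_same_shape(A, F); assert_same_shape(B, F)
  (psnr_one(F, A) + psnr_one(F, B)) / 2
}

# Sobel gradients with symmetric padding: list(gx, gy, g, alpha).
sobel_edges <- function(img) {
  ridx <- pad_index(nrow(img), 1L, "symmetric")
  cidx <- pad_index(ncol(img), 1L, "symmetric")
  p <- img[ridx, cidx]
  M <- nrow(img); N <- ncol(img)
  sh <- function(dr, dc) p[(1L + dr):(M + dr), (1L + dc):(N + dc)]
  gx <- (sh(1L, 2L) - sh(1L, 0L)) * 2 +
        (sh(0L, 2L) - sh(0L, 0L)) + (sh(2L, 2L) - sh(2L, 0L))
  gy <- (sh(2L, 1L) - sh(0L, 1L)) * 2 +
        (sh(2L, 0L) - sh(0L, 0L)) + (sh(2L, 2L) - sh(0L, 2L))
  g <- sqrt(gx^2 + gy^2)
  alpha <- atan2(gy, gx)
  alpha <- ifelse(alpha > pi / 2, alpha - pi, alpha)   # undirected
  alpha <- ifelse(alpha <= -pi / 2, alpha + pi, alpha)
  list(g = g, alpha = alpha)
}

# Sigmoid preservation score, normalized so a perfect input scores 1.
petrovic_sigmoid <- function(x, gamma, kappa, sigma) {
  raw <- gamma / (1 + exp(kappa * (x - sigma)))
  top <- gamma / (1 + exp(kappa * (1 - sigma)))
  raw / top
}

# Per-source edge preservation Q^{XF}.
edge_preservation <- function(eX, eF) {
  gX <- eX$g; gF <- eF$g
  G <- ifelse(gX == 0 & gF == 0, 1,
       ifelse(gX >= gF, ifelse(gX == 0, 0, gF / gX),
              gX / gF))
  d <- abs(eX$alpha - eF$alpha)
  d <- pmin(d, pi - d)                     # fold: orientation is undirected
  A <- 1 - d / (pi / 2)
  Qg <- petrovic_sigmoid(G, 0.9994, -15, 0.5)
  Qa <- petrovic_sigmoid(A, 0.9879, -22, 0.8)
  Qg * Qa
}

#' Edge-information-transfer index Q
#'
#' The Xydeas-Petrovic Q^(AB/F): Sobel edge strength and orientation are
#' computed for sources and fused image; per-pixel strength and orientation
#' preservation pass through sigmoids (constants 0.9994/-15/0.5 and
#' 0.9879/-22/0.8, each normalized so perfect preservation scores 1); the
#' two per-source scores are averaged with the sources' edge strengths as
#' weights. 1 means all edge information was transferred; images with no
#' edges at all score 1 by convention.
#'
#' @param A,B Source image matrices.
#' @param F Fused image matrix.
#' @return Q in [0, 1].
#' @export
q_index <- function(A, B, F) {
  assert_image(A); assert_image(B); assert_image(F)
  assert_same_shape(A, F); assert_same_shape(B, F)
  eA <- sobel_edges(A); eB <- sobel_edges(B); eF <- sobel_edges(F)
  QAF <- edge_preservation(eA, eF)
  QBF <- edge_preservation(eB, eF)
  wsum <- sum(eA$g) + sum(eB$g)
  if (wsum == 0) return(1)
  sum(QAF * eA$g + QBF * eB$g) / wsum
}

# MI between two floor-binned images, in bits.
mi_one <- function(X, Y) {
  bx <- as.integer(floor(clamp(X, 0, 255)))
  by <- as.integer(floor(clamp(Y, 0, 255)))
  joint <- tabulate(bx * 256L + by + 1L, nbins = 256L * 256L)
  joint <- joint[joint > 0] / length(bx)
  px <- tabulate(bx + 1L, nbins = 256L) / length(bx)
  py <- tabulate(by + 1L, nbins = 256L) / length(by)
  hx <- -sum(px[px > 0] * log2(px[px > 0]))
  hy <- -sum(py[py > 0] * log2(py[py > 0]))
  hxy <- -sum(joint * log2(joint))
  hx + hy - hxy
}

#' Mutual information between the fused image and both sources
#'
#' `MI(A; F) + MI(B; F)` in bits, from 256-bin joint histograms of
#' floor-binned intensities.
#'
#' @param A,B Source image matrices.
#' @param F Fused image matrix.
#' @return Mutual information in bits.
#' @export
mutual_information <- function(A, B, F) {
  assert_image(A); assert_image(B); assert_image(F)
  assert_same_shape(A, F); assert_same_shape(B, F)
  mi_one(A, F) + mi_one(B, F)
}

#' Windowed spectral-angle average (ESAM AE)
#'
#' Both images are tiled into non-overlapping `window_size` square blocks
#' (partial border blocks are dropped); per block, the spectral angle
#' `acos(<x, f> / (|x| |f|))` between the vectorized blocks is taken, with
#' zero-norm pairs contributing 0. The AE is the mean angle in degrees;
#' lower means more similar.
#'
#' @param X One source image matrix.
#' @param F Fused image matrix, same shape.
#' @param window_size Block side length (e.g. 16, 32, 64).
#' @return Mean spectral angle in degrees, in [0, 90].
#' @export
esam_ae <- function(X, F, window_size = 16L) {
  assert_image(X); assert_image(F)
  assert_same_shape(X, F)
  ws <- as.integer(window_size)
  nbr <- nrow(X) %/% ws
  nbc <- ncol(X) %/% ws
  if (nbr < 1L || nbc < 1L) {
    stop("`window_size` larger than the image", call. = FALSE)
  }
  angles <- numeric(nbr * nbc)
  k <- 0L
  for (i in seq_len(nbr)) {
    for (j in seq_len(nbc)) {
      rows <- ((i - 1L) * ws + 1L):(i * ws)
      cols <- ((j - 1L) * ws + 1L):(j * ws)
      x <- as.vector(X[rows, cols]); f <- as.vector(F[rows, cols])
      nx <- sqrt(sum(x^2)); nf <- sqrt(sum(f^2))
      k <- k + 1L
      angles[k] <- if (nx == 0 || nf == 0) 0 else {
        acos(clamp(sum(x * f) / (nx * nf), -1, 1)) * 180 / pi
      }
    }
  }
  mean(angles)
}

#' Full fusion quality report
#'
#' Computes the seven-statistic evaluation suite for one (A, B, F) triple:
#' entropy, standard deviation and average gradient of the fused image,
#' PSNR against the sources, the Q index, mutual information, and the
#' spectral-angle averages for each source at each requested window size.
#'
#' @param A,B Source image matrices.
#' @param F Fused image matrix.
#' @param esam_windows Block sizes for the spectral-angle metric.
#' @return A one-row tibble: `ie`, `sd`, `ag`, `psnr`, `q_index`, `mi`, and
#'   `ae_a_<w>` / `ae_b_<w>` columns per window size.
#' @export
fusion_metrics <- function(A, B, F, esam_windows = c(16L, 32L, 64L)) {
  out <- tibble::tibble(
    ie = information_entropy(F),
    sd = standard_deviation(F),
    ag = average_gradient(F),
    psnr = psnr_pair(A, B, F),
    q_index = q_index(A, B, F),
    mi = mutual_information(A, B, F)
  )
  for (w in esam_windows) {
    out[[paste0("ae_a_", w)]] <- esam_ae(A, F, w)
    out[[paste0("ae_b_", w)]] <- esam_ae(B, F, w)
  }
  out
}
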