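# Comparator fusers for the benchmarking harness: PCA weighting, classic
# (Lee-Seung) whole-image NMF, a decimated biorthogonal 9/7 wavelet fuser,
# and a basic contourlet fuser with conventional rules (low-pass averaging,
# band-pass max-abs selection).

#' PCA-weighted fusion
#'
#' The fused image is the weighted sum of the sources, with weights the
#' leading eigenvector of the 2 x 2 covariance of the vectorized sources,
#' normalized to sum to 1.
#'
#' @param A,B Registered same-size grayscale matrices.
#' @return The fused image matrix.
#' @export
pca_fuse <- function(A, B) {
  assert_image(A); assert_image(B)
  assert_same_shape(A, B, "source images")
  C <- stats::cov(cbind(as.vector(A), as.vector(B)))
  ev <- eigen(C, symmetric = TRUE)$vectors[, 1L]
  ev <- abs(ev)
  if (sum(ev) == 0) ev <- c(1, 1)          # both sources constant
  w <- ev / sum(ev)
  w[1L] * A + w[2L] * B
}

#' Classic whole-image NMF fusion
#'
#' The same rank-1 scheme as [fuse_lowpass()] -- vectorized sources as the
#' two columns of V, fused image `W * mean(H)` -- but applied to the whole
#' images with plain Lee-Seung updates and no contourlet decomposition.
#'
#' @param A,B Registered same-size grayscale matrices.
#' @param config A [fusion_config()]; its `anmf` component supplies
#'   iteration count, guard and seed.
#' @return The fused image matrix.
#' @export
nmf_fuse <- function(A, B, config = fusion_config()) {
  bm <- build_lowpass_matrix(A, B)
  fit <- lee_seung_factorize(bm$V, 1L, config$anmf)
  fused <- fit$W[, 1L] * mean(fit$H) + bm$shift
  matrix(fused, nrow = bm$dim[1L], ncol = bm$dim[2L], byrow = TRUE)
}

# ---- CDF 9/7 biorthogonal wavelet via the lifting factorization ----------
# Lifting is exactly invertible for any signal length, so the fuser's
# self-fusion identity holds to floating tolerance.

cdf97 <- list(a1 = -1.586134342059924, a2 = -0.052980118572961,
              a3 = 0.882911075530934, a4 = 0.443506852043971,
              k = 1.230174104914001)

# One lifting step: y_i <- y_i + a * (x_left(i) + x_right(i)), where for a
# predict step y = odd samples flanked by evens and vice versa for update.
# s has ns samples, d has nd samples, nd in {ns - 1, ns} (interleaved
# s1 d1 s2 d2 ...). Boundaries replicate the nearest existing neighbor.
lift_predict <- function(d, s, a) {
  nd <- length(d); ns <- length(s)
  right <- if (ns >= nd + 1L) s[2L:(nd + 1L)] else c(s[-1L], s[ns])
  d + a * (s[1L:nd] + right)
}
lift_update <- function(s, d, a) {
  ns <- length(s); nd <- length(d)
  left <- c(d[1L], d)[1L:ns]               # replicate first d at the edge
  right <- if (nd >= ns) d[1L:ns] else c(d, d[nd])[1L:ns]
  s + a * (left + right)
}

dwt97_1d <- function(x) {
  n <- length(x)
  if (n < 2L) return(list(s = x, d = numeric(0)))
  s <- x[seq(1L, n, by = 2L)]
  d <- x[seq(2L, n, by = 2L)]
  d <- lift_predict(d, s, cdf97$a1)
  s <- lift_update(s, d, cdf97$a2)
  d <- lift_predict(d, s, cdf97$a3)
  s <- lift_update(s, d, cdf97$a4)
  list(s = s * cdf97$k, d = d / cdf97$k)
}

idwt97_1d <- function(s, d) {
  if (length(d) == 0L) return(s)
  s <- s / cdf97$k
  d <- d * cdf97$k
  s <- lift_update(s, d, -cdf97$a4)
  d <- lift_predict(d, s, -cdf97$a3)
  s <- lift_update(s, d, -cdf97$a2)
  d <- lift_predict(d, s, -cdf97$a1)
  n <- length(s) + length(d)
  x <- numeric(n)
  x[seq(1L, n, by = 2L)] <- s
  x[seq(2L, n, by = 2L)] <- d
  x
}

dwt97_2d <- function(x) {
  colres <- apply(x, 2L, dwt97_1d)
  L <- do.call(cbind, lapply(colres, `[[`, "s"))
  Hh <- do.call(cbind, lapply(colres, `[[`, "d"))
  rsplit <- function(m) {
    res <- apply(m, 1L, dwt97_1d)
    list(lo = do.call(rbind, lapply(res, `[[`, "s")),
         hi = do.call(rbind, lapply(res, `[[`, "d")))
  }
  l <- rsplit(L); h <- rsplit(Hh)
  list(LL = l$lo, LH = l$hi, HL = h$lo, HH = h$hi)
}

idwt97_2d <- function(bands, n_rows, n_cols) {
  rjoin <- function(lo, hi, nc) {
    t(vapply(seq_len(nrow(lo)),
             function(i) idwt97_1d(lo[i, ], hi[i, ]), numeric(nc)))
  }
  L <- rjoin(bands$LL, bands$LH, n_cols)
  Hh <- rjoin(bands$HL, bands$HH, n_cols)
  vapply(seq_len(n_cols),
         function(j) idwt97_1d(L[, j], Hh[, j]), numeric(n_rows))
}

wave97_forward <- function(x, levels) {
  out <- list()
  dims <- list()
  for (lev in seq_len(levels)) {
    if (min(dim(x)) < 8L) break
    dims[[lev]] <- dim(x)
    b <- dwt97_2d(x)
    out[[lev]] <- b[c("LH", "HL", "HH")]
    x <- b$LL
  }
  list(approx = x, detail = out, dims = dims)
}

wave97_inverse <- function(w) {
  x <- w$approx
  for (lev in rev(seq_along(w$detail))) {
    b <- w$detail[[lev]]
    b$LL <- x
    x <- idwt97_2d(b, w$dims[[lev]][1L], w$dims[[lev]][2L])
  }
  x
}

#' Biorthogonal 9/7 wavelet fusion
#'
#' Decimated CDF 9/7 wavelet decomposition of both sources (`levels` deep);
#' detail coefficients are fused by maximum absolute value, the coarse
#' approximation by the mean; inverse transform returns the fused image.
#'
#' @param A,B Registered same-size grayscale matrices.
#' @param levels Decomposition depth. Default 3.
#' @return The fused image matrix.
#' @export
wavelet_fuse <- function(A, B, levels = 3L) {
  assert_image(A, min_dim = 8L); assert_image(B, min_dim = 8L)
  assert_same_shape(A, B, "source images")
  wA <- wave97_forward(A, levels)
  wB <- wave97_forward(B, levels)
  fused <- wA
  fused$approx <- (wA$approx + wB$approx) / 2
  for (lev in seq_along(wA$detail)) {
    for (nm in names(wA$detail[[lev]])) {
      a <- wA$detail[[lev]][[nm]]; b <- wB$detail[[lev]][[nm]]
      fused$detail[[lev]][[nm]] <- ifelse(abs(a) >= abs(b), a, b)
    }
  }
  wave97_inverse(fused)
}

#' Basic contourlet fusion (conventional rules)
#'
#' The contourlet pipeline of [fuse_images()] with the learned/adaptive
#' rules replaced by conventional ones: low-pass bands averaged, band-pass
#' coefficients selected by maximum absolute value. Serves as the
#' plain-contourlet comparator in the benchmark harness.
#'
#' @param A,B Registered same-size grayscale matrices.
#' @param config A [fusion_config()] (decomposition settings and output
#'   handling are honored; `T` and the ANMF settings are unused).
#' @return The fused image matrix.
#' @export
nsct_basic_fuse <- function(A, B, config = fusion_config()) {
  assert_image(A, min_dim = 8L); assert_image(B, min_dim = 8L)
  assert_same_shape(A, B, "source images")
  cA <- nsct_forward(A, config$spec, config$dspec)
  cB <- nsct_forward(B, config$spec, config$dspec)
  fused <- cA
  fused$lowpass <- (cA$lowpass + cB$lowpass) / 2
  for (j in seq_along(cA$bands)) {
    for (d in seq_along(cA$bands[[j]])) {
      a <- cA$bands[[j]][[d]]; b <- cB$bands[[j]][[d]]
      fused$bands[[j]][[d]] <- ifelse(abs(a) >= abs(b), a, b)
    }
  }
  out <- nsct_inverse(fused)
  if (config$output == "clip-0-255") out <- clamp(out, 0, 255)
  out
}
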