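# The four-step fusion pipeline: contourlet analysis of both sources,
# rank-1 accelerated-NMF fusion of the low-pass pair, neighborhood-
# homogeneity fusion of every band-pass directional pair, and additive
# synthesis.

#' Configuration for the fusion pipeline
#'
#' @param spec Pyramid specification ([pyramid_spec()]).
#' @param dspec Directional specification ([directional_spec()]).
#' @param T NHM threshold in (0.5, 1) separating selection from weighted
#'   averaging of band-pass coefficients. Default 0.75.
#' @param anmf An [anmf_config()] for the low-pass factorization
#'   (default: 1000 iterations, `tau = 0.99`).
#' @param neighborhood Odd side length of the NHM/energy window. Default 3.
#' @param output One of `"clip-0-255"` (8-bit-style clamped output, default)
#'   or `"float"` (raw reconstruction).
#' @param seed Seed forwarded to the ANMF initialization.
#' @return An object of class `fusion_config`.
#' @export
fusion_config <- function(spec = pyramid_spec(), dspec = directional_spec(),
                          T = 0.75, anmf = anmf_config(seed = seed),
                          neighborhood = 3L,
                          output = c("clip-0-255", "float"), seed = 1L) {
  if (!(T > 0.5 && T < 1)) stop("`T` must lie in (0.5, 1)", call. = FALSE)
  neighborhood <- as.integer(neighborhood)
  if (neighborhood < 1L || neighborhood %% 2L != 1L) {
    stop("`neighborhood` must be a positive odd integer", call. = FALSE)
  }
  structure(list(spec = spec, dspec = dspec, T = T, anmf = anmf,
                 neighborhood = neighborhood, output = match.arg(output),
                 seed = seed),
            class = "fusion_config")
}

#' Stack two low-pass bands as a nonnegative two-column matrix
#'
#' Row-major vectorizations of the two bands become the two columns of the
#' factorization data matrix. If either band dips below zero, both columns
#' are shifted up by the common minimum; the shift is returned so the fused
#' band can be restored to the original intensity scale.
#'
#' @param lowA,lowB Same-shape low-pass band matrices.
#' @return `list(V = <n x 2 matrix>, shift = <scalar>, dim = dim(lowA))`.
#' @export
build_lowpass_matrix <- function(lowA, lowB) {
  assert_image(lowA); assert_image(lowB)
  assert_same_shape(lowA, lowB, "low-pass bands")
  shift <- min(0, min(lowA), min(lowB))
  # row-major: transpose before vectorizing (R stores column-major)
  V <- cbind(as.vector(t(lowA)) - shift, as.vector(t(lowB)) - shift)
  list(V = V, shift = shift, dim = dim(lowA))
}

#' Fuse two low-pass bands by rank-1 accelerated NMF
#'
#' The two vectorized bands form the columns of a nonnegative matrix `V`;
#' a rank-1 factorization `V ~ W %*% H` extracts the shared structure, and
#' the fused band is `W * mean(H)` -- the mean of the two mixing
#' coefficients fixes the scale indeterminacy of NMF so the fused band sits
#' on the sources' intensity scale.
#'
#' @param lowA,lowB Same-shape low-pass band matrices.
#' @param config A [fusion_config()] (its `anmf` component drives the
#'   factorization).
#' @return The fused low-pass band matrix.
#' @export
fuse_lowpass <- function(lowA, lowB, config = fusion_config()) {
  bm <- build_lowpass_matrix(lowA, lowB)
  fit <- anmf_factorize(bm$V, 1L, config$anmf)
  fused <- fit$W[, 1L] * mean(fit$H) + bm$shift
  matrix(fused, nrow = bm$dim[1L], ncol = bm$dim[2L], byrow = TRUE)
}

#' Neighborhood energy at one position
#'
#' Sum of squared coefficients over the odd `window` x `window` neighborhood
#' centered at (`row`, `col`), with symmetric border padding.
#'
#' @param band Coefficient matrix.
#' @param row,col Center position (1-based).
#' @param window Odd window side length.
#' @return A nonnegative scalar.
#' @export
neighborhood_energy <- function(band, row, col, window = 3L) {
  assert_image(band)
  if (window %% 2L != 1L) stop("`window` must be odd", call. = FALSE)
  E <- box_sum(band^2, window)
  E[row, col]
}

#' Neighborhood homogeneity map of two band-pass bands
#'
#' At each position, `2 * sum(|A| * |B|) / (E_A + E_B)` over the window,
#' where `E_X` is the windowed sum of squared coefficients: a [0, 1] score
#' of how alike the two neighborhoods are (1 where identical, 0 where one
#' band is empty). Positions where both energies vanish are defined as 1.
#'
#' @param bandA,bandB Same-shape coefficient matrices.
#' @param window Odd window side length. Default 3.
#' @return A matrix of NHM values in [0, 1].
#' @export
nhm_map <- function(bandA, bandB, window = 3L) {
  assert_image(bandA); assert_image(bandB)
  assert_same_shape(bandA, bandB, "band-pass bands")
  EA <- box_sum(bandA^2, window)
  EB <- box_sum(bandB^2, window)
  S <- box_sum(abs(bandA) * abs(bandB), window)
  denom <- EA + EB
  nhm <- ifelse(denom == 0, 1, 2 * S / denom)
  clamp(nhm, 0, 1)
}

#' Fuse a pair of band-pass directional bands by the NHM rule
#'
#' Where the neighborhoods disagree (`NHM < T`) the coefficient with the
#' larger neighborhood energy is selected (ties go to A); where they agree
#' (`NHM >= T`) the fused coefficient is the NHM-weighted average
#' `NHM * c_max + (1 - NHM) * c_min`, with `c_max`/`c_min` the source
#' coefficients of larger/smaller absolute value.
#'
#' @param bandA,bandB Same-shape coefficient matrices.
#' @param config A [fusion_config()] supplying `T` and the window size.
#' @return The fused band matrix.
#' @export
fuse_bandpass <- function(bandA, bandB, config = fusion_config()) {
  assert_image(bandA); assert_image(bandB)
  assert_same_shape(bandA, bandB, "band-pass bands")
  w <- config$neighborhood
  EA <- box_sum(bandA^2, w)
  EB <- box_sum(bandB^2, w)
  S <- box_sum(abs(bandA) * abs(bandB), w)
  denom <- EA + EB
  nhm <- clamp(ifelse(denom == 0, 1, 2 * S / denom), 0, 1)

  sel <- ifelse(EA >= EB, bandA, bandB)          # NHM < T: energy selection
  a_major <- abs(bandA) >= abs(bandB)            # ties -> A
  cmax <- ifelse(a_major, bandA, bandB)
  cmin <- ifelse(a_major, bandB, bandA)
  avg <- nhm * cmax + (1 - nhm) * cmin           # NHM >= T: weighted average
  ifelse(nhm < config$T, sel, avg)
}

#' Fuse two registered grayscale images
#'
#' The full pipeline: non-subsampled contourlet analysis of both sources,
#' rank-1 accelerated-NMF fusion of the low-pass pair ([fuse_lowpass()]),
#' NHM fusion of each directional band pair ([fuse_bandpass()]), and
#' additive synthesis ([nsct_inverse()]). Deterministic given
#' `config$seed`.
#'
#' @param A,B Registered same-size grayscale image matrices
#'   (nominal range 0-255).
#' @param config A [fusion_config()].
#' @return The fused image matrix (clamped to [0, 255] unless
#'   `config$output == "float"`).
#' @export
fuse_images <- function(A, B, config = fusion_config()) {
  assert_image(A, min_dim = 8L); assert_image(B, min_dim = 8L)
  assert_same_shape(A, B, "source images")
  cA <- nsct_forward(A, config$spec, config$dspec)
  cB <- nsct_forward(B, config$spec, config$dspec)
  fused <- cA
  fused$lowpass <- fuse_lowpass(cA$lowpass, cB$lowpass, config)
  for (j in seq_along(cA$bands)) {
    for (d in seq_along(cA$bands[[j]])) {
      fused$bands[[j]][[d]] <-
        fuse_bandpass(cA$bands[[j]][[d]], cB$bands[[j]][[d]], config)
    }
  }
  out <- nsct_inverse(fused)
  if (config$output == "clip-0-255") out <- clamp(out, 0, 255)
  out
}
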