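# Seeded synthetic test scenes standing in for the three classic fusion
# regimes: complementary-defocus multi-focus pairs with an all-in-focus
# ground truth, CT/MRI-like modality pairs with complementary contrast, and
# visible/infrared pairs with a hot target absent from the visible band.
# All generators are deterministic given the seed.

#' Scene specification for the synthetic generators
#'
#' @param rows,cols Scene size in pixels (at least 64 x 64).
#' @param seed Integer seed; equal seeds give bit-identical scenes.
#' @param blur_sigma Gaussian defocus sigma (pixels) for the multi-focus
#'   pair. Default 3.
#' @param split Column fraction of the focus boundary. Default 0.5.
#' @param feather Width (pixels) of the linear cross-fade at the focus
#'   boundary. Default 5.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(rows = 64L, cols = 64L, seed = 1L, blur_sigma = 3,
                       split = 0.5, feather = 5L) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows < 64L || cols < 64L) stop("scene must be at least 64 x 64", call. = FALSE)
  if (blur_sigma <= 0) stop("`blur_sigma` must be positive", call. = FALSE)
  if (!(split > 0 && split < 1)) stop("`split` must lie in (0, 1)", call. = FALSE)
  structure(list(rows = rows, cols = cols, seed = as.integer(seed),
                 blur_sigma = blur_sigma, split = split,
                 feather = as.integer(feather)),
            class = "scene_spec")
}

# Add a filled random rectangle or disc of the given intensity.
add_shapes <- function(img, n_shapes, lo = 30, hi = 225) {
  M <- nrow(img); N <- ncol(img)
  rr <- matrix(seq_len(M), M, N)
  cc <- matrix(seq_len(N), M, N, byrow = TRUE)
  for (i in seq_len(n_shapes)) {
    val <- runif(1, lo, hi)
    if (runif(1) < 0.5) {
      r0 <- sample.int(M - 8L, 1L); c0 <- sample.int(N - 8L, 1L)
      h <- sample(4:max(5L, M %/% 3L), 1L); w <- sample(4:max(5L, N %/% 3L), 1L)
      img[r0:min(M, r0 + h), c0:min(N, c0 + w)] <- val
    } else {
      cy <- runif(1, 1, M); cx <- runif(1, 1, N)
      rad <- runif(1, min(M, N) / 16, min(M, N) / 5)
      img[(rr - cy)^2 + (cc - cx)^2 <= rad^2] <- val
    }
  }
  img
}

#' Generate a base scene
#'
#' A seeded composite of a smooth illumination gradient, sharp-edged
#' polygons and discs, and fine texture, rescaled to span [0, 255]. Rich
#' enough in edges and gray levels (entropy well above 4 bits) to exercise
#' every stage of the fusion pipeline.
#'
#' @param spec A [scene_spec()].
#' @return A `rows x cols` grayscale matrix in [0, 255].
#' @export
make_base_scene <- function(spec = scene_spec()) {
  with_seed(spec$seed, {
    M <- spec$rows; N <- spec$cols
    rr <- matrix(seq_len(M) / M, M, N)
    cc <- matrix(seq_len(N) / N, M, N, byrow = TRUE)
    base <- 90 + 70 * rr + 50 * sin(2 * pi * cc * runif(1, 0.5, 1.5))
    base <- add_shapes(base, 8L)
    texture <- gaussian_blur(matrix(rnorm(M * N), M, N), 0.8) * 18
    img <- base + texture
    img <- (img - min(img)) / (max(img) - min(img)) * 255
    img
  })
}

# Linear cross-fade mask: 0 left of the boundary, 1 right, feathered.
focus_mask <- function(M, N, split, feather) {
  edge <- split * N
  ramp <- clamp((seq_len(N) - edge) / max(feather, 1L) + 0.5, 0, 1)
  matrix(ramp, M, N, byrow = TRUE)
}

#' Generate a multi-focus pair with ground truth
#'
#' `G` is the all-in-focus base scene; `A` is `G` defocused (Gaussian blur)
#' to the right of the split boundary, `B` defocused to the left. The
#' boundary is feathered so no seam artifact dominates the fusion test; the
#' far sides of the boundary are untouched copies of `G`.
#'
#' @param spec A [scene_spec()].
#' @return `list(A = , B = , G = )` of grayscale matrices.
#' @export
make_multifocus_pair <- function(spec = scene_spec()) {
  G <- make_base_scene(spec)
  blurred <- gaussian_blur(G, spec$blur_sigma)
  m <- focus_mask(spec$rows, spec$cols, spec$split, spec$feather)
  list(A = G * (1 - m) + blurred * m,    # right side out of focus
       B = G * m + blurred * (1 - m),    # left side out of focus
       G = G)
}

#' Generate a CT/MRI-like modality pair
#'
#' `A` is a piecewise-constant phantom with a bright bone-like shell and a
#' dim interior; `B` shares the geometry but inverts the shell contrast and
#' carries internal soft-structure texture absent from `A`. The pair has
#' complementary information by construction.
#'
#' @param spec A [scene_spec()].
#' @return `list(A = , B = )` of grayscale matrices.
#' @export
make_modal_pair <- function(spec = scene_spec()) {
  with_seed(spec$seed, {
    M <- spec$rows; N <- spec$cols
    rr <- matrix(seq_len(M), M, N)
    cc <- matrix(seq_len(N), M, N, byrow = TRUE)
    cy <- M / 2 + runif(1, -M / 16, M / 16)
    cx <- N / 2 + runif(1, -N / 16, N / 16)
    ry <- M * 0.38; rx <- N * 0.34
    r2 <- ((rr - cy) / ry)^2 + ((cc - cx) / rx)^2
    shell <- r2 <= 1 & r2 >= 0.72
    interior <- r2 < 0.72

    A <- matrix(12, M, N)                 # CT-like: bright shell, dim inside
    A[interior] <- 60
    A[shell] <- 235

    B <- matrix(25, M, N)                 # MR-like: dark shell, soft detail
    B[shell] <- 40
    soft <- 120 + 60 * sin(2 * pi * rr / M * 3) * cos(2 * pi * cc / N * 2.3) +
      gaussian_blur(matrix(rnorm(M * N), M, N), 1.5) * 45
    B[interior] <- clamp(soft[interior], 5, 250)
    # a few focal bright structures only B sees
    B <- with_seed(spec$seed + 101L, {
      Bi <- add_shapes(matrix(0, M, N), 4L, lo = 150, hi = 245)
      ifelse(interior & Bi > 0, Bi, B)
    })
    list(A = clamp(A, 0, 255), B = clamp(B, 0, 255))
  })
}

#' Generate a visible/infrared pair with a hot target
#'
#' `A` (visible) is a textured scene in which the target region sits at
#' background intensity -- invisible; `B` (infrared) is a smooth,
#' low-texture rendition with a bright hot blob at the target region.
#'
#' @param spec A [scene_spec()].
#' @return `list(A = , B = , target = <logical mask>)`.
#' @export
make_visible_ir_pair <- function(spec = scene_spec()) {
  with_seed(spec$seed, {
    M <- spec$rows; N <- spec$cols
    rr <- matrix(seq_len(M), M, N)
    cc <- matrix(seq_len(N), M, N, byrow = TRUE)
    # visible: textured background with structures
    A <- 80 + 50 * (rr / M) + 25 * sin(2 * pi * cc / N * 4)
    A <- add_shapes(A, 6L, lo = 60, hi = 200)
    A <- A + gaussian_blur(matrix(rnorm(M * N), M, N), 0.7) * 15
    A <- clamp(A, 0, 255)
    # target: ellipse in the lower half, at background intensity in A
    cy <- M * runif(1, 0.55, 0.75); cx <- N * runif(1, 0.3, 0.7)
    target <- ((rr - cy) / (M * 0.1))^2 + ((cc - cx) / (N * 0.05))^2 <= 1
    A[target] <- mean(A[!target])
    # infrared: heavy smoothing, compressed contrast, hot target
    B <- gaussian_blur(A, 4) * 0.35 + 40
    B[target] <- 235
    B <- clamp(B, 0, 255)
    list(A = A, B = B, target = target)
  })
}
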