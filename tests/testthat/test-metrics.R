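# Quality metrics: closed-form fixed points, brute-force oracles, bounds.

test_that("information entropy hits its closed-form anchors", {
  expect_identical(information_entropy(matrix(7, 16, 16)), 0)
  half <- matrix(c(0, 255), 16, 16)
  expect_equal(information_entropy(half), 1)
  u <- matrix(rep(0:255, each = 4), 32, 32)
  expect_equal(information_entropy(u), 8)
})

test_that("standard deviation is the population formula", {
  expect_identical(standard_deviation(matrix(9, 8, 8)), 0)
  expect_equal(standard_deviation(matrix(c(0, 2), 8, 8)), 1)
  x <- rand_image(16, seed = 1)
  expect_equal(standard_deviation(x),
               sqrt(sum((x - mean(x))^2) / length(x)))
})

test_that("average gradient matches forward differences", {
  expect_identical(average_gradient(matrix(5, 8, 8)), 0)
  ramp <- matrix(rep(1:8, times = 8), 8, 8, byrow = TRUE)
  expect_equal(average_gradient(ramp), sqrt(1 / 2))
  x <- rand_image(6, seed = 2)
  acc <- 0
  for (i in 1:5) for (j in 1:5) {
    dx <- x[i, j + 1] - x[i, j]; dy <- x[i + 1, j] - x[i, j]
    acc <- acc + sqrt((dx^2 + dy^2) / 2)
  }
  expect_equal(average_gradient(x), acc / 25)
})

test_that("PSNR closed forms and the zero-MSE cap hold", {
  A <- rand_image(16, seed = 3)
  expect_identical(psnr_pair(A, A, A), 100)
  F1 <- A + matrix(sample(c(-1, 1), 256, TRUE), 16, 16)
  expect_equal(psnr_pair(A, A, F1), 10 * log10(255^2))
  B <- rand_image(16, seed = 4)
  F2 <- rand_image(16, seed = 5)
  expect_equal(psnr_pair(A, B, F2),
               (10 * log10(255^2 / mean((F2 - A)^2)) +
                10 * log10(255^2 / mean((F2 - B)^2))) / 2)
})

test_that("Q index scores perfect fusion near 1 and a flat fusion near 0", {
  A <- make_base_scene(scene_spec(seed = 6))
  expect_gte(q_index(A, A, A), 0.99)
  expect_lte(q_index(A, A, matrix(100, nrow(A), ncol(A))), 0.1)
})

test_that("Q index matches an independent transcription on a fixed triple", {
  A <- rand_image(8, seed = 7); B <- rand_image(8, seed = 8)
  F <- (A + B) / 2
  # independent double-loop transcription of the edge-preservation model
  reflect <- function(i, n) { m <- (i - 1) %% (2 * n); if (m < n) m + 1 else 2 * n - m }
  sob <- function(img) {
    M <- nrow(img); N <- ncol(img)
    g <- matrix(0, M, N); al <- matrix(0, M, N)
    kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)        # columns: -1 0 1
    ky <- t(kx)
    for (i in 1:M) for (j in 1:N) {
      sx <- 0; sy <- 0
      for (a in -1:1) for (b in -1:1) {
        v <- img[reflect(i + a, M), reflect(j + b, N)]
        sx <- sx + v * kx[a + 2, b + 2]
        sy <- sy + v * ky[a + 2, b + 2]
      }
      g[i, j] <- sqrt(sx^2 + sy^2)
      aa <- atan2(sy, sx)
      if (aa > pi / 2) aa <- aa - pi
      if (aa <= -pi / 2) aa <- aa + pi
      al[i, j] <- aa
    }
    list(g = g, al = al)
  }
  sig <- function(x, ga, ka, si) {
    (ga / (1 + exp(ka * (x - si)))) / (ga / (1 + exp(ka * (1 - si))))
  }
  qxf <- function(eX, eF) {
    G <- matrix(1, 8, 8)
    for (i in 1:8) for (j in 1:8) {
      gx <- eX$g[i, j]; gf <- eF$g[i, j]
      G[i, j] <- if (gx == 0 && gf == 0) 1 else if (gx >= gf) gf / gx else gx / gf
    }
    d <- abs(eX$al - eF$al); d <- pmin(d, pi - d)
    sig(G, 0.9994, -15, 0.5) * sig(1 - d / (pi / 2), 0.9879, -22, 0.8)
  }
  eA <- sob(A); eB <- sob(B); eF <- sob(F)
  want <- sum(qxf(eA, eF) * eA$g + qxf(eB, eF) * eB$g) / (sum(eA$g) + sum(eB$g))
  expect_equal(q_index(A, B, F), want, tolerance = 1e-10)
})

test_that("mutual information matches joint-histogram brute force", {
  u <- matrix(rep(0:255, each = 4), 32, 32)
  expect_equal(mutual_information(u, u, u), 16)
  # independent coarse-leveled noise: finite-sample MI near zero
  set.seed(9)
  A <- matrix(sample(seq(0, 224, by = 32), 4096, TRUE), 64, 64)
  F <- matrix(sample(seq(0, 224, by = 32), 4096, TRUE), 64, 64)
  expect_lte(mutual_information(A, A, F) / 2, 0.2)
  # small brute-force oracle
  a <- matrix(sample(0:3, 64, TRUE), 8, 8) * 60
  f <- matrix(sample(0:3, 64, TRUE), 8, 8) * 60
  tab <- table(factor(floor(a), levels = 0:255), factor(floor(f), levels = 0:255))
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  mi <- 0
  for (i in seq_len(256)) for (j in seq_len(256)) {
    if (p[i, j] > 0) mi <- mi + p[i, j] * log2(p[i, j] / (px[i] * py[j]))
  }
  expect_equal(nsctfuse:::mi_one(a, f), as.numeric(mi), tolerance = 1e-10)
})

test_that("MI between an image and the fused image never exceeds either entropy", {
  for (s in 1:5) {
    A <- floor(rand_image(32, seed = 300 + s))
    F <- floor(nsctfuse:::gaussian_blur(A, 1))
    mi <- nsctfuse:::mi_one(A, F)
    expect_lte(mi, information_entropy(A) + 1e-10)
    expect_lte(mi, information_entropy(F) + 1e-10)
  }
})

test_that("spectral-angle average matches a per-block oracle and its bounds", {
  X <- rand_image(32, seed = 10)
  expect_lt(esam_ae(X, X, 16), 1e-5)
  x <- matrix(0, 16, 16); x[1, 1] <- 1
  y <- matrix(0, 16, 16); y[2, 1] <- 1
  expect_equal(esam_ae(x, y, 16), 90)
  F <- rand_image(32, seed = 11)
  got <- esam_ae(X, F, 16)
  angles <- c()
  for (i in 0:1) for (j in 0:1) {
    xb <- as.vector(X[(i * 16 + 1):(i * 16 + 16), (j * 16 + 1):(j * 16 + 16)])
    fb <- as.vector(F[(i * 16 + 1):(i * 16 + 16), (j * 16 + 1):(j * 16 + 16)])
    angles <- c(angles, acos(sum(xb * fb) / sqrt(sum(xb^2) * sum(fb^2))) * 180 / pi)
  }
  expect_equal(got, mean(angles), tolerance = 1e-10)
  expect_true(got >= 0 && got <= 90)
  expect_error(esam_ae(X, F, 64), "window_size")
})

test_that("metrics are invariant to joint transposition", {
  A <- rand_image(24, 32, seed = 12); B <- rand_image(24, 32, seed = 13)
  F <- (A + B) / 2
  expect_equal(information_entropy(t(F)), information_entropy(F))
  expect_equal(standard_deviation(t(F)), standard_deviation(F))
  expect_equal(average_gradient(t(F)), average_gradient(F))
  expect_equal(psnr_pair(t(A), t(B), t(F)), psnr_pair(A, B, F))
  expect_equal(mutual_information(t(A), t(B), t(F)),
               mutual_information(A, B, F))
  expect_equal(q_index(t(A), t(B), t(F)), q_index(A, B, F), tolerance = 1e-10)
})

test_that("the full metrics report is complete, finite, and in range", {
  A <- make_base_scene(scene_spec(seed = 15))
  B <- make_base_scene(scene_spec(seed = 16))
  F <- pmin(pmax((A + B) / 2, 0), 255)
  rep <- fusion_metrics(A, B, F, esam_windows = c(16L, 32L))
  expect_identical(nrow(rep), 1L)
  expect_true(all(vapply(rep, is.finite, logical(1))))
  expect_true(rep$ie >= 0 && rep$ie <= 8)
  expect_true(rep$q_index >= 0 && rep$q_index <= 1)
  expect_true(all(c("ae_a_16", "ae_b_16", "ae_a_32", "ae_b_32") %in% names(rep)))
})

test_that("Q index stays within [0, 1] across random triples", {
  for (s in 1:20) {
    A <- rand_image(16, seed = 400 + s); B <- rand_image(16, seed = 500 + s)
    F <- rand_image(16, seed = 600 + s)
    q <- q_index(A, B, F)
    expect_true(q >= 0 && q <= 1)
  }
})
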