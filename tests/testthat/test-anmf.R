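# Accelerated NMF: objectives, update rules, line-search step lengths,
# and the full solver's convergence/monotonicity guarantees.

test_that("Euclidean objective matches its definition", {
  W <- matrix(c(1, 2, 3), 3, 1); H <- matrix(c(1, 2), 1, 2)
  expect_identical(euclid_objective(W %*% H, W, H), 0)
  expect_identical(euclid_objective(matrix(2), matrix(1), matrix(1)), 1)
  set.seed(7)
  V <- matrix(runif(12), 3, 4); W <- matrix(runif(6), 3, 2)
  H <- matrix(runif(8), 2, 4)
  brute <- 0
  R <- W %*% H
  for (i in 1:3) for (j in 1:4) brute <- brute + (V[i, j] - R[i, j])^2
  expect_equal(euclid_objective(V, W, H), brute)
  expect_error(euclid_objective(V, W, t(H)), "conformable")
})

test_that("KL objective matches its definition and flags its domain", {
  W <- matrix(c(1, 2), 2, 1); H <- matrix(c(1, 3), 1, 2)
  expect_equal(kl_objective(W %*% H, W, H), 0)
  expect_equal(kl_objective(matrix(0), matrix(1), matrix(3)), 3)
  set.seed(8)
  V <- matrix(runif(6, 0.1, 2), 2, 3)
  W <- matrix(runif(4, 0.1, 1), 2, 2); H <- matrix(runif(6, 0.1, 1), 2, 3)
  R <- W %*% H
  brute <- sum(V * log(V / R) - V + R)
  expect_equal(kl_objective(V, W, H), brute)
  expect_error(kl_objective(matrix(1), matrix(0), matrix(0)), "undefined")
})

test_that("Lee-Seung step fixes exact factorizations and kills zero rows", {
  set.seed(3)
  W <- matrix(runif(10, 0.5, 1), 5, 2); H <- matrix(runif(8, 0.5, 1), 2, 4)
  V <- W %*% H
  st <- lee_seung_step(V, W, H)
  expect_equal(st$H, H, tolerance = 1e-8)
  expect_equal(st$W, W, tolerance = 1e-8)

  V2 <- V; V2[2, ] <- 0
  st2 <- st
  for (k in 1:50) st2 <- lee_seung_step(V2, st2$W, st2$H)
  expect_true(all(st2$W >= 0) && all(st2$H >= 0))
  expect_lt(max(st2$W[2, ]), 1e-3)
})

test_that("Lee-Seung step agrees with a literal multiplicative oracle", {
  set.seed(12)
  V <- matrix(runif(20, 0.1, 5), 5, 4)
  W <- matrix(runif(10, 0.1, 1), 5, 2); H <- matrix(runif(8, 0.1, 1), 2, 4)
  st <- lee_seung_step(V, W, H)
  or <- lee_seung_oracle(V, W, H)
  expect_equal(st$H, or$H, tolerance = 1e-6)
  expect_equal(st$W, or$W, tolerance = 1e-6)
  # and the objective does not increase
  expect_lte(euclid_objective(V, st$W, st$H),
             euclid_objective(V, W, H) * (1 + 1e-10))
})

test_that("line-search step length reproduces scalar worked cases", {
  A <- matrix(1, 1, 1)
  expect_equal(tnnls_step(A, 2, 1), 1, tolerance = 1e-6)
  expect_equal(tnnls_step(A, 0, 1, tau = 0.99), 0.99, tolerance = 1e-6)
  expect_identical(tnnls_step(A, 1, 1), 1)   # stationary point
})

test_that("vectorized column step lengths agree with the scalar routine", {
  set.seed(21)
  W <- matrix(runif(30, 0.1, 1), 10, 3)
  V <- matrix(runif(50, 0.1, 2), 10, 5)
  H <- matrix(runif(15, 0.1, 1), 3, 5)
  WtW <- crossprod(W)
  G <- crossprod(W, V) - WtW %*% H
  al <- nsctfuse:::tnnls_steps_cols(WtW, H, G, 0.99, 1e-9)
  for (j in 1:5) {
    expect_equal(al[j], tnnls_step(W, V[, j], H[, j], 0.99, 1e-9, AtA = WtW),
                 tolerance = 1e-12)
  }
})

test_that("accelerated H update reduces to the Lee-Seung half at unit steps", {
  set.seed(30)
  V <- matrix(runif(30, 0.1, 2), 6, 5)
  W <- matrix(runif(12, 0.1, 1), 6, 2); H <- matrix(runif(10, 0.1, 1), 2, 5)
  cfg1 <- anmf_config(force_unit_steps = TRUE)
  Hunit <- anmf_update_H(V, W, H, cfg1)
  D <- crossprod(W) %*% H
  Hls <- pmax(H + H / (D + cfg1$eps_guard) * (crossprod(W, V) - D), 0)
  expect_identical(Hunit, Hls)

  # exact factorization: gradient is zero, H unchanged
  Vx <- W %*% H
  expect_equal(anmf_update_H(Vx, W, H, anmf_config()), H, tolerance = 1e-6)
})

test_that("accelerated H update beats a plain Lee-Seung H-step per column", {
  for (s in 1:5) {
    set.seed(40 + s)
    V <- matrix(runif(30, 0.1, 2), 6, 5)
    W <- matrix(runif(12, 0.1, 1), 6, 2); H <- matrix(runif(10, 0.1, 1), 2, 5)
    cfg <- anmf_config()
    Ha <- anmf_update_H(V, W, H, cfg)
    D <- crossprod(W) %*% H
    Hls <- pmax(H + H / (D + cfg$eps_guard) * (crossprod(W, V) - D), 0)
    obj_a <- colSums((V - W %*% Ha)^2)
    obj_l <- colSums((V - W %*% Hls)^2)
    expect_true(all(obj_a <= obj_l * (1 + 1e-10)))
  }
})

test_that("W update mirrors the transposed H update", {
  set.seed(50)
  V <- matrix(runif(30, 0.1, 2), 6, 5)
  W <- matrix(runif(12, 0.1, 1), 6, 2); H <- matrix(runif(10, 0.1, 1), 2, 5)
  cfg <- anmf_config()
  expect_equal(anmf_update_W(V, W, H, cfg),
               t(anmf_update_H(t(V), t(H), t(W), cfg)), tolerance = 1e-12)
})

test_that("solver drives an exactly rank-1 matrix to zero objective", {
  set.seed(60)
  w <- runif(30, 0.5, 2); h <- runif(8, 0.5, 2)
  V <- outer(w, h)
  fit <- anmf_factorize(V, 1L, anmf_config(max_iter = 200, tol = 0, seed = 1))
  expect_lt(fit$objective_trace[length(fit$objective_trace)],
            1e-8 * sum(V^2))
})

test_that("solver is deterministic, nonnegative, and validates inputs", {
  set.seed(61)
  V <- matrix(runif(200), 20, 10)
  cfg <- anmf_config(max_iter = 50, tol = 0, seed = 9)
  f1 <- anmf_factorize(V, 3L, cfg)
  f2 <- anmf_factorize(V, 3L, cfg)
  expect_identical(f1$objective_trace, f2$objective_trace)
  expect_identical(f1$W, f2$W)
  expect_true(all(f1$W >= 0) && all(f1$H >= 0))
  expect_error(anmf_factorize(-V, 3L), "nonnegative")
  expect_error(anmf_factorize(V, 10L), "rank")
})

test_that("objective trace is non-increasing across seeds and inits", {
  for (s in 1:6) {
    set.seed(70 + s)
    V <- matrix(runif(30 * 20), 30, 20)
    for (init in c("data-mean", "random-uniform")) {
      fit <- anmf_factorize(V, 4L, anmf_config(max_iter = 60, tol = 0,
                                               seed = s, init = init))
      expect_true(all(diff(fit$objective_trace) <=
                        1e-10 * fit$objective_trace[1]))
    }
  }
})

test_that("early stopping honors the relative-change tolerance", {
  set.seed(80)
  w <- runif(25, 0.5, 2); h <- runif(6, 0.5, 2)
  fit <- anmf_factorize(outer(w, h), 1L,
                        anmf_config(max_iter = 1000, tol = 1e-6, seed = 2))
  expect_lt(fit$iterations_run, 1000)
  expect_length(fit$objective_trace, fit$iterations_run + 1)
})

test_that("tidy and glance summarize a fit", {
  set.seed(81)
  V <- matrix(runif(60), 10, 6)
  fit <- anmf_factorize(V, 2L, anmf_config(max_iter = 20, tol = 0, seed = 3))
  td <- generics::tidy(fit)
  expect_identical(nrow(td), 21L)
  expect_identical(td$objective, fit$objective_trace)
  gl <- generics::glance(fit)
  expect_identical(gl$method, "anmf")
  expect_identical(gl$iterations, 20L)
})
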