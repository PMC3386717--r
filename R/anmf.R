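# Accelerated non-negative matrix factorization. The classic Lee-Seung
# multiplicative update is a diagonally scaled gradient step of length 1;
# here each column of H (and row of W) instead takes a step length from a
# nonnegative least-squares line search along the same scaled-gradient
# direction, truncated at a tau-fraction of the distance to the nonnegative
# boundary. A per-column/per-row fallback to step length 1 keeps the
# objective non-increasing by construction.

#' Configuration for the accelerated NMF solver
#'
#' @param tau Boundary safety fraction in (0, 1) for the line-search step;
#'   the step never exceeds `tau` times the distance to the nonnegative
#'   orthant boundary. Default 0.99.
#' @param max_iter Maximum number of alternating H/W iterations. Default 1000.
#' @param tol Relative objective-change stopping threshold; set to 0 to run
#'   all `max_iter` iterations. Default 1e-6.
#' @param eps_guard Small positive additive guard for denominators.
#'   Default 1e-9.
#' @param seed Integer seed used for initialization (jitter / random init).
#' @param init Initialization scheme: `"data-mean"` (columns of W set to the
#'   mean of V's columns plus 1% seeded jitter, H by least squares clipped at
#'   zero) or `"random-uniform"`.
#' @param force_unit_steps If `TRUE`, skip the line search and use step
#'   length 1 everywhere; the iteration then reproduces the Lee-Seung trace
#'   exactly.
#' @return An object of class `anmf_config`.
#' @export
anmf_config <- function(tau = 0.99, max_iter = 1000L, tol = 1e-6,
                        eps_guard = 1e-9, seed = 1L,
                        init = c("data-mean", "random-uniform"),
                        force_unit_steps = FALSE) {
  if (!(tau > 0 && tau < 1)) stop("`tau` must lie in (0, 1)", call. = FALSE)
  if (max_iter < 1L) stop("`max_iter` must be >= 1", call. = FALSE)
  if (eps_guard <= 0) stop("`eps_guard` must be positive", call. = FALSE)
  if (tol < 0) stop("`tol` must be >= 0", call. = FALSE)
  structure(list(tau = tau, max_iter = as.integer(max_iter), tol = tol,
                 eps_guard = eps_guard, seed = seed, init = match.arg(init),
                 force_unit_steps = isTRUE(force_unit_steps)),
            class = "anmf_config")
}

assert_nonneg <- function(x, arg = deparse(substitute(x))) {
  if (any(x < 0)) stop(sprintf("`%s` must be nonnegative", arg), call. = FALSE)
  invisible(x)
}

#' Squared Frobenius objective of a factorization
#'
#' `sum((V - W %*% H)^2)`, the Euclidean-distance NMF objective.
#'
#' @param V,W,H Nonnegative matrices with conformable shapes.
#' @return A nonnegative scalar.
#' @export
euclid_objective <- function(V, W, H) {
  if (nrow(W) != nrow(V) || ncol(H) != ncol(V) || ncol(W) != nrow(H)) {
    stop("shapes not conformable for V ~ W %*% H", call. = FALSE)
  }
  sum((V - W %*% H)^2)
}

#' Generalized Kullback-Leibler objective of a factorization
#'
#' `sum(V * log(V / WH) - V + WH)` with the convention `0 * log 0 = 0`.
#' Provided as a diagnostic; the solver minimizes [euclid_objective()].
#'
#' @inheritParams euclid_objective
#' @return A nonnegative scalar.
#' @export
kl_objective <- function(V, W, H) {
  if (nrow(W) != nrow(V) || ncol(H) != ncol(V) || ncol(W) != nrow(H)) {
    stop("shapes not conformable for V ~ W %*% H", call. = FALSE)
  }
  R <- W %*% H
  if (any(R == 0 & V > 0)) {
    stop("KL divergence undefined: (WH)_ij = 0 where V_ij > 0", call. = FALSE)
  }
  pos <- V > 0
  sum(V[pos] * log(V[pos] / R[pos])) - sum(V) + sum(R)
}

#' One Lee-Seung update of both factors
#'
#' The scaled-gradient (equivalently multiplicative) update:
#' `H <- H + eta * (W'V - W'WH)` with `eta = H / (W'WH + eps_guard)`, then
#' the mirrored update of `W` using the new `H`. Results are clipped at zero
#' against floating-point underflow. The Euclidean objective does not
#' increase.
#'
#' @inheritParams euclid_objective
#' @param eps_guard Additive denominator guard.
#' @return `list(W = , H = )`.
#' @export
lee_seung_step <- function(V, W, H, eps_guard = 1e-9) {
  assert_nonneg(V); assert_nonneg(W); assert_nonneg(H)
  WtV <- crossprod(W, V)
  D <- crossprod(W) %*% H
  H <- pmax(H + H / (D + eps_guard) * (WtV - D), 0)
  VHt <- tcrossprod(V, H)
  Dw <- W %*% tcrossprod(H)
  W <- pmax(W + W / (Dw + eps_guard) * (VHt - Dw), 0)
  list(W = W, H = H)
}

#' Line-search step length for a totally nonnegative least-squares problem
#'
#' For `min ||A x - b||^2` with `A, b, x >= 0`, the search direction is the
#' diagonally scaled negative gradient `p = (x / (A'A x)) * q` with
#' `q = A'(b - A x)`. The step is the smaller of the exact quadratic
#' minimizer along `p` and `tau` times the largest step keeping `x + a p`
#' nonnegative (infinite when `p >= 0`). At a stationary point (`q = 0`)
#' the step is 1.
#'
#' @param A Nonnegative matrix. @param b,x Nonnegative vectors; components of
#'   `x` below `eps_guard` are treated as `eps_guard` in the scaling.
#' @param tau Boundary fraction in (0, 1).
#' @param eps_guard Denominator guard.
#' @param AtA Optional precomputed `crossprod(A)`.
#' @return A positive scalar step length.
#' @export
tnnls_step <- function(A, b, x, tau = 0.99, eps_guard = 1e-9, AtA = NULL) {
  assert_nonneg(A); assert_nonneg(b); assert_nonneg(x)
  if (is.null(AtA)) AtA <- crossprod(A)
  q <- crossprod(A, b - A %*% x)
  if (all(q == 0)) return(1)
  xg <- pmax(x, eps_guard)
  d <- AtA %*% x
  p <- (xg / (d + eps_guard)) * q
  curv <- sum(p * (AtA %*% p))
  neg <- p < 0
  boundary <- if (any(neg)) tau * min(xg[neg] / (-p[neg])) else Inf
  if (curv <= 0) {
    if (!is.finite(boundary)) return(1)
    return(boundary)
  }
  min(sum(p * q) / curv, boundary)
}

# Vectorized tnnls step lengths for all columns of the subproblem
# min ||V - W H||^2: Q = W'V - W'W H is the per-column negative gradient.
# Returns one step length per column.
tnnls_steps_cols <- function(AtA, X, Q, tau, eps_guard) {
  Xg <- pmax(X, eps_guard)
  D <- AtA %*% X
  P <- (Xg / (D + eps_guard)) * Q
  curv <- colSums(P * (AtA %*% P))
  pq <- colSums(P * Q)
  ratio <- ifelse(P < 0, Xg / (-P), Inf)
  boundary <- tau * apply(ratio, 2, min)
  alpha <- ifelse(curv > 0, pmin(pq / curv, boundary),
                  ifelse(is.finite(boundary), boundary, 1))
  alpha[colSums(Q != 0) == 0] <- 1   # stationary columns
  alpha
}

#' Accelerated update of the coefficient matrix H
#'
#' Each column `j` of `H` moves along its scaled negative gradient with the
#' [tnnls_step()] step length `alpha_j`; columns whose sub-objective would
#' increase fall back to `alpha_j = 1` (the Lee-Seung step, which cannot
#' increase it). With all `alpha_j = 1` the update is exactly
#' [lee_seung_step()]'s H-half.
#'
#' @inheritParams euclid_objective
#' @param config An [anmf_config()].
#' @return The updated `H`.
#' @export
anmf_update_H <- function(V, W, H, config = anmf_config()) {
  WtV <- crossprod(W, V)
  WtW <- crossprod(W)
  D <- WtW %*% H
  G <- WtV - D
  S <- H / (D + config$eps_guard) * G
  if (config$force_unit_steps) {
    return(pmax(H + S, 0))
  }
  alpha <- tnnls_steps_cols(WtW, H, G, config$tau, config$eps_guard)
  Hc <- pmax(H + S * rep(alpha, each = nrow(H)), 0)
  # fallback: any column whose objective rose reverts to the unit step
  R0 <- V - W %*% H
  Rc <- V - W %*% Hc
  bad <- colSums(Rc^2) > colSums(R0^2)
  if (any(bad)) {
    H1 <- pmax(H + S, 0)
    Hc[, bad] <- H1[, bad]
  }
  Hc
}

#' Accelerated update of the basis matrix W
#'
#' Row-wise mirror of [anmf_update_H()]: row `i` of `W` solves the transposed
#' subproblem with design `t(H)`, step length `beta_i`, and the same
#' fallback to the Lee-Seung step.
#'
#' @inheritParams anmf_update_H
#' @return The updated `W`.
#' @export
anmf_update_W <- function(V, W, H, config = anmf_config()) {
  VHt <- tcrossprod(V, H)          # M x L
  HHt <- tcrossprod(H)             # L x L
  D <- W %*% HHt
  G <- VHt - D
  S <- W / (D + config$eps_guard) * G
  if (config$force_unit_steps) {
    return(pmax(W + S, 0))
  }
  # transposed view: columns of t(W) are the row subproblems
  beta <- tnnls_steps_cols(HHt, t(W), t(G), config$tau, config$eps_guard)
  Wc <- pmax(W + S * beta, 0)      # beta recycles down rows
  R0 <- V - W %*% H
  Rc <- V - Wc %*% H
  bad <- rowSums(Rc^2) > rowSums(R0^2)
  if (any(bad)) {
    W1 <- pmax(W + S, 0)
    Wc[bad, ] <- W1[bad, ]
  }
  Wc
}

# Shared initialization so accelerated and plain runs start identically.
nmf_init <- function(V, L, config) {
  M <- nrow(V); N <- ncol(V)
  with_seed(config$seed, {
    if (config$init == "random-uniform") {
      W <- matrix(runif(M * L), M, L)
      H <- matrix(runif(L * N), L, N)
    } else {
      m <- rowMeans(V)
      W <- matrix(m, M, L) * (1 + 0.01 * matrix(runif(M * L), M, L))
      H <- tryCatch(qr.coef(qr(W), V), error = function(e) NULL)
      if (is.null(H) || any(!is.finite(H))) {
        H <- matrix(1 / L, L, N)
      }
      H <- pmax(H, 0)
    }
    list(W = W, H = H)
  })
}

nmf_iterate <- function(V, L, config, accelerated) {
  assert_nonneg(V)
  M <- nrow(V); N <- ncol(V)
  if ((M + N) * L >= M * N) {
    stop("rank L too large: need (M + N) * L < M * N", call. = FALSE)
  }
  st <- nmf_init(V, L, config)
  W <- st$W; H <- st$H
  trace <- numeric(config$max_iter + 1L)
  trace[1L] <- euclid_objective(V, W, H)
  it <- 0L
  for (k in seq_len(config$max_iter)) {
    if (accelerated) {
      H <- anmf_update_H(V, W, H, config)
      W <- anmf_update_W(V, W, H, config)
    } else {
      st <- lee_seung_step(V, W, H, config$eps_guard)
      W <- st$W; H <- st$H
    }
    it <- k
    trace[k + 1L] <- euclid_objective(V, W, H)
    if (config$tol > 0) {
      rel <- abs(trace[k] - trace[k + 1L]) / max(trace[1L], .Machine$double.eps)
      if (rel < config$tol) break
    }
  }
  structure(list(W = W, H = H, objective_trace = trace[seq_len(it + 1L)],
                 iterations_run = it, rank = L,
                 method = if (accelerated) "anmf" else "lee-seung",
                 config = config),
            class = "anmf_fit")
}

#' Accelerated non-negative matrix factorization
#'
#' Alternates the accelerated column-wise H update and row-wise W update,
#' recording the Euclidean objective each iteration (element 1 of the trace
#' is the objective at initialization). The per-column/per-row fallback
#' makes the trace non-increasing. With `config$force_unit_steps = TRUE`
#' the run coincides with [lee_seung_factorize()] exactly.
#'
#' @param V Nonnegative data matrix (columns are observations).
#' @param L Factorization rank; must satisfy `(M + N) * L < M * N`.
#' @param config An [anmf_config()].
#' @return An `anmf_fit`: `W` (M x L), `H` (L x N), `objective_trace`,
#'   `iterations_run`, `method`, `config`.
#' @export
anmf_factorize <- function(V, L, config = anmf_config()) {
  nmf_iterate(V, L, config, accelerated = TRUE)
}

#' Classic Lee-Seung factorization (comparison baseline)
#'
#' Same initialization, objective bookkeeping and stopping rule as
#' [anmf_factorize()], but with plain unit-step multiplicative updates.
#'
#' @inheritParams anmf_factorize
#' @return An `anmf_fit` with `method = "lee-seung"`.
#' @export
lee_seung_factorize <- function(V, L, config = anmf_config()) {
  nmf_iterate(V, L, config, accelerated = FALSE)
}

#' @export
print.anmf_fit <- function(x, ...) {
  cat(sprintf("<anmf_fit> method=%s rank=%d iterations=%d objective=%.6g\n",
              x$method, x$rank, x$iterations_run,
              x$objective_trace[length(x$objective_trace)]))
  invisible(x)
}

#' Tidy the objective trace of a factorization
#'
#' @param x An `anmf_fit`.
#' @param ... Unused.
#' @return A tibble with columns `iteration` (0 = initialization) and
#'   `objective`.
#' @exportS3Method generics::tidy
tidy.anmf_fit <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$objective_trace) - 1L,
                 objective = x$objective_trace)
}

#' One-row summary of a factorization
#'
#' @param x An `anmf_fit`.
#' @param ... Unused.
#' @return A one-row tibble: method, rank, iterations, initial and final
#'   objective.
#' @exportS3Method generics::glance
glance.anmf_fit <- function(x, ...) {
  tibble::tibble(method = x$method, rank = x$rank,
                 iterations = x$iterations_run,
                 objective_initial = x$objective_trace[1L],
                 objective_final = x$objective_trace[length(x$objective_trace)])
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
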