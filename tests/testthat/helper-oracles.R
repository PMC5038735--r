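# Independent oracle code used across the suite.  These re-derive the
# quantities the package computes through a different route (direct
# formulas, generic solvers, first-order convex optimization) and must not
# call the solver internals they check.

# Closed-form ridge regression with intercept by centering.
ridge_oracle <- function(X, Y, lambda) {
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  Yc <- Y - mean(Y)
  w <- drop(qr.solve(crossprod(Xc) + lambda * diag(ncol(X)),
                     crossprod(Xc, Yc)))
  list(w = w, b = mean(Y) - sum(mu * w))
}

# Random multi-trial regression instance on the score scale.
rand_instance <- function(N, D, m, seed) {
  withr::with_seed(seed, {
    Xs <- replicate(m, matrix(rnorm(N * D), N, D), simplify = FALSE)
    Y <- pmin(pmax(rnorm(N, 70, 8), 0), 100)
    multitrial_dataset(Xs, Y)
  })
}

# First-order convex solver (FISTA with singular-value thresholding) of
#   min_W sum_i ||Xc_i w_i - Yc||^2 + lambda ||W||_F^2 + gamma ||W||_*
# with the biases eliminated analytically by centering.  Independent of the
# package's iteratively-reweighted closed-form path.
fista_oracle <- function(Xs, Y, lambda, gamma, max_iter = 20000,
                         tol = 1e-12) {
  m <- length(Xs)
  D <- ncol(Xs[[1]])
  Xc <- lapply(Xs, function(X) sweep(X, 2, colMeans(X)))
  Yc <- Y - mean(Y)
  L <- 2 * (max(vapply(Xc, function(X) svd(X, nu = 0, nv = 0)$d[1],
                       numeric(1)))^2 + lambda)
  W <- Z <- matrix(0, D, m)
  tk <- 1
  obj <- function(W) {
    sum(vapply(seq_len(m), function(i) sum((Xc[[i]] %*% W[, i] - Yc)^2),
               numeric(1))) +
      lambda * sum(W^2) + gamma * sum(svd(W, nu = 0, nv = 0)$d)
  }
  o_prev <- obj(W)
  for (it in seq_len(max_iter)) {
    G <- vapply(seq_len(m), function(i) {
      drop(2 * (crossprod(Xc[[i]], Xc[[i]] %*% Z[, i] - Yc) +
                  lambda * Z[, i]))
    }, numeric(D))
    V <- Z - matrix(G, D, m) / L
    sv <- svd(V)
    dth <- pmax(sv$d - gamma / L, 0)
    W_new <- sv$u %*% (t(sv$v) * dth)
    t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    Z <- W_new + ((tk - 1) / t_new) * (W_new - W)
    W <- W_new
    tk <- t_new
    if (it %% 50 == 0) {
      o <- obj(W)
      if (abs(o_prev - o) / max(1, o) < tol) break
      o_prev <- o
    }
  }
  b <- vapply(seq_len(m), function(i) mean(Y - drop(Xs[[i]] %*% W[, i])),
              numeric(1))
  list(W = W, b = b, iterations = it)
}

final_objective <- function(fit) {
  fit$objective_trace[length(fit$objective_trace)]
}

is_monotone_trace <- function(tr, slack = 1e-9) {
  all(diff(tr) <= slack * pmax(1, abs(tr[-length(tr)])))
}
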