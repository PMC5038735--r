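test_that("nuclear norm matches singular-value sums and rejects bad input", {
  expect_equal(nuclear_norm(diag(c(3, 4))), 7)
  expect_equal(nuclear_norm(matrix(0, 3, 2)), 0)
  W <- withr::with_seed(11, matrix(rnorm(12), 4, 3))
  # independent route: singular values via the eigenvalues of W'W
  expect_equal(nuclear_norm(W),
               sum(sqrt(pmax(eigen(crossprod(W))$values, 0))),
               tolerance = 1e-12)
  expect_error(nuclear_norm(matrix(c(1, NA), 1, 2)), "non-finite")
})

test_that("trace surrogate converges to the nuclear norm as delta -> 0", {
  expect_equal(trace_surrogate(matrix(0, 4, 2), 0.5), 0)
  expect_equal(trace_surrogate(diag(c(3, 4)), 1e-12), 7, tolerance = 1e-5)
  W <- withr::with_seed(21, matrix(rnorm(15), 5, 3))
  expect_equal(trace_surrogate(W, 1e-10), nuclear_norm(W), tolerance = 1e-4)
  expect_error(trace_surrogate(W, 0), "positive")
  expect_error(trace_surrogate(W, -1), "positive")
})

test_that("reweighting matrix is the half inverse square root of WW^T", {
  D <- 3
  expect_equal(reweight_matrix(diag(D), delta = 1e-12), diag(D) / 2,
               tolerance = 1e-6)
  expect_equal(reweight_matrix(matrix(2, 1, 1), delta = 1e-12),
               matrix(0.25, 1, 1), tolerance = 1e-6)
  W <- withr::with_seed(31, matrix(rnorm(12), 3, 4))
  M <- reweight_matrix(W, delta = 1e-8)
  expect_equal(M, t(M))
  # defining identity: (2M)^(-2) = WW^T + delta I
  expect_equal(solve((2 * M) %*% (2 * M)),
               tcrossprod(W) + 1e-8 * diag(3), tolerance = 1e-6)
})

test_that("weight update solves the regularized normal equations", {
  N <- 4
  Y <- c(2, -1, 4, 0.5)
  # X = I, lambda = 1, gamma = 0: (I + I)^{-1} Y = Y / 2
  expect_equal(solve_trial_weights(diag(N), Y, b = 0, Dr = diag(N),
                                   lambda = 1, gamma = 0), Y / 2)
  # penalty-free limit is ordinary least squares
  X <- withr::with_seed(41, matrix(rnorm(20 * 3), 20, 3))
  Y2 <- withr::with_seed(42, rnorm(20))
  w_ols <- solve_trial_weights(X, Y2, b = 0, Dr = diag(3),
                               lambda = 0, gamma = 0)
  expect_equal(w_ols, unname(coef(lm(Y2 ~ X - 1))), tolerance = 1e-10,
               ignore_attr = TRUE)
  # generic-linear-solver oracle with both penalties active
  Dr <- reweight_matrix(withr::with_seed(43, matrix(rnorm(9), 3, 3)))
  b <- 0.7
  w2 <- solve_trial_weights(X, Y2, b = b, Dr = Dr, lambda = 1, gamma = 1)
  w2_or <- qr.solve(crossprod(X) + diag(3) + Dr, crossprod(X, Y2 - b))
  expect_equal(w2, drop(w2_or), tolerance = 1e-10)
  # stationarity residual of the returned solution
  resid <- (crossprod(X) + diag(3) + Dr) %*% w2 - crossprod(X, Y2 - b)
  expect_lt(max(abs(resid)), 1e-8 * max(1, max(abs(w2))))
  # rank-deficient unpenalized system errors, naming the trial
  Xs <- cbind(1:4, 1:4)
  expect_error(
    solve_trial_weights(Xs, Y, b = 0, Dr = diag(2), lambda = 0, gamma = 0,
                        trial = "trial_03"),
    "trial_03")
})

test_that("bias update is the residual mean", {
  X <- withr::with_seed(51, matrix(rnorm(12), 6, 2))
  Y <- withr::with_seed(52, rnorm(6))
  expect_equal(solve_trial_bias(X, Y, c(0, 0)), mean(Y))
  w <- c(1.5, -2)
  expect_equal(solve_trial_bias(X, drop(X %*% w), w), 0)
  expect_equal(solve_trial_bias(X, Y, w), mean(Y - X %*% w))
})

test_that("objective matches a term-by-term independent computation", {
  d <- rand_instance(5, 2, 2, seed = 61)
  Y <- unname(d$scores)
  # zero model, no penalties: pure residual term m * ||Y||^2
  expect_equal(mtjl_objective(d, matrix(0, 2, 2), c(0, 0), 0, 0), 2 * sum(Y^2))
  W <- withr::with_seed(62, matrix(rnorm(4), 2, 2))
  b <- c(0.5, -1)
  direct <- sum(vapply(1:2, function(i) {
    sum((d$trials[[i]] %*% W[, i] + b[i] - Y)^2)
  }, numeric(1))) + sum(W^2) + trace_surrogate(W, 1e-8)
  expect_equal(mtjl_objective(d, W, b, lambda = 1, gamma = 1), direct,
               tolerance = 1e-12)
  expect_error(mtjl_objective(d, matrix(0, 3, 2), c(0, 0), 1, 1), "D x m")
})

test_that("gamma = 0 decouples into per-trial ridge solutions", {
  d <- rand_instance(25, 4, 3, seed = 71)
  fit <- mtjl_fit(d, mtjl_control(lambda = 2, gamma = 0), normalize = "none")
  for (i in 1:3) {
    or <- ridge_oracle(unname(d$trials[[i]]), unname(d$scores), lambda = 2)
    expect_equal(unname(fit$W[, i]), or$w, tolerance = 1e-8)
    expect_equal(unname(fit$b[i]), or$b, tolerance = 1e-8)
  }
})

test_that("single-trial fit equals the centered ridge-with-intercept oracle", {
  d <- rand_instance(30, 5, 1, seed = 81)
  fit <- mtjl_fit(d, mtjl_control(lambda = 1, gamma = 0), normalize = "none")
  or <- ridge_oracle(unname(d$trials[[1]]), unname(d$scores), lambda = 1)
  expect_equal(unname(fit$W[, 1]), or$w, tolerance = 1e-8)
  expect_equal(unname(fit$b[1]), or$b, tolerance = 1e-8)
})

test_that("objective trace is non-increasing and the fit is stationary", {
  for (seed in c(91, 92, 93)) {
    d <- rand_instance(20, 4, 5, seed = seed)
    for (init in c("ridge", "zeros")) {
      fit <- mtjl_fit(d, mtjl_control(lambda = 1, gamma = 1, init = init),
                      normalize = "none")
      expect_true(is_monotone_trace(fit$objective_trace))
      expect_true(fit$converged)
      # re-applying the closed-form updates must not move a fully
      # converged fit (tight tolerance so the fixed point is reached)
      fit <- mtjl_fit(d, mtjl_control(lambda = 1, gamma = 1, init = init,
                                      tol = 1e-13, max_iter = 3000),
                      normalize = "none")
      Dr <- reweight_matrix(fit$W, fit$control$delta)
      Y <- unname(d$scores)
      for (i in 1:5) {
        Xi <- unname(d$trials[[i]])
        w_new <- solve_trial_weights(Xi, Y, fit$b[i], Dr, 1, 1)
        expect_lt(max(abs(w_new - fit$W[, i])), 1e-6)
        expect_lt(abs(solve_trial_bias(Xi, Y, fit$W[, i]) - fit$b[i]), 1e-6)
      }
    }
  }
})

test_that("feature permutation permutes weights and leaves predictions fixed", {
  d <- rand_instance(20, 5, 3, seed = 101)
  perm <- c(4, 1, 5, 3, 2)
  d_perm <- multitrial_dataset(lapply(d$trials, function(X) X[, perm]),
                               d$scores,
                               feature_names = d$feature_names[perm])
  ctl <- mtjl_control(lambda = 1, gamma = 1)
  f1 <- mtjl_fit(d, ctl, normalize = "none")
  f2 <- mtjl_fit(d_perm, ctl, normalize = "none")
  expect_equal(unname(f2$W), unname(f1$W[perm, ]), tolerance = 1e-10)
  expect_equal(predict(f2, d_perm)$.pred, predict(f1, d)$.pred,
               tolerance = 1e-10)
})

test_that("noiseless low-rank truth is recovered almost exactly", {
  cfg <- cohort_config(n_participants = 200, n_trials = 8, n_features = 6,
                       true_rank = 2, noise_sd = 0)
  sim <- simulate_cohort(cfg, seed = 111, raw = FALSE)
  fit <- mtjl_fit(sim$data, mtjl_control(lambda = 1e-6, gamma = 1e-6),
                  normalize = "none")
  W_eff <- fit$W / sim$truth$score_scale
  expect_lt(norm(W_eff - sim$truth$W_star, "F") /
              norm(sim$truth$W_star, "F"), 0.01)
  # exact-fit limit: predictions reproduce the true scores
  pred <- predict(fit, sim$data)
  expect_equal(pred$.pred, unname(sim$data$scores), tolerance = 1e-6)
})

test_that("prediction is the mean of per-trial affine maps", {
  d <- rand_instance(8, 3, 4, seed = 121)
  fit <- mtjl_fit(d, mtjl_control(), normalize = "none")
  # constant model predicts the constant
  const <- fit
  const$W[] <- 0
  const$b[] <- 42
  expect_equal(predict(const, d)$.pred, rep(42, 8))
  # hand-computed aggregation
  manual <- rowMeans(vapply(1:4, function(i) {
    drop(unname(d$trials[[i]]) %*% fit$W[, i]) + fit$b[i]
  }, numeric(8)))
  expect_equal(predict(fit, d)$.pred, manual, tolerance = 1e-12)
  med <- apply(vapply(1:4, function(i) {
    drop(unname(d$trials[[i]]) %*% fit$W[, i]) + fit$b[i]
  }, numeric(8)), 1, median)
  expect_equal(predict(fit, d, aggregate = "median")$.pred, med)
  # dimension guards
  d_bad <- rand_instance(8, 3, 3, seed = 122)
  expect_error(predict(fit, d_bad), "trials")
  d_bad2 <- rand_instance(8, 2, 4, seed = 123)
  expect_error(predict(fit, d_bad2), "features")
})

test_that("tidy and glance summarize a fit consistently", {
  d <- rand_instance(15, 3, 2, seed = 131)
  fit <- mtjl_fit(d, mtjl_control(), normalize = "none")
  td <- tidy(fit)
  expect_equal(nrow(td), 6)
  expect_equal(td$weight[td$feature == "feature_2" & td$trial == "trial_1"],
               unname(fit$W["feature_2", "trial_1"]))
  gl <- glance(fit)
  expect_equal(gl$objective, final_objective(fit))
  expect_equal(gl$nuclear_norm, nuclear_norm(fit$W))
  expect_true(gl$converged)
  expect_s3_class(autoplot(fit), "ggplot")
})
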