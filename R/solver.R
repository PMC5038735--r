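#' Nuclear norm of a matrix
#'
#' Sum of singular values, the convex surrogate of matrix rank used by the
#' low-rank coupling term of the multi-trial model.
#'
#' @param W numeric matrix.
#' @return A non-negative scalar.
#' @examples
#' nuclear_norm(diag(c(3, 4)))  # 7
#' @export
nuclear_norm <- function(W) {
  W <- as.matrix(W)
  if (!all(is.finite(W))) stop("`W` contains non-finite entries.", call. = FALSE)
  sum(svd(W, nu = 0, nv = 0)$d)
}

#' Smoothed trace surrogate of the nuclear norm
#'
#' Computes \eqn{Trace(W^T (WW^T + \delta I)^{-1/2} W)} through the
#' symmetric eigendecomposition of \eqn{WW^T + \delta I}.  As
#' `delta` tends to zero this converges to [nuclear_norm()]; the smoothing
#' keeps the expression defined for rank-deficient `W`.
#'
#' @param W numeric matrix (`D x m`).
#' @param delta positive smoothing constant.
#' @return A non-negative scalar.
#' @export
trace_surrogate <- function(W, delta = 1e-8) {
  W <- as.matrix(W)
  if (!all(is.finite(W))) stop("`W` contains non-finite entries.", call. = FALSE)
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0) {
    stop("`delta` must be a positive scalar.", call. = FALSE)
  }
  ev <- eigen(tcrossprod(W) + delta * diag(nrow(W)), symmetric = TRUE,
              only.values = TRUE)$values
  ev <- pmax(ev, delta)
  # eigenvalues are sigma^2 + delta, so the trace is sum sigma^2 / sqrt(sigma^2 + delta)
  sum((ev - delta) / sqrt(ev))
}

#' Reweighting matrix of the trace-norm surrogate
#'
#' The half inverse square root \eqn{\frac{1}{2}(WW^T + \delta I)^{-1/2}}
#' that enters the closed-form weight update; computed by symmetric
#' eigendecomposition with eigenvalues clipped at `delta`.
#'
#' @inheritParams trace_surrogate
#' @return A symmetric positive-definite `D x D` matrix.
#' @export
reweight_matrix <- function(W, delta = 1e-8) {
  W <- as.matrix(W)
  if (!all(is.finite(W))) stop("`W` contains non-finite entries.", call. = FALSE)
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0) {
    stop("`delta` must be a positive scalar.", call. = FALSE)
  }
  eg <- eigen(tcrossprod(W) + delta * diag(nrow(W)), symmetric = TRUE)
  vals <- pmax(eg$values, delta)
  Dr <- eg$vectors %*% (t(eg$vectors) * (0.5 / sqrt(vals)))
  (Dr + t(Dr)) / 2
}

#' Closed-form update of one trial's weight vector
#'
#' Solves \eqn{(X_i^T X_i + \lambda I + \gamma D_r) w_i = X_i^T(Y - 1 b_i)}
#' by factorization (never by forming an explicit inverse).
#'
#' @param X numeric `N x D` trial matrix.
#' @param Y numeric score vector of length `N`.
#' @param b scalar bias of the trial.
#' @param Dr `D x D` reweighting matrix from [reweight_matrix()].
#' @param lambda,gamma non-negative penalty weights.
#' @param trial optional label used in error messages.
#' @return The length-`D` weight vector.
#' @export
solve_trial_weights <- function(X, Y, b, Dr, lambda = 1, gamma = 1,
                                trial = NULL) {
  A <- crossprod(X) + lambda * diag(ncol(X)) + gamma * Dr
  rhs <- crossprod(X, Y - b)
  w <- tryCatch(solve(A, rhs), error = function(e) {
    stop("Singular weight system", if (!is.null(trial)) paste0(" in trial '", trial, "'"),
         " (lambda = gamma = 0 with rank-deficient features?): ",
         conditionMessage(e), call. = FALSE)
  })
  drop(w)
}

#' Closed-form update of one trial's bias
#'
#' The stationary bias is the mean residual: `mean(Y - X %*% w)`.
#'
#' @inheritParams solve_trial_weights
#' @param w the trial's weight vector.
#' @return A scalar.
#' @export
solve_trial_bias <- function(X, Y, w) mean(Y - drop(X %*% w))

#' Multi-trial joint objective
#'
#' \deqn{J = \sum_i \|X_i w_i + 1 b_i - Y\|^2 + \lambda \sum_i \|w_i\|^2 +
#'   \gamma\, Trace(W^T (WW^T + \delta I)^{-1/2} W)}
#'
#' @param data a [multitrial_dataset()] (normalized features expected for the
#'   regularization to act on comparable scales).
#' @param W `D x m` stacked weight matrix, column `i` for trial `i`.
#' @param b numeric vector of `m` biases.
#' @param lambda,gamma non-negative penalty weights.
#' @param delta smoothing constant of the trace surrogate.
#' @return A non-negative scalar.
#' @export
mtjl_objective <- function(data, W, b, lambda = 1, gamma = 1, delta = 1e-8) {
  W <- as.matrix(W)
  m <- n_trials(data)
  if (ncol(W) != m || length(b) != m || nrow(W) != n_features(data)) {
    stop("W must be D x m and b length m for this dataset.", call. = FALSE)
  }
  Y <- unname(data$scores)
  loss <- 0
  for (i in seq_len(m)) {
    r <- drop(data$trials[[i]] %*% W[, i]) + b[i] - Y
    loss <- loss + sum(r^2)
  }
  loss + lambda * sum(W^2) + gamma * trace_surrogate(W, delta)
}

#' Solver settings for the multi-trial model
#'
#' @param lambda non-negative weight of the per-trial ridge (\eqn{\ell_2})
#'   penalty; default 1.
#' @param gamma non-negative weight of the nuclear-norm (low-rank) coupling;
#'   default 1.
#' @param delta positive smoothing constant for the inverse matrix square
#'   root (default `1e-8`).
#' @param tol relative convergence threshold on the objective,
#'   \eqn{|J_t - J_{t-1}| / \max(1, |J_{t-1}|) \le tol}.
#' @param max_iter maximum number of reweighting iterations.
#' @param init `"ridge"` warm-starts every trial at its decoupled
#'   ridge-with-intercept solution (the `gamma = 0` optimum); `"zeros"`
#'   starts from the zero matrix.
#' @return A list of class `mtjl_control`.
#' @export
mtjl_control <- function(lambda = 1, gamma = 1, delta = 1e-8, tol = 1e-6,
                         max_iter = 100L, init = c("ridge", "zeros")) {
  init <- match.arg(init)
  stopifnot(lambda >= 0, gamma >= 0, delta > 0, tol > 0, max_iter >= 1)
  structure(list(lambda = lambda, gamma = gamma, delta = delta, tol = tol,
                 max_iter = as.integer(max_iter), init = init),
            class = "mtjl_control")
}

# Decoupled ridge-with-intercept fit of one trial: center X and Y, solve
# (Xc'Xc + lambda I) w = Xc'Yc, recover the intercept from the means.
ridge_with_intercept <- function(X, Y, lambda, trial = NULL) {
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  Yc <- Y - mean(Y)
  A <- crossprod(Xc) + lambda * diag(ncol(X))
  w <- tryCatch(drop(solve(A, crossprod(Xc, Yc))), error = function(e) {
    stop("Singular ridge system",
         if (!is.null(trial)) paste0(" in trial '", trial, "'"),
         ": ", conditionMessage(e), call. = FALSE)
  })
  list(w = w, b = mean(Y) - sum(mu * w))
}

#' Fit the multi-trial joint learning model
#'
#' Minimizes the sum of per-trial squared prediction errors plus an
#' \eqn{\ell_2} penalty on every trial's weights and a nuclear-norm penalty
#' coupling the stacked weight matrix.  Each iteration applies exact
#' closed-form updates: all trial weights (using the current reweighting
#' matrix), then all biases, then the reweighting matrix and the objective;
#' the loop stops when the relative objective change falls below
#' `control$tol`.
#'
#' @param data a [multitrial_dataset()] or long data frame (see
#'   [as_multitrial()]; then `scores` must be supplied).
#' @param control an [mtjl_control()] settings list.
#' @param normalize `"zscore"` (default) z-scores every feature per trial
#'   with the fitting data's own statistics and stores them in the model so
#'   that [predict()] can apply them to new participants; `"none"` fits on
#'   the features as given.
#' @param scores score vector/table when `data` is a long data frame.
#' @return An object of class `mtjl_model`: stacked weights `W` (`D x m`),
#'   biases `b`, the full `objective_trace`, iteration count, convergence
#'   flag, the control settings and the normalization statistics.
#' @examples
#' sim <- simulate_cohort(cohort_config(n_participants = 20, n_trials = 4,
#'                                      n_features = 5), seed = 1)
#' fit <- mtjl_fit(sim$data, mtjl_control(lambda = 1, gamma = 1))
#' glance(fit)
#' @export
mtjl_fit <- function(data, control = mtjl_control(),
                     normalize = c("zscore", "none"), scores = NULL) {
  if (is.data.frame(data)) data <- as_multitrial(data, scores)
  stopifnot(inherits(data, "multitrial_dataset"),
            inherits(control, "mtjl_control"))
  normalize <- match.arg(normalize)

  Y <- unname(data$scores)
  N <- n_participants(data)
  D <- n_features(data)
  m <- n_trials(data)

  norm_stats <- NULL
  if (normalize == "zscore") {
    nf <- normalize_features(data)
    data <- nf$train
    norm_stats <- nf$stats
  }
  # absent cells enter the solver as the training mean (0 after z-scoring)
  if (any(vapply(data$trials, anyNA, logical(1)))) {
    data <- impute_missing(data, strategy = if (normalize == "zscore")
      "zero_after_normalization" else "train_mean")
  }
  Xs <- lapply(data$trials, unname)

  lam <- control$lambda; gam <- control$gamma; delta <- control$delta
  W <- matrix(0, D, m)
  b <- numeric(m)
  if (control$init == "ridge") {
    for (i in seq_len(m)) {
      rf <- ridge_with_intercept(Xs[[i]], Y, lam, trial = data$trial_ids[i])
      W[, i] <- rf$w; b[i] <- rf$b
    }
  }

  XtX <- lapply(Xs, crossprod)
  XtY <- lapply(Xs, function(X) drop(crossprod(X, Y)))
  Xt1 <- lapply(Xs, colSums)
  I_D <- diag(D)

  obj <- function(W, b) {
    loss <- 0
    for (i in seq_len(m)) {
      r <- drop(Xs[[i]] %*% W[, i]) + b[i] - Y
      loss <- loss + sum(r^2)
    }
    loss + lam * sum(W^2) + gam * trace_surrogate(W, delta)
  }

  J <- obj(W, b)
  trace_J <- J
  converged <- FALSE
  n_iter <- 0L
  Dr <- reweight_matrix(W, delta)
  for (t in seq_len(control$max_iter)) {
    for (i in seq_len(m)) {
      A <- XtX[[i]] + lam * I_D + gam * Dr
      rhs <- XtY[[i]] - Xt1[[i]] * b[i]
      W[, i] <- tryCatch(drop(solve(A, rhs)), error = function(e) {
        stop("Singular weight system in trial '", data$trial_ids[i], "': ",
             conditionMessage(e), call. = FALSE)
      })
    }
    for (i in seq_len(m)) b[i] <- mean(Y - drop(Xs[[i]] %*% W[, i]))
    Dr <- reweight_matrix(W, delta)
    J_new <- obj(W, b)
    if (!is.finite(J_new)) {
      stop("Objective became non-finite at iteration ", t,
           "; the problem is numerically degenerate.", call. = FALSE)
    }
    trace_J <- c(trace_J, J_new)
    n_iter <- t
    if (abs(J_new - J) / max(1, abs(J)) <= control$tol) {
      converged <- TRUE
      J <- J_new
      break
    }
    J <- J_new
  }
  if (!converged) {
    warning("mtjl_fit did not converge within ", control$max_iter,
            " iterations (relative change ",
        formatC(abs(diff(tail2(trace_J))) / max(1, abs(trace_J[length(trace_J) - 1])),
                format = "e", digits = 2), ").", call. = FALSE)
  }
  dimnames(W) <- list(data$feature_names, data$trial_ids)
  structure(
    list(W = W, b = setNames(b, data$trial_ids),
         objective_trace = trace_J, n_iter = n_iter, converged = converged,
         control = control, feature_names = data$feature_names,
         trial_ids = data$trial_ids, normalization = norm_stats,
         n_participants = N),
    class = "mtjl_model"
  )
}

tail2 <- function(x) x[max(1L, length(x) - 1L):length(x)]

#' Predict reading scores for new participants
#'
#' Applies the per-trial affine predictors to the new feature matrices and
#' aggregates the `m` per-trial predictions into one score per participant.
#'
#' @param object a fitted `mtjl_model`.
#' @param newdata a [multitrial_dataset()] with the model's `m` trials and
#'   `D` features for new participants.
#' @param aggregate combine per-trial predictions by their `"mean"`
#'   (default) or `"median"`.
#' @param clip clip the aggregated score into `[0, 100]`?
#' @param ... unused.
#' @return A tibble with `participant_id` and `.pred` (plus per-trial
#'   predictions in the attribute `"per_trial"`).
#' @export
predict.mtjl_model <- function(object, newdata, aggregate = c("mean", "median"),
                               clip = FALSE, ...) {
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(newdata, "multitrial_dataset"))
  if (n_trials(newdata) != length(object$trial_ids)) {
    stop("`newdata` has ", n_trials(newdata), " trials but the model was fit on ",
         length(object$trial_ids), ".", call. = FALSE)
  }
  if (n_features(newdata) != length(object$feature_names)) {
    stop("`newdata` has ", n_features(newdata),
         " features but the model was fit on ",
         length(object$feature_names), ".", call. = FALSE)
  }
  mats <- newdata$trials
  if (!is.null(object$normalization)) {
    mats <- apply_normalization(mats, object$normalization)
  }
  per_trial <- vapply(seq_along(mats), function(i) {
    X <- unname(mats[[i]])
    X[is.na(X)] <- 0  # training-mean imputation on the z-score scale
    drop(X %*% object$W[, i]) + object$b[i]
  }, numeric(n_participants(newdata)))
  per_trial <- matrix(per_trial, nrow = n_participants(newdata))
  pred <- switch(aggregate,
                 mean = rowMeans(per_trial),
                 median = apply(per_trial, 1L, median))
  if (clip) pred <- pmin(pmax(pred, 0), 100)
  out <- tibble::tibble(participant_id = newdata$participant_ids,
                        .pred = pred)
  attr(out, "per_trial") <- per_trial
  out
}

#' @export
print.mtjl_model <- function(x, ...) {
  cat(sprintf("<mtjl_model> %d features x %d trials (lambda = %g, gamma = %g)\n",
              nrow(x$W), ncol(x$W), x$control$lambda, x$control$gamma))
  cat(sprintf("  %s after %d iteration(s); objective %.6g; nuclear norm %.4g\n",
              if (x$converged) "converged" else "NOT converged", x$n_iter,
              x$objective_trace[length(x$objective_trace)],
              nuclear_norm(x$W)))
  invisible(x)
}

#' @describeIn mtjl_fit one row per feature-trial weight.
#' @param x an `mtjl_model`.
#' @param ... unused.
#' @export
tidy.mtjl_model <- function(x, ...) {
  tibble::as_tibble(x$W, rownames = "feature") |>
    tidyr::pivot_longer(-"feature", names_to = "trial",
                        values_to = "weight")
}

#' @describeIn mtjl_fit one-row model summary (objective, penalties, rank
#'   diagnostics, convergence).
#' @export
glance.mtjl_model <- function(x, ...) {
  sv <- svd(x$W, nu = 0, nv = 0)$d
  tibble::tibble(
    objective = x$objective_trace[length(x$objective_trace)],
    lambda = x$control$lambda, gamma = x$control$gamma,
    nuclear_norm = sum(sv),
    effective_rank = sum(sv > 1e-8 * max(sv, 1e-300)),
    n_iter = x$n_iter, converged = x$converged
  )
}

#' @describeIn mtjl_fit convergence curve of the objective.
#' @param object an `mtjl_model`.
#' @export
autoplot.mtjl_model <- function(object, ...) {
  df <- tibble::tibble(iteration = seq_along(object$objective_trace) - 1L,
                       objective = object$objective_trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$objective)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Iteration", y = "Objective J(t)",
                  title = "Convergence of the multi-trial objective") +
    ggplot2::theme_minimal()
}
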