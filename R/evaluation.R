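#' Z-score features per trial with training-fold statistics
#'
#' Every feature in every trial is centered and scaled (population
#' standard deviation, i.e. denominator `n`) with statistics computed on
#' `train` only; the identical statistics transform `apply_to`, so no test
#' information leaks into the representation.  Zero-variance columns are
#' centered only, with a warning.
#'
#' @param train a [multitrial_dataset()] used to compute the statistics.
#' @param apply_to optional second dataset (e.g. the test fold) transformed
#'   with the training statistics.
#' @return A list with `train`, `apply_to` (or `NULL`) and `stats`
#'   (`center` and `scale`, each a `D x m` matrix).
#' @examples
#' sim <- simulate_cohort(cohort_config(n_participants = 10, n_trials = 2,
#'                                      n_features = 3), seed = 1)
#' nf <- normalize_features(sim$data)
#' colMeans(nf$train$trials[[1]])  # ~0
#' @export
normalize_features <- function(train, apply_to = NULL) {
  stopifnot(inherits(train, "multitrial_dataset"))
  if (!is.null(apply_to)) {
    stopifnot(inherits(apply_to, "multitrial_dataset"))
    if (n_features(apply_to) != n_features(train) ||
        n_trials(apply_to) != n_trials(train)) {
      stop("`apply_to` must share the training data's features and trials.",
           call. = FALSE)
    }
  }
  D <- n_features(train)
  m <- n_trials(train)
  center <- matrix(NA_real_, D, m,
                   dimnames = list(train$feature_names, train$trial_ids))
  scale_ <- center
  zero_var <- character(0)
  for (i in seq_len(m)) {
    X <- train$trials[[i]]
    mu <- colMeans(X, na.rm = TRUE)
    sdv <- sqrt(colMeans(sweep(X, 2L, mu)^2, na.rm = TRUE))
    zv <- !is.na(sdv) & sdv < 1e-12
    if (any(zv)) {
      zero_var <- union(zero_var, train$feature_names[zv])
      sdv[zv] <- 1
    }
    center[, i] <- mu
    scale_[, i] <- sdv
  }
  if (length(zero_var)) {
    warning("Zero-variance column(s) centered but not scaled: ",
            paste(zero_var, collapse = ", "), call. = FALSE)
  }
  stats <- list(center = center, scale = scale_)
  out_train <- train
  out_train$trials <- apply_normalization(train$trials, stats)
  out_train$normalized <- TRUE
  out <- list(train = out_train, apply_to = NULL, stats = stats)
  if (!is.null(apply_to)) {
    out_apply <- apply_to
    out_apply$trials <- apply_normalization(apply_to$trials, stats)
    out_apply$normalized <- TRUE
    out$apply_to <- out_apply
  }
  out
}

apply_normalization <- function(mats, stats) {
  lapply(seq_along(mats), function(i) {
    X <- sweep(mats[[i]], 2L, stats$center[, i])
    sweep(X, 2L, stats$scale[, i], "/")
  }) |> setNames(names(mats))
}

#' Split participants into two halves
#'
#' Participant-level partition into folds of size `ceiling(N/2)` and
#' `floor(N/2)`; all trials of a participant stay on one side.  With
#' `stratify = TRUE` the split is balanced across the score median so that
#' both folds span the ability range.
#'
#' @param data a [multitrial_dataset()].
#' @param seed integer seed making the split reproducible.
#' @param stratify balance the folds across the score median?
#' @return A list with `train`, `test` (both [multitrial_dataset()]s) and
#'   the participant index vectors `train_idx`, `test_idx`.
#' @export
split_half <- function(data, seed = NULL, stratify = FALSE) {
  stopifnot(inherits(data, "multitrial_dataset"))
  N <- n_participants(data)
  draw <- function() {
    if (stratify) {
      hi <- which(data$scores >= median(data$scores))
      lo <- setdiff(seq_len(N), hi)
      c(sample(hi, ceiling(length(hi) / 2)),
        sample(lo, ceiling(length(lo) / 2)))
    } else {
      sample(seq_len(N), ceiling(N / 2))
    }
  }
  train_idx <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(N), train_idx)
  list(train = subset_participants(data, train_idx),
       test = subset_participants(data, test_idx),
       train_idx = train_idx, test_idx = test_idx)
}

#' Prediction error on the score scale
#'
#' @param pred,truth numeric vectors of equal length (points, 0-100 scale).
#' @param metric `"mae"` (mean absolute error, default) or `"rmse"`.
#' @return A scalar.
#' @export
prediction_error <- function(pred, truth, metric = c("mae", "rmse")) {
  metric <- match.arg(metric)
  if (length(pred) != length(truth)) {
    stop("`pred` and `truth` must have equal length.", call. = FALSE)
  }
  switch(metric,
         mae = mean(abs(pred - truth)),
         rmse = sqrt(mean((pred - truth)^2)))
}

#' Indicator contributions of a fitted model
#'
#' The contribution of feature `d` is the mean absolute weight across
#' trials, normalized so the contributions sum to one.
#'
#' @param model an `mtjl_model`.
#' @return A tibble with `feature` and `contribution` (non-negative,
#'   summing to 1).
#' @export
indicator_contributions <- function(model) {
  stopifnot(inherits(model, "mtjl_model"))
  raw <- rowMeans(abs(model$W))
  tot <- sum(raw)
  if (tot <= 0) {
    warning("All weights are zero; reporting uniform contributions.",
            call. = FALSE)
    raw <- rep(1, length(raw))
    tot <- length(raw)
  }
  tibble::tibble(feature = model$feature_names,
                 contribution = unname(raw) / tot)
}

#' Trial contributions of a fitted model
#'
#' The contribution of trial `i` is the absolute column sum of the weight
#' matrix, reported both raw and scaled by the maximum.
#'
#' @param model an `mtjl_model`.
#' @return A tibble with `trial`, `contribution` (raw) and
#'   `contribution_scaled` (max-normalized).
#' @export
trial_contributions <- function(model) {
  stopifnot(inherits(model, "mtjl_model"))
  raw <- colSums(abs(model$W))
  mx <- max(raw)
  if (mx <= 0) {
    warning("All weights are zero; trial contributions are zero.",
            call. = FALSE)
    mx <- 1
  }
  tibble::tibble(trial = model$trial_ids, contribution = unname(raw),
                 contribution_scaled = unname(raw) / mx)
}

#' Repeated half-split evaluation
#'
#' The consistency protocol of the method: `n_runs` times, split the
#' participants in half, z-score on the training fold, impute missing
#' cells with training statistics, fit the multi-trial model, predict the
#' held-out fold and record the error on the 0-100 score scale.  Failed
#' runs are recorded and excluded from the summaries; more than 20\%
#' failures aborts.
#'
#' @param data a [multitrial_dataset()].
#' @param control an [mtjl_control()].
#' @param n_runs number of random splits (the reference protocol uses 100).
#' @param base_seed run `k` uses seed `base_seed + k - 1`.
#' @param metric `"mae"` or `"rmse"`.
#' @param stratify stratify the splits across the score median?
#' @param clip clip predictions into `[0, 100]`?
#' @return An object of class `mtjl_evaluation`: per-run tibble, summary
#'   statistics, indicator/trial contribution tables (mean across runs and
#'   final run), and the median iteration count.
#' @examples
#' sim <- simulate_cohort(cohort_config(n_participants = 20, n_trials = 4,
#'                                      n_features = 5), seed = 1)
#' ev <- repeated_evaluation(sim$data, n_runs = 3, base_seed = 1)
#' glance(ev)
#' @export
repeated_evaluation <- function(data, control = mtjl_control(),
                                n_runs = 100L, base_seed = 1L,
                                metric = c("mae", "rmse"), stratify = FALSE,
                                clip = FALSE) {
  stopifnot(inherits(data, "multitrial_dataset"), n_runs >= 1L)
  metric <- match.arg(metric)
  runs <- vector("list", n_runs)
  last_model <- NULL
  ic_sum <- NULL
  tc_sum <- NULL
  n_ok <- 0L
  for (k in seq_len(n_runs)) {
    seed_k <- base_seed + k - 1L
    runs[[k]] <- tryCatch({
      sp <- split_half(data, seed = seed_k, stratify = stratify)
      nf <- normalize_features(sp$train, apply_to = sp$test)
      fit <- mtjl_fit(nf$train, control = control, normalize = "none")
      pred <- predict(fit, nf$apply_to, clip = clip)
      err <- prediction_error(pred$.pred, unname(sp$test$scores),
                              metric = metric)
      ic <- indicator_contributions(fit)$contribution
      tc <- trial_contributions(fit)$contribution
      ic_sum <- if (is.null(ic_sum)) ic else ic_sum + ic
      tc_sum <- if (is.null(tc_sum)) tc else tc_sum + tc
      last_model <- fit
      tibble::tibble(run = k, seed = seed_k, error = err,
                     n_iter = fit$n_iter, converged = fit$converged,
                     failed = FALSE)
    }, error = function(e) {
      tibble::tibble(run = k, seed = seed_k, error = NA_real_,
                     n_iter = NA_integer_, converged = NA,
                     failed = TRUE)
    })
  }
  per_run <- dplyr::bind_rows(runs)
  n_failed <- sum(per_run$failed)
  if (n_failed > 0.2 * n_runs) {
    stop(n_failed, " of ", n_runs, " evaluation runs failed (> 20%).",
         call. = FALSE)
  }
  ok <- per_run[!per_run$failed, ]
  n_ok <- nrow(ok)
  if (n_ok == 0L) stop("All evaluation runs failed.", call. = FALSE)
  structure(
    list(
      per_run = per_run,
      mean_error = mean(ok$error),
      std_error = if (n_ok > 1L) sd(ok$error) else 0,
      single_run = n_ok == 1L,
      n_runs = n_runs, n_failed = n_failed,
      metric = metric, base_seed = base_seed,
      median_iterations = median(ok$n_iter),
      indicator_contributions = indicator_contributions(last_model) |>
        dplyr::mutate(contribution_mean = ic_sum / n_ok / sum(ic_sum / n_ok)),
      trial_contributions = trial_contributions(last_model) |>
        dplyr::mutate(contribution_mean = tc_sum / n_ok),
      control = control
    ),
    class = "mtjl_evaluation")
}

#' @export
print.mtjl_evaluation <- function(x, ...) {
  cat(sprintf(
    "<mtjl_evaluation> %d run(s): %s = %.3f (sd %.3f)%s; median iterations %g\n",
    x$n_runs, toupper(x$metric), x$mean_error, x$std_error,
    if (x$n_failed) sprintf(" [%d failed]", x$n_failed) else "",
    x$median_iterations))
  if (x$single_run) cat("  (single run: sd reported as 0 by convention)\n")
  invisible(x)
}

#' @describeIn repeated_evaluation one row per evaluation run.
#' @param x an `mtjl_evaluation`.
#' @param ... unused.
#' @export
tidy.mtjl_evaluation <- function(x, ...) x$per_run

#' @describeIn repeated_evaluation one-row summary (mean/sd error, runs,
#'   failures, median iterations).
#' @export
glance.mtjl_evaluation <- function(x, ...) {
  tibble::tibble(mean_error = x$mean_error, std_error = x$std_error,
                 n_runs = x$n_runs, n_failed = x$n_failed,
                 metric = x$metric,
                 median_iterations = x$median_iterations)
}

#' @describeIn repeated_evaluation per-run error curve.
#' @param object an `mtjl_evaluation`.
#' @export
autoplot.mtjl_evaluation <- function(object, ...) {
  df <- object$per_run[!object$per_run$failed, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$run, y = .data$error)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$mean_error, linetype = 2) +
    ggplot2::labs(x = "Run", y = paste0(toupper(object$metric),
                                        " (score points)"),
                  title = sprintf("Repeated half-split evaluation (mean %.2f, sd %.2f)",
                                  object$mean_error, object$std_error)) +
    ggplot2::theme_minimal()
}

#' Bar chart of indicator contributions
#'
#' @param x an `mtjl_model` or `mtjl_evaluation`.
#' @return A ggplot.
#' @export
plot_indicator_contributions <- function(x) {
  df <- if (inherits(x, "mtjl_evaluation")) x$indicator_contributions
        else indicator_contributions(x)
  df$feature <- factor(df$feature, levels = df$feature[order(df$contribution)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$contribution, y = .data$feature)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Contribution (normalized mean |weight|)", y = NULL,
                  title = "Indicator contributions") +
    ggplot2::theme_minimal()
}

#' Per-trial contribution profile
#'
#' @param x an `mtjl_model` or `mtjl_evaluation`.
#' @param scaled plot the max-normalized contributions?
#' @return A ggplot.
#' @export
plot_trial_contributions <- function(x, scaled = TRUE) {
  df <- if (inherits(x, "mtjl_evaluation")) x$trial_contributions
        else trial_contributions(x)
  df$idx <- seq_len(nrow(df))
  y <- if (scaled) "contribution_scaled" else "contribution"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$idx, y = .data[[y]])) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Trial", y = if (scaled) "Contribution (max-scaled)"
                  else "Contribution (sum |weight|)",
                  title = "Trial contributions") +
    ggplot2::theme_minimal()
}
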