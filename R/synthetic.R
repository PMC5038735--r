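#' Default feature specification of the emulated cohort
#'
#' Nineteen features: sixteen eye-tracking indicators (pupil, blink,
#' fixation, saccade, regression families plus overall reading duration)
#' and three entrance-exam scores.  `location`/`scale` give plausible
#' raw-unit magnitudes per family (pixel, millisecond, per-second and count
#' scales); `group_effect` is the standardized mean shift between the two
#' ability groups (1.0 SD for the thirteen indicators the motivating cohort
#' found sensitive, 0 elsewhere); `loading_weight` scales how strongly a
#' feature's row of the ground-truth weight matrix loads on the latent
#' ability (0.3 for the near-null indicators, Chinese exam strongest and
#' math weakest among the exams).
#'
#' @return A tibble with columns `name`, `family`, `unit`, `location`,
#'   `scale`, `group_effect`, `loading_weight`.
#' @export
default_feature_spec <- function() {
  tibble::tribble(
    ~name,                 ~family,      ~unit,       ~location, ~scale, ~group_effect, ~loading_weight,
    "pupil_diameter",      "pupil",      "pixels",    850,       120,    1,             1,
    "blink_count",         "blink",      "count",     4,         2,      1,             1,
    "blink_rate",          "blink",      "per s",     0.25,      0.12,   1,             1,
    "fixation_count",      "fixation",   "count",     18,        6,      1,             1,
    "fixation_rate",       "fixation",   "per s",     3.1,       0.7,    1,             1,
    "fixation_duration",   "fixation",   "ms",        240,       60,     1,             1,
    "fixation_position_x", "fixation",   "pixels",    512,       90,     1,             1,
    "fixation_position_y", "fixation",   "pixels",    384,       40,     0,             0.3,
    "saccade_count",       "saccade",    "count",     16,        5,      1,             1,
    "saccade_rate",        "saccade",    "per s",     2.9,       0.8,    1,             1,
    "saccade_duration",    "saccade",    "ms",        45,        12,     1,             1,
    "saccade_amplitude",   "saccade",    "degrees",   2.1,       0.6,    1,             1,
    "regression_count",    "regression", "count",     3,         1.5,    1,             1,
    "regression_rate",     "regression", "per s",     0.45,      0.2,    1,             1,
    "regression_length",   "regression", "pixels",    140,       60,     0,             0.3,
    "reading_duration",    "other",      "s",         6,         1.8,    0,             0.3,
    "chinese_exam",        "exam",       "points",    105,       20,     0,             1.5,
    "math_exam",           "exam",       "points",    95,        25,     0,             0.5,
    "english_exam",        "exam",       "points",    100,       22,     0,             1
  )
}

generic_feature_spec <- function(n) {
  tibble::tibble(name = paste0("feature_", seq_len(n)), family = "other",
                 unit = "unitless", location = 0, scale = 1,
                 group_effect = 0, loading_weight = 1)
}

#' Configuration of the synthetic cohort generator
#'
#' Defaults emulate the structure of the motivating study: 74 participants,
#' 42 sentence-reading trials, 19 features, scores mapped into the observed
#' 48.8-90.83 range, a rank-2 ground-truth weight matrix, score noise of
#' 0.5 points and 10\% sporadic missingness in the blink columns (applied
#' by [inject_missing()], not by the generator itself).
#'
#' @param n_participants number of participants `N`.
#' @param n_trials number of trials `m`.
#' @param feature_spec tibble as returned by [default_feature_spec()].
#' @param n_features shortcut: replace `feature_spec` by a generic
#'   `n_features`-feature specification (unit scales, no group shifts).
#' @param true_rank rank `r` of the ground-truth weight matrix,
#'   `1 <= r <= min(D, m)`.
#' @param noise_sd standard deviation of the score noise, in points on the
#'   0-100 scale.
#' @param score_range the interval the noiseless scores are mapped onto.
#' @param missing_fraction default fraction of blink-family cells that
#'   [inject_missing()] masks.
#' @param seed default random seed used by [simulate_cohort()].
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 74L, n_trials = 42L,
                          feature_spec = default_feature_spec(),
                          n_features = NULL, true_rank = 2L, noise_sd = 0.5,
                          score_range = c(48.8, 90.83),
                          missing_fraction = 0.1, seed = NULL) {
  if (!is.null(n_features)) feature_spec <- generic_feature_spec(n_features)
  D <- nrow(feature_spec)
  if (true_rank < 1L || true_rank > min(D, n_trials)) {
    stop("`true_rank` must lie in [1, min(D, m)] = [1, ",
         min(D, n_trials), "].", call. = FALSE)
  }
  stopifnot(n_participants >= 2L, n_trials >= 1L, noise_sd >= 0,
            missing_fraction >= 0, missing_fraction < 1,
            length(score_range) == 2L, score_range[1] < score_range[2],
            score_range[1] >= 0, score_range[2] <= 100)
  structure(list(n_participants = as.integer(n_participants),
                 n_trials = as.integer(n_trials),
                 feature_spec = feature_spec, true_rank = as.integer(true_rank),
                 noise_sd = noise_sd, score_range = score_range,
                 missing_fraction = missing_fraction, seed = seed),
            class = "cohort_config")
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Simulate a multi-trial eye-tracking cohort with known ground truth
#'
#' Draws a latent reading ability per participant, balanced high/low group
#' labels, and per-trial feature matrices built from three orthogonal
#' components: an ability component aligned with the trial's ground-truth
#' weight vector, a group-shift component on the designated sensitive
#' indicators (constrained orthogonal to the weight columns so it never
#' leaks into the scores), and feature noise orthogonal to both.  By
#' construction every trial's normalized features reproduce the ability
#' exactly (`X_i w*_i = ability`), so the stacked rank-`r` weight matrix
#' `W*` is identifiable.  Scores are the across-trial mean prediction
#' affinely mapped into `score_range`, plus Normal(0, `noise_sd`) points,
#' clipped to the range.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed (overrides `config$seed`; default 1).
#' @param raw if `TRUE` (default) features are returned on plausible raw
#'   family scales (`location + scale * z`); if `FALSE` the exact
#'   normalized representation used to build the scores is returned, which
#'   is the representation to fit on (with `normalize = "none"`) when
#'   comparing a fitted weight matrix against `W*`.
#' @return A list with `data` (a [multitrial_dataset()]) and `truth`
#'   (class `cohort_truth`: `W_star`, `b_star`, `group_labels`, `ability`,
#'   the affine score map `score_shift`/`score_scale`, `noise_sd`,
#'   `feature_spec`, `seed`).
#' @examples
#' sim <- simulate_cohort(cohort_config(), seed = 7)
#' sim$data
#' qr(sim$truth$W_star)$rank  # true_rank
#' @export
simulate_cohort <- function(config = cohort_config(), seed = NULL,
                            raw = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  seed <- seed %||% config$seed %||% 1L
  spec <- config$feature_spec
  N <- config$n_participants
  D <- nrow(spec)
  m <- config$n_trials
  r <- config$true_rank

  withr::with_seed(seed, {
    ability <- rnorm(N)
    ability <- (ability - mean(ability)) / pop_sd(ability)

    n_high <- N %/% 2L
    grp <- sample(rep(c("high", "low"), c(n_high, N - n_high)))
    shifts <- spec$group_effect
    h <- NULL
    if (any(shifts != 0)) {
      h0 <- ifelse(grp == "high", 0.5, -0.5)
      h0 <- h0 - mean(h0)
      h0 <- h0 - ability * sum(ability * h0) / sum(ability^2)
      if (pop_sd(h0) < 1e-12) {
        stop("Degenerate group contrast; increase n_participants.",
             call. = FALSE)
      }
      h <- h0 / pop_sd(h0) * 0.5
    }

    A <- matrix(rnorm(D * r), D, r) * spec$loading_weight
    if (!is.null(h)) {
      A <- A - shifts %*% (crossprod(shifts, A) / sum(shifts^2))
    }
    B <- matrix(rnorm(m * r), m, r)
    B[, 1] <- B[, 1] + 2  # trials share a dominant direction: consistent profiles
    W_star <- A %*% t(B)
    norms <- sqrt(colSums(W_star^2))
    if (any(norms < 1e-10)) {
      stop("Degenerate ground-truth weight column; try another seed.",
           call. = FALSE)
    }
    W_star <- sweep(W_star, 2L, norms, "/")
    b_star <- rnorm(m, 0, 0.25)

    # orthonormal basis spanning the constant, ability and group directions
    Q <- qr.Q(qr(cbind(1, ability, if (is.null(h)) NULL else h)))
    trials <- vector("list", m)
    for (i in seq_len(m)) {
      w <- W_star[, i]
      s2 <- pmax(0.1, 1 - w^2 - 0.25 * shifts^2)
      E <- matrix(rnorm(N * D), N, D) * rep(sqrt(s2), each = N)
      P <- E - (E %*% w) %*% t(w)          # orthogonal to the weight vector
      P <- P - Q %*% crossprod(Q, P)       # centered, independent of a and h
      Xt <- ability %*% t(w) + P
      if (!is.null(h)) Xt <- Xt + h %*% t(shifts)
      trials[[i]] <- Xt
    }

    Y0 <- ability + mean(b_star)
    rg <- range(Y0)
    if (diff(rg) < 1e-12) {
      stop("Degenerate ability spread; cannot map scores onto the range.",
           call. = FALSE)
    }
    beta <- diff(config$score_range) / diff(rg)
    alpha <- config$score_range[1] - beta * rg[1]
    Y <- alpha + beta * Y0
    if (config$noise_sd > 0) {
      Y <- Y + rnorm(N, 0, config$noise_sd)
      Y <- pmin(pmax(Y, config$score_range[1]), config$score_range[2])
    }

    if (raw) {
      trials <- lapply(trials, function(X) {
        sweep(sweep(X, 2L, spec$scale, "*"), 2L, spec$location, "+")
      })
    }

    pid <- sprintf("P%03d", seq_len(N))
    tid <- sprintf("trial_%02d", seq_len(m))
    trials <- lapply(trials, function(X) {
      dimnames(X) <- list(pid, spec$name)
      X
    })
    names(trials) <- tid
    data <- multitrial_dataset(trials, Y, feature_names = spec$name,
                               participant_ids = pid, trial_ids = tid,
                               normalized = !raw)
    dimnames(W_star) <- list(spec$name, tid)
    truth <- structure(
      list(W_star = W_star, b_star = setNames(b_star, tid),
           group_labels = setNames(grp, pid),
           ability = setNames(ability, pid),
           score_shift = alpha, score_scale = beta,
           noise_sd = config$noise_sd, feature_spec = spec, seed = seed),
      class = "cohort_truth")
    list(data = data, truth = truth)
  })
}

#' Mask a random fraction of cells in selected feature families
#'
#' Emulates the sporadic empty values that low-frequency events (blinks)
#' leave in per-trial indicator tables: each cell of the target-family
#' columns is masked independently with probability `fraction`.
#'
#' @param data a [multitrial_dataset()].
#' @param fraction probability in `[0, 1)` that a target cell is masked.
#' @param families character vector of indicator families to affect
#'   (default `"blink"`).
#' @param feature_spec feature-family mapping (default
#'   [default_feature_spec()]).
#' @param seed optional seed for reproducible masking.
#' @return The dataset with `NA` in the masked cells.
#' @export
inject_missing <- function(data, fraction = 0.1, families = "blink",
                           feature_spec = default_feature_spec(),
                           seed = NULL) {
  stopifnot(inherits(data, "multitrial_dataset"),
            fraction >= 0, fraction < 1)
  known <- unique(feature_spec$family)
  bad <- setdiff(families, known)
  if (length(bad)) {
    stop("Unknown feature famil", if (length(bad) > 1) "ies: " else "y: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (fraction == 0) return(data)
  target <- feature_spec$name[feature_spec$family %in% families]
  cols <- which(data$feature_names %in% target)
  if (!length(cols)) return(data)
  mask_one <- function(X) {
    hit <- matrix(stats::runif(nrow(X) * length(cols)) < fraction,
                  nrow(X), length(cols))
    X[, cols][hit] <- NA_real_
    X
  }
  data$trials <- if (is.null(seed)) {
    lapply(data$trials, mask_one)
  } else {
    withr::with_seed(seed, lapply(data$trials, mask_one))
  }
  data
}

#' Replace missing cells
#'
#' `"train_mean"` replaces each missing cell by its column's (per-trial)
#' mean over observed values -- or by externally supplied statistics, which
#' is what the evaluation pipeline does so that only training-fold
#' information is used.  `"zero_after_normalization"` requires z-scored
#' data and sets missing cells to 0, the training mean on that scale.
#'
#' @param data a [multitrial_dataset()].
#' @param strategy imputation strategy.
#' @param means optional `D x m` matrix of column means to impute with
#'   (features x trials), e.g. training-fold statistics.
#' @return The dataset with every mask cleared.
#' @export
impute_missing <- function(data,
                           strategy = c("train_mean",
                                        "zero_after_normalization"),
                           means = NULL) {
  stopifnot(inherits(data, "multitrial_dataset"))
  strategy <- match.arg(strategy)
  if (!any(vapply(data$trials, anyNA, logical(1)))) return(data)
  if (strategy == "zero_after_normalization") {
    if (!data$normalized) {
      stop("`zero_after_normalization` needs normalized data.", call. = FALSE)
    }
    data$trials <- lapply(data$trials, function(X) {
      X[is.na(X)] <- 0
      X
    })
    return(data)
  }
  for (i in seq_along(data$trials)) {
    X <- data$trials[[i]]
    for (d in seq_len(ncol(X))) {
      nas <- is.na(X[, d])
      if (!any(nas)) next
      fill <- if (!is.null(means)) {
        means[d, i]
      } else if (all(nas)) {
        NA_real_
      } else {
        mean(X[!nas, d])
      }
      if (is.na(fill)) {
        stop("Column '", data$feature_names[d], "' in trial '",
             data$trial_ids[i], "' is entirely missing; cannot impute.",
             call. = FALSE)
      }
      X[nas, d] <- fill
    }
    data$trials[[i]] <- X
  }
  data
}

#' @export
print.cohort_truth <- function(x, ...) {
  cat(sprintf(
    "<cohort_truth> W*: %d x %d (rank %d), score map y = %.3f + %.3f * z, noise sd %.2f\n",
    nrow(x$W_star), ncol(x$W_star), qr(x$W_star)$rank, x$score_shift,
    x$score_scale, x$noise_sd))
  invisible(x)
}
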