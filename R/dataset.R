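#' Multi-trial dataset container
#'
#' Bundles the `m` per-trial feature matrices (participants x indicators)
#' with the shared reading-score vector.  All trials must cover the same
#' participants in the same order; absent measurements are `NA` and tracked
#' by [missing_mask()].
#'
#' @param trials either a list of `m` numeric matrices (each `N x D`) or a
#'   long data frame with columns `participant_id`, `trial`, then one column
#'   per feature.
#' @param scores numeric vector of length `N`, reading scores on the 0-100
#'   scale; may be named by participant id.
#' @param feature_names,participant_ids,trial_ids optional labels; inferred
#'   from `trials` when available.
#' @param normalized logical flag: `TRUE` when the features are already on
#'   the unitless z-score scale.
#'
#' @return An object of class `multitrial_dataset` with elements `trials`
#'   (list of matrices), `scores`, `feature_names`, `participant_ids`,
#'   `trial_ids` and `normalized`.
#' @examples
#' X <- replicate(3, matrix(rnorm(8), 4, 2), simplify = FALSE)
#' d <- multitrial_dataset(X, scores = c(50, 60, 70, 80))
#' n_trials(d)
#' @export
multitrial_dataset <- function(trials, scores, feature_names = NULL,
                               participant_ids = NULL, trial_ids = NULL,
                               normalized = FALSE) {
  if (is.data.frame(trials)) {
    return(as_multitrial(trials, scores, normalized = normalized))
  }
  if (!is.list(trials) || length(trials) < 1L) {
    stop("`trials` must be a non-empty list of matrices or a long data frame.",
         call. = FALSE)
  }
  trials <- lapply(trials, function(x) {
    x <- as.matrix(x)
    storage.mode(x) <- "double"
    x
  })
  dims <- vapply(trials, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("All trial matrices must share the same N x D shape.", call. = FALSE)
  }
  N <- dims[1, 1]
  D <- dims[2, 1]
  if (N < 2L) stop("Need at least 2 participants.", call. = FALSE)
  if (D < 1L) stop("Need at least 1 feature.", call. = FALSE)
  if (length(scores) != N) {
    stop("`scores` must have one entry per participant (", N, ").",
         call. = FALSE)
  }
  scores <- as.numeric(scores)
  bad <- which(!is.na(scores) & (scores < 0 | scores > 100))
  if (length(bad)) {
    stop("Scores must lie in [0, 100]; offending participant row(s): ",
         paste(head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  if (is.null(feature_names)) {
    feature_names <- colnames(trials[[1]]) %||% paste0("feature_", seq_len(D))
  }
  if (is.null(participant_ids)) {
    participant_ids <- rownames(trials[[1]]) %||% paste0("P", seq_len(N))
  }
  if (is.null(trial_ids)) {
    trial_ids <- names(trials) %||% paste0("trial_", seq_along(trials))
  }
  if (anyDuplicated(participant_ids)) {
    stop("Duplicate participant ids.", call. = FALSE)
  }
  trials <- lapply(trials, function(x) {
    dimnames(x) <- list(participant_ids, feature_names)
    x
  })
  names(trials) <- trial_ids
  structure(
    list(trials = trials, scores = setNames(scores, participant_ids),
         feature_names = feature_names, participant_ids = participant_ids,
         trial_ids = trial_ids, normalized = isTRUE(normalized)),
    class = "multitrial_dataset"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a multi-trial dataset from a long table
#'
#' @param features long data frame: `participant_id`, `trial`, then one
#'   numeric column per feature.  Every participant must appear exactly once
#'   per trial; row order is not trusted, the participant id is the join key.
#' @param scores data frame with columns `participant_id` and `score`, or a
#'   numeric vector named by participant id.
#' @inheritParams multitrial_dataset
#' @return A [multitrial_dataset()].
#' @export
as_multitrial <- function(features, scores, normalized = FALSE) {
  stopifnot(is.data.frame(features))
  need <- c("participant_id", "trial")
  if (!all(need %in% names(features))) {
    stop("`features` needs columns 'participant_id' and 'trial'.",
         call. = FALSE)
  }
  feat_cols <- setdiff(names(features), need)
  if (!length(feat_cols)) stop("No feature columns found.", call. = FALSE)
  not_num <- feat_cols[!vapply(features[feat_cols], is.numeric, logical(1))]
  if (length(not_num)) {
    stop("Non-numeric feature column(s): ", paste(not_num, collapse = ", "),
         call. = FALSE)
  }
  trial_ids <- as.character(unique(features$trial))
  by_trial <- split(features, factor(as.character(features$trial),
                                     levels = trial_ids))
  pid <- as.character(by_trial[[1]]$participant_id)
  if (anyDuplicated(pid)) {
    stop("Duplicate participant_id within trial '", trial_ids[1], "'.",
         call. = FALSE)
  }
  if (is.data.frame(scores)) {
    if (!all(c("participant_id", "score") %in% names(scores))) {
      stop("`scores` needs columns 'participant_id' and 'score'.",
           call. = FALSE)
    }
    scores <- setNames(scores$score, as.character(scores$participant_id))
  }
  if (!is.null(names(scores))) {
    missing_ids <- setdiff(pid, names(scores))
    if (length(missing_ids)) {
      stop("No score for participant(s): ",
           paste(head(missing_ids, 5L), collapse = ", "), call. = FALSE)
    }
    scores <- scores[pid]
  }
  mats <- lapply(seq_along(by_trial), function(i) {
    tb <- by_trial[[i]]
    ids <- as.character(tb$participant_id)
    if (anyDuplicated(ids)) {
      stop("Duplicate participant_id within trial '", trial_ids[i], "'.",
           call. = FALSE)
    }
    if (!setequal(ids, pid)) {
      stop("Trial '", trial_ids[i],
           "' does not cover the same participants as trial '", trial_ids[1],
           "'.", call. = FALSE)
    }
    m <- as.matrix(tb[match(pid, ids), feat_cols, drop = FALSE])
    rownames(m) <- pid
    m
  })
  names(mats) <- trial_ids
  multitrial_dataset(mats, scores, feature_names = feat_cols,
                     participant_ids = pid, trial_ids = trial_ids,
                     normalized = normalized)
}

#' @export
as_tibble.multitrial_dataset <- function(x, ...) {
  purrr::imap_dfr(x$trials, function(m, id) {
    tibble::as_tibble(m) |>
      dplyr::mutate(participant_id = x$participant_ids, trial = id,
                    .before = 1L)
  })
}

#' Number of participants, trials and features
#'
#' @param data a [multitrial_dataset()].
#' @return An integer.
#' @export
n_participants <- function(data) length(data$participant_ids)

#' @rdname n_participants
#' @export
n_trials <- function(data) length(data$trials)

#' @rdname n_participants
#' @export
n_features <- function(data) length(data$feature_names)

#' Missingness mask
#'
#' @param data a [multitrial_dataset()].
#' @return A list of `m` logical matrices, `TRUE` where the value is absent.
#' @export
missing_mask <- function(data) lapply(data$trials, is.na)

#' Keep a subset of participants
#'
#' All trials of a participant travel together (the unit of analysis in any
#' split is the participant, never the single trial).
#'
#' @param data a [multitrial_dataset()].
#' @param idx integer or character index into the participants.
#' @return A [multitrial_dataset()] restricted to those participants.
#' @export
subset_participants <- function(data, idx) {
  if (is.character(idx)) idx <- match(idx, data$participant_ids)
  multitrial_dataset(
    lapply(data$trials, function(m) m[idx, , drop = FALSE]),
    data$scores[idx],
    feature_names = data$feature_names,
    participant_ids = data$participant_ids[idx],
    trial_ids = data$trial_ids,
    normalized = data$normalized
  )
}

#' @export
print.multitrial_dataset <- function(x, ...) {
  n_na <- sum(vapply(x$trials, function(m) sum(is.na(m)), numeric(1)))
  cat(sprintf(
    "<multitrial_dataset> %d participants x %d features x %d trials%s\n",
    n_participants(x), n_features(x), n_trials(x),
    if (x$normalized) " (normalized)" else ""))
  cat(sprintf("  scores: %.1f-%.1f; missing cells: %d\n",
              min(x$scores, na.rm = TRUE), max(x$scores, na.rm = TRUE),
              n_na))
  invisible(x)
}
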