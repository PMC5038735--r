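#' Read per-trial feature tables and scores
#'
#' Accepts either one long CSV with a `trial` column, a character vector of
#' per-trial CSVs, or a directory containing them.  Columns are
#' `participant_id`, (`trial`,) then one numeric column per feature; empty
#' cells become missing values.  The participant id is the join key across
#' trials -- row order is not trusted.  Scores are a two-column CSV
#' (`participant_id`, `score`) and must lie in `[0, 100]`.
#'
#' @param features path(s) as described above.
#' @param scores path to the score table, or a data frame / named vector.
#' @param normalized are the features already z-scored?
#' @return A [multitrial_dataset()].
#' @export
read_feature_tables <- function(features, scores, normalized = FALSE) {
  if (is.character(features) && length(features) == 1L &&
      dir.exists(features)) {
    features <- sort(list.files(features, pattern = "\\.csv$",
                                full.names = TRUE))
    features <- features[!grepl("scores?\\.csv$", basename(features))]
    if (!length(features)) {
      stop("No feature CSV files found in the directory.", call. = FALSE)
    }
  }
  if (is.character(features)) {
    tabs <- lapply(features, function(p) {
      if (!file.exists(p)) stop("File not found: ", p, call. = FALSE)
      tb <- readr::read_csv(p, show_col_types = FALSE, progress = FALSE)
      prob <- readr::problems(tb)
      if (nrow(prob)) {
        stop("Parse problem in ", p, " at row ", prob$row[1], ": ",
             prob$expected[1], " expected.", call. = FALSE)
      }
      if (!"participant_id" %in% names(tb)) {
        stop("Missing 'participant_id' column in ", p, call. = FALSE)
      }
      tb
    })
    long <- if (length(tabs) == 1L && "trial" %in% names(tabs[[1]])) {
      tabs[[1]]
    } else {
      purrr::imap_dfr(tabs, function(tb, i) {
        if (!"trial" %in% names(tb)) {
          tb$trial <- sub("\\.[^.]*$", "", basename(features[[i]]))
        }
        tb
      })
    }
  } else {
    long <- features
  }
  long$participant_id <- as.character(long$participant_id)
  feat_cols <- setdiff(names(long), c("participant_id", "trial"))
  for (cl in feat_cols) {
    if (!is.numeric(long[[cl]])) {
      bad_row <- which(!is.na(long[[cl]]) &
                         is.na(suppressWarnings(as.numeric(long[[cl]]))))[1]
      stop("Non-numeric value in feature column '", cl, "'",
           if (!is.na(bad_row)) paste0(" at row ", bad_row), ".",
           call. = FALSE)
    }
  }

  if (is.character(scores)) {
    if (!file.exists(scores)) stop("File not found: ", scores, call. = FALSE)
    scores <- readr::read_csv(scores, show_col_types = FALSE,
                              progress = FALSE)
  }
  if (is.data.frame(scores)) {
    if (!all(c("participant_id", "score") %in% names(scores))) {
      stop("Score table needs columns 'participant_id' and 'score'.",
           call. = FALSE)
    }
    bad <- which(!is.na(scores$score) &
                   (scores$score < 0 | scores$score > 100))
    if (length(bad)) {
      stop("Score out of [0, 100] in score table at row ", bad[1],
           " (participant ", scores$participant_id[bad[1]], ", score ",
           scores$score[bad[1]], ").", call. = FALSE)
    }
  }
  as_multitrial(long, scores, normalized = normalized)
}

#' Write a cohort to disk
#'
#' Emits `features.csv` (long format with a `trial` column), `scores.csv`
#' and, when ground truth is supplied, a `truth.json` sidecar for test
#' harnesses.
#'
#' @param data a [multitrial_dataset()].
#' @param dir output directory (created if needed).
#' @param truth optional `cohort_truth`.
#' @return The directory, invisibly.
#' @export
write_cohort <- function(data, dir, truth = NULL) {
  stopifnot(inherits(data, "multitrial_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(as_tibble(data), file.path(dir, "features.csv"),
                   na = "")
  readr::write_csv(
    tibble::tibble(participant_id = data$participant_ids,
                   score = unname(data$scores)),
    file.path(dir, "scores.csv"))
  if (!is.null(truth)) {
    jsonlite::write_json(
      list(W_star = truth$W_star, b_star = as.list(truth$b_star),
           group_labels = as.list(truth$group_labels),
           ability = as.list(truth$ability),
           score_shift = truth$score_shift,
           score_scale = truth$score_scale,
           noise_sd = truth$noise_sd, seed = truth$seed,
           feature_names = rownames(truth$W_star),
           trial_ids = colnames(truth$W_star)),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory holding `features.csv` and `scores.csv`.
#' @inheritParams read_feature_tables
#' @return A [multitrial_dataset()].
#' @export
read_cohort <- function(dir, normalized = FALSE) {
  read_feature_tables(file.path(dir, "features.csv"),
                      file.path(dir, "scores.csv"),
                      normalized = normalized)
}

#' Serialize / restore a fitted model as JSON
#'
#' The document embeds the weight matrix with its feature and trial
#' labels, biases, solver settings, normalization statistics, the full
#' objective trace and the convergence metadata, so that predictions are
#' reproducible from the file alone.
#'
#' @param model an `mtjl_model`.
#' @param path output / input path.
#' @return `write_mtjl_model()` returns `path` invisibly;
#'   `read_mtjl_model()` returns the restored `mtjl_model`.
#' @export
write_mtjl_model <- function(model, path) {
  stopifnot(inherits(model, "mtjl_model"))
  doc <- list(
    package = "mtjl", format = 1L,
    feature_names = model$feature_names,
    trial_ids = model$trial_ids,
    W = unname(model$W), b = unname(model$b),
    control = unclass(model$control),
    normalization = if (is.null(model$normalization)) NULL else
      list(center = unname(model$normalization$center),
           scale = unname(model$normalization$scale)),
    objective_trace = model$objective_trace,
    n_iter = model$n_iter, converged = model$converged,
    n_participants = model$n_participants
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_mtjl_model
#' @export
read_mtjl_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  ctl <- doc$control
  control <- mtjl_control(lambda = ctl$lambda, gamma = ctl$gamma,
                          delta = ctl$delta, tol = ctl$tol,
                          max_iter = ctl$max_iter, init = ctl$init)
  W <- matrix(doc$W, nrow = length(doc$feature_names),
              dimnames = list(doc$feature_names, doc$trial_ids))
  normalization <- NULL
  if (!is.null(doc$normalization)) {
    dn <- list(doc$feature_names, doc$trial_ids)
    normalization <- list(
      center = matrix(doc$normalization$center,
                      nrow = length(doc$feature_names), dimnames = dn),
      scale = matrix(doc$normalization$scale,
                     nrow = length(doc$feature_names), dimnames = dn))
  }
  structure(
    list(W = W, b = setNames(doc$b, doc$trial_ids),
         objective_trace = doc$objective_trace,
         n_iter = doc$n_iter, converged = doc$converged,
         control = control, feature_names = doc$feature_names,
         trial_ids = doc$trial_ids, normalization = normalization,
         n_participants = doc$n_participants),
    class = "mtjl_model")
}

#' Write an evaluation report
#'
#' JSON summary (embedding the solver settings and base seed that produced
#' it) plus optional flat CSVs of the per-run errors and contribution
#' tables.
#'
#' @param report an `mtjl_evaluation`.
#' @param path path of the JSON report.
#' @param csv_dir optional directory for `per_run.csv`,
#'   `indicator_contributions.csv` and `trial_contributions.csv`.
#' @return `path`, invisibly.
#' @export
write_evaluation_report <- function(report, path, csv_dir = NULL) {
  stopifnot(inherits(report, "mtjl_evaluation"))
  doc <- list(
    package = "mtjl",
    mean_error = report$mean_error, std_error = report$std_error,
    metric = report$metric, n_runs = report$n_runs,
    n_failed = report$n_failed, base_seed = report$base_seed,
    median_iterations = report$median_iterations,
    single_run = report$single_run,
    control = unclass(report$control),
    per_run_error = report$per_run$error,
    indicator_contributions = report$indicator_contributions,
    trial_contributions = report$trial_contributions
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  if (!is.null(csv_dir)) {
    dir.create(csv_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(report$per_run, file.path(csv_dir, "per_run.csv"))
    readr::write_csv(report$indicator_contributions,
                     file.path(csv_dir, "indicator_contributions.csv"))
    readr::write_csv(report$trial_contributions,
                     file.path(csv_dir, "trial_contributions.csv"))
  }
  invisible(path)
}

#' Read a run configuration file
#'
#' YAML key-value file with any of the solver, screening, evaluation and
#' synthetic-generator settings; unspecified keys fall back to the package
#' defaults (lambda = gamma = 1, alpha = 0.05, n_runs = 100, and the
#' default cohort structure N = 74, m = 42, D = 19).
#'
#' @param path YAML file path (or `NULL` for pure defaults).
#' @return A named list with elements `control` ([mtjl_control()]),
#'   `alpha`, `n_runs`, `base_seed`, `metric`, `stratify` and `cohort`
#'   ([cohort_config()]).
#' @export
read_run_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  ctl <- raw$control %||% list()
  cohort <- raw$cohort %||% list()
  list(
    control = mtjl_control(
      lambda = ctl$lambda %||% 1, gamma = ctl$gamma %||% 1,
      delta = ctl$delta %||% 1e-8, tol = ctl$tol %||% 1e-6,
      max_iter = ctl$max_iter %||% 100L, init = ctl$init %||% "ridge"),
    alpha = raw$alpha %||% 0.05,
    n_runs = raw$n_runs %||% 100L,
    base_seed = raw$base_seed %||% 1L,
    metric = raw$metric %||% "mae",
    stratify = raw$stratify %||% FALSE,
    cohort = cohort_config(
      n_participants = cohort$n_participants %||% 74L,
      n_trials = cohort$n_trials %||% 42L,
      true_rank = cohort$true_rank %||% 2L,
      noise_sd = cohort$noise_sd %||% 0.5,
      score_range = unlist(cohort$score_range %||% c(48.8, 90.83)),
      missing_fraction = cohort$missing_fraction %||% 0.1,
      seed = cohort$seed)
  )
}
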