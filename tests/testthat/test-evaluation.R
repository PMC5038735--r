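test_that("z-score normalization uses population SD and training statistics", {
  X <- matrix(c(2, 4, 6, 1, 1, 1), 3, 2,
              dimnames = list(NULL, c("a", "b")))
  d <- suppressWarnings(multitrial_dataset(list(X), scores = c(10, 20, 30)))
  expect_warning(nf <- normalize_features(d), "Zero-variance")
  expect_equal(unname(nf$train$trials[[1]][, "a"]),
               c(-1.2247448, 0, 1.2247448), tolerance = 1e-6)
  expect_equal(unname(nf$train$trials[[1]][, "b"]), c(0, 0, 0))
  # idempotence on already-standardized data
  z <- nf$train$trials[[1]][, "a"]
  d2 <- multitrial_dataset(list(matrix(c(z, z), 3, 2)), c(10, 20, 30))
  nf2 <- normalize_features(d2)
  expect_equal(unname(nf2$train$trials[[1]][, 1]), unname(z),
               tolerance = 1e-10)
  # the test fold is transformed with TRAIN statistics, not its own
  tr <- rand_instance(20, 3, 2, seed = 51)
  te <- rand_instance(10, 3, 2, seed = 52)
  te$trials <- lapply(te$trials, function(X) X + 5)  # shifted test fold
  nf3 <- normalize_features(tr, apply_to = te)
  expect_gt(abs(mean(nf3$apply_to$trials[[1]][, 1])), 0.5)
  expect_lt(abs(mean(nf3$train$trials[[1]][, 1])), 1e-12)
})

test_that("half splits partition participants reproducibly", {
  sim <- simulate_cohort(cohort_config(), seed = 61)
  sp <- split_half(sim$data, seed = 1)
  expect_equal(n_participants(sp$train), 37)
  expect_equal(n_participants(sp$test), 37)
  expect_setequal(c(sp$train$participant_ids, sp$test$participant_ids),
                  sim$data$participant_ids)
  expect_length(intersect(sp$train$participant_ids,
                          sp$test$participant_ids), 0)
  expect_identical(split_half(sim$data, seed = 1)$train_idx, sp$train_idx)
  expect_false(identical(split_half(sim$data, seed = 2)$train_idx,
                         sp$train_idx))
  # odd N: ceiling / floor
  d9 <- rand_instance(9, 2, 2, seed = 62)
  sp9 <- split_half(d9, seed = 3)
  expect_equal(n_participants(sp9$train), 5)
  expect_equal(n_participants(sp9$test), 4)
  # stratified split balances the score median across folds
  sps <- split_half(sim$data, seed = 4, stratify = TRUE)
  med <- median(sim$data$scores)
  expect_equal(sum(sps$train$scores >= med), sum(sps$test$scores >= med),
               tolerance = 1)
})

test_that("error metrics are symmetric and hand-checkable", {
  x <- c(70, 80, 90)
  expect_equal(prediction_error(x, x), 0)
  expect_equal(prediction_error(x + 2, x), 2)
  expect_equal(prediction_error(x + 2, x, metric = "rmse"), 2)
  a <- withr::with_seed(71, runif(10, 50, 90))
  b <- withr::with_seed(72, runif(10, 50, 90))
  expect_equal(prediction_error(a, b), mean(abs(a - b)))
  expect_equal(prediction_error(a, b, "rmse"), sqrt(mean((a - b)^2)))
  expect_equal(prediction_error(a, b), prediction_error(b, a))
  expect_error(prediction_error(a, b[1:5]), "equal length")
})

test_that("contribution summaries match their direct formulas", {
  d <- rand_instance(15, 4, 3, seed = 81)
  fit <- mtjl_fit(d, mtjl_control(), normalize = "none")
  ic <- indicator_contributions(fit)
  expect_equal(sum(ic$contribution), 1, tolerance = 1e-10)
  expect_true(all(ic$contribution >= 0))
  raw <- rowMeans(abs(fit$W))
  expect_equal(ic$contribution, unname(raw / sum(raw)))
  tc <- trial_contributions(fit)
  expect_equal(tc$contribution, unname(colSums(abs(fit$W))))
  expect_equal(tc$contribution_scaled,
               unname(colSums(abs(fit$W)) / max(colSums(abs(fit$W)))))
  # single nonzero row concentrates all contribution
  one <- fit
  one$W[] <- 0
  one$W[2, ] <- 3
  expect_equal(indicator_contributions(one)$contribution,
               c(0, 1, 0, 0))
  # identical columns spread trial contributions evenly
  expect_equal(trial_contributions(one)$contribution_scaled, rep(1, 3))
  zero <- fit
  zero$W[] <- 0
  expect_warning(icz <- indicator_contributions(zero), "uniform")
  expect_equal(icz$contribution, rep(0.25, 4))
  expect_warning(trial_contributions(zero), "zero")
})

test_that("repeated evaluation is reproducible and internally consistent", {
  sim <- simulate_cohort(cohort_config(n_participants = 30, n_trials = 6,
                                       n_features = 5), seed = 91)
  ev <- repeated_evaluation(sim$data, mtjl_control(), n_runs = 6,
                            base_seed = 7)
  ev2 <- repeated_evaluation(sim$data, mtjl_control(), n_runs = 6,
                             base_seed = 7)
  expect_identical(ev$per_run, ev2$per_run)
  ok <- ev$per_run[!ev$per_run$failed, ]
  expect_equal(ev$mean_error, mean(ok$error), tolerance = 1e-12)
  expect_equal(ev$std_error, sd(ok$error), tolerance = 1e-12)
  expect_equal(sum(ev$indicator_contributions$contribution), 1,
               tolerance = 1e-10)
  expect_true(all(ev$indicator_contributions$contribution_mean >= 0))
  expect_equal(sum(ev$indicator_contributions$contribution_mean), 1,
               tolerance = 1e-10)
  expect_s3_class(tidy(ev), "tbl_df")
  expect_equal(glance(ev)$mean_error, ev$mean_error)
  expect_s3_class(autoplot(ev), "ggplot")
  # degenerate single run: sd 0 by convention, flagged
  ev1 <- repeated_evaluation(sim$data, mtjl_control(), n_runs = 1,
                             base_seed = 7)
  expect_equal(ev1$std_error, 0)
  expect_true(ev1$single_run)
})

test_that("a sentinel shift in the test fold never touches the fitted model", {
  sim <- simulate_cohort(cohort_config(n_participants = 24, n_trials = 4,
                                       n_features = 5), seed = 101)
  sp <- split_half(sim$data, seed = 1)
  poisoned <- sp$test
  poisoned$trials <- lapply(poisoned$trials, function(X) X * 10 + 1000)
  nf1 <- normalize_features(sp$train, apply_to = sp$test)
  nf2 <- normalize_features(sp$train, apply_to = poisoned)
  f1 <- mtjl_fit(nf1$train, mtjl_control(), normalize = "none")
  f2 <- mtjl_fit(nf2$train, mtjl_control(), normalize = "none")
  expect_identical(f1$W, f2$W)
  expect_identical(f1$b, f2$b)
})

test_that("holdout error grows with the generator noise level", {
  mean_err <- vapply(c(0.25, 1, 3), function(ns) {
    errs <- vapply(1:4, function(s) {
      sim <- simulate_cohort(cohort_config(n_participants = 40, n_trials = 6,
                                           n_features = 8, noise_sd = ns),
                             seed = 200 + s)
      ev <- repeated_evaluation(sim$data,
                                mtjl_control(lambda = 1e-2, gamma = 1e-2),
                                n_runs = 3, base_seed = s)
      ev$mean_error
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_true(all(diff(mean_err) > 0))
})
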