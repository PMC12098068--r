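test_that("R-squared and RMSE implement the printed formulas", {
  y <- c(1, 2, 3)
  yh <- c(1.1, 1.9, 3.2)
  expect_equal(r_squared(y, yh), 1 - 0.06 / 2, tolerance = 1e-12)
  expect_equal(rmse(y, yh), sqrt(0.06 / 3), tolerance = 1e-12)
  # limits: perfect prediction and the mean predictor
  expect_equal(r_squared(y, y), 1.0)
  expect_equal(r_squared(y, rep(mean(y), 3)), 0.0)
  expect_equal(rmse(y, y), 0.0)
  # translation invariance of RMSE
  expect_equal(rmse(y + 5, yh + 5), rmse(y, yh), tolerance = 1e-12)
  # R2 may be negative; constant truth is rejected, not returned
  expect_lt(r_squared(y, c(3, 2, 1)), 0)
  expect_error(r_squared(c(2, 2, 2), y), "constant")
  expect_error(r_squared(y, c(1, 2)), "lengths differ")
  expect_error(rmse(y, c(1, 2)), "lengths differ")
})

test_that("metric identity R2 = 1 - n RMSE^2 / SS_tot holds on random data", {
  set.seed(8)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    y <- rnorm(n)
    yh <- y + rnorm(n, sd = runif(1, 0.01, 2))
    lhs <- r_squared(y, yh)
    rhs <- 1 - rmse(y, yh)^2 * n / sum((y - mean(y))^2)
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("three-fold partitions are disjoint, exhaustive and balanced", {
  p <- three_fold_partition(440, seed = 1)
  expect_setequal(sort(vapply(p, length, integer(1))), c(146L, 147L, 147L))
  for (s in 1:20) {
    ps <- three_fold_partition(sample(10:100, 1), seed = s)
    all_idx <- unname(unlist(ps))
    expect_identical(sort(all_idx), seq_along(all_idx))
    sizes <- vapply(ps, length, integer(1))
    expect_lte(max(sizes) - min(sizes), 1L)
  }
  expect_identical(three_fold_partition(30, seed = 5),
                   three_fold_partition(30, seed = 5))
  expect_error(three_fold_partition(2, seed = 1), "at least 3")
})

test_that("subject-grouped partitions never split a subject across folds", {
  co <- tiny_cohort()
  p <- three_fold_partition(co, seed = 2, grouping = "subject")
  subj <- lapply(p, function(i) unique(co$meta$subject_id[i]))
  expect_length(Reduce(intersect, subj), 0)
  expect_setequal(unlist(subj), co$profiles$subject_id)
})

test_that("fold aggregation reproduces published table averages", {
  eg <- summarize_folds(data.frame(fold_id = c("A", "B", "C"),
                                   test_r2 = c(0.61, 0.65, 0.64)))
  expect_equal(eg$mean_test_r2, mean(c(0.61, 0.65, 0.64)), tolerance = 1e-12)
  expect_equal(round(eg$mean_test_r2, 2), 0.63)
  all_groups <- summarize_folds(data.frame(test_r2 = c(0.61, 0.64, 0.61),
                                           test_rmse = c(0.2, 0.21, 0.19)))
  expect_equal(round(all_groups$mean_test_r2, 2), 0.62)
  expect_equal(all_groups$mean_test_rmse, 0.2, tolerance = 1e-12)
})

test_that("run_cv retrains per fold and aggregates over the three rounds", {
  co <- tiny_cohort()
  cv <- run_cv(co, tiny_spec("hybrid"),
               train_config(epochs = 5, batch_size = 8), seed = 4)
  expect_identical(cv$folds$fold_id, c("A", "B", "C"))
  expect_identical(cv$folds$n_train + cv$folds$n_test, rep(24L, 3))
  expect_true(all(cv$folds$test_r2 <= 1))
  expect_equal(cv$mean_test_r2, mean(cv$folds$test_r2), tolerance = 1e-12)
  expect_false(cv$incomplete)
  cv2 <- run_cv(co, tiny_spec("hybrid"),
                train_config(epochs = 5, batch_size = 8), seed = 4)
  expect_identical(cv$folds, cv2$folds)
})

test_that("model comparison shares folds and reports one row per model", {
  co <- tiny_cohort()
  cfg <- train_config(epochs = 5, batch_size = 8)
  cmp <- compare_models(co, list(a = tiny_spec("hybrid"),
                                 b = tiny_spec("hybrid"),
                                 lstm = tiny_spec("lstm")),
                        cfg, seed = 6)
  expect_identical(nrow(cmp$table), 3L)
  # duplicate specs under the same seed give identical results
  expect_equal(cmp$summaries$a$folds, cmp$summaries$b$folds)
  # identical partition across models
  expect_identical(cmp$summaries$a$partition, cmp$summaries$lstm$partition)
  expect_true(all(diff(cmp$table$mean_test_r2) <= 0))
})

test_that("subject-grouped CV is the honest estimate under subject-level structure", {
  # labels dominated by a per-subject effect: cycle-level splits let the
  # model recognise subjects (leakage), subject-grouped splits do not
  co <- generate_cohort(9, 4, 0.5, seed = 31)
  set.seed(99)
  eff <- rnorm(9, 0, 1)
  y <- eff[co$meta$subject_id] + rnorm(length(co$labels), 0, 0.05)
  cfg <- train_config(epochs = 30, batch_size = 8)
  cv_cycle <- run_cv(co, tiny_spec("hybrid"), cfg, seed = 7,
                     grouping = "cycle", labels = y)
  cv_subj <- run_cv(co, tiny_spec("hybrid"), cfg, seed = 7,
                    grouping = "subject", labels = y)
  expect_lte(cv_subj$mean_test_r2, cv_cycle$mean_test_r2)
})
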