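#' Coefficient of determination
#'
#' `R^2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`. May be negative
#' for predictions worse than the mean predictor. A constant truth vector
#' makes the denominator zero and is rejected rather than returned as a
#' number.
#'
#' @param y True values (length >= 2, not constant).
#' @param yhat Predictions, same length.
#' @return R-squared (numeric scalar).
#' @export
r_squared <- function(y, yhat) {
  if (length(y) != length(yhat))
    abort("y and yhat lengths differ (%d vs %d)", length(y), length(yhat))
  if (length(y) < 2) abort("need at least 2 observations")
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0)
    abort("y is constant; R-squared is undefined (zero total sum of squares)")
  1 - sum((y - yhat)^2) / ss_tot
}

#' Root mean squared error
#'
#' `RMSE = sqrt(mean((y - yhat)^2))`, in the units of `y` (body weights
#' for ACL force labels).
#'
#' @param y True values.
#' @param yhat Predictions, same length.
#' @return Non-negative numeric scalar.
#' @export
rmse <- function(y, yhat) {
  if (length(y) != length(yhat))
    abort("y and yhat lengths differ (%d vs %d)", length(y), length(yhat))
  if (length(y) < 1) abort("need at least 1 observation")
  sqrt(mean((y - yhat)^2))
}

#' Random three-fold partition
#'
#' Randomly divides the records into three non-overlapping, exhaustive
#' subsets A, B and C whose sizes differ by at most one unit of the
#' grouping level. With `grouping = "cycle"` records are split directly
#' (440 records give sizes 147/147/146); with `grouping = "subject"`
#' subjects are split and a subject's cycles never straddle folds, which
#' avoids leaking subject identity across folds.
#'
#' @param dataset A `gait_cohort`, or an integer number of records.
#' @param seed Integer seed (the partition is deterministic given it).
#' @param grouping `"cycle"` or `"subject"`.
#' @param subject_ids Record-level subject ids; required for subject
#'   grouping when `dataset` is a plain count.
#' @return Named list of record index vectors `A`, `B`, `C`.
#' @export
three_fold_partition <- function(dataset, seed = 1,
                                 grouping = c("cycle", "subject"),
                                 subject_ids = NULL) {
  grouping <- match.arg(grouping)
  if (inherits(dataset, "gait_cohort")) {
    n <- length(dataset$labels)
    subject_ids <- dataset$meta$subject_id
  } else {
    n <- as.integer(dataset)
  }
  split3 <- function(units) {
    k <- length(units)
    if (k < 3) abort("need at least 3 %s units to form 3 folds",
                     if (is.null(subject_ids)) "record" else "partition")
    sizes <- rep(k %/% 3, 3) + (seq_len(3) <= k %% 3)
    shuffled <- with_seed(derive_seed(seed, 3), sample(units))
    split(shuffled, rep(c("A", "B", "C"), sizes))
  }
  if (grouping == "cycle") {
    parts <- split3(seq_len(n))
  } else {
    if (is.null(subject_ids))
      abort("subject grouping needs subject ids")
    subj_parts <- split3(unique(subject_ids))
    parts <- lapply(subj_parts, function(s) which(subject_ids %in% s))
  }
  lapply(parts[c("A", "B", "C")], function(x)
    sort(as.integer(unname(x))))
}

#' Aggregate per-fold results into a cross-validation summary
#'
#' Computes the cross-fold averages from a table of per-fold results; the
#' mean test R-squared is the arithmetic mean of the fold test R-squared
#' values (and likewise for RMSE). Accepts hand-entered fold values, so
#' published fold tables can be re-aggregated directly.
#'
#' @param folds A `data.frame` with at least a `test_r2` column;
#'   `train_r2`, `test_rmse`, `fold_id`, `n_train`, `n_test` are carried
#'   through when present.
#' @param incomplete Mark the summary as incomplete (some folds failed)?
#' @return A list of class `cv_summary` with `folds`, `mean_test_r2`,
#'   `mean_test_rmse` (NA when absent) and `incomplete`.
#' @export
summarize_folds <- function(folds, incomplete = FALSE) {
  stopifnot(is.data.frame(folds), "test_r2" %in% names(folds))
  structure(list(folds = folds,
                 mean_test_r2 = mean(folds$test_r2, na.rm = TRUE),
                 mean_test_rmse = if ("test_rmse" %in% names(folds))
                   mean(folds$test_rmse, na.rm = TRUE) else NA_real_,
                 incomplete = incomplete),
            class = "cv_summary")
}

#' @export
print.cv_summary <- function(x, ...) {
  cat("<cv_summary>", if (x$incomplete) "(incomplete)" else "", "\n")
  f <- x$folds
  num <- vapply(f, is.numeric, logical(1))
  f[num] <- lapply(f[num], round, digits = 2)
  print(f, row.names = FALSE)
  cat(sprintf("mean test R2 = %.2f", x$mean_test_r2))
  if (is.finite(x$mean_test_rmse))
    cat(sprintf(", mean test RMSE = %.2f BW", x$mean_test_rmse))
  cat("\n")
  invisible(x)
}

#' Three-fold cross-validation of one model
#'
#' Runs the three-round protocol: subsets A/B/C are held out in turn as
#' the test set while the other two form the training set; a model is
#' retrained from scratch each round with a fold-specific seed derived
#' from the master seed, and the per-round train/test R-squared and test
#' RMSE are averaged over rounds. The static feature scaler is refitted
#' on each round's training subjects only (no leakage of test-set
#' statistics).
#'
#' @param cohort A `gait_cohort`.
#' @param spec A [model_spec()].
#' @param config A [train_config()].
#' @param seed Master seed.
#' @param grouping Partition grouping, see [three_fold_partition()].
#' @param include_rom_t3 Include stage-T3 ROM among the static features?
#' @param labels Optional label override (defaults to the cohort labels).
#' @return A `cv_summary` (see [summarize_folds()]) with additional
#'   elements `partition` and `predictions` (per-fold test-set truth and
#'   predictions).
#' @export
run_cv <- function(cohort, spec, config = train_config(), seed = 1,
                   grouping = "cycle", include_rom_t3 = FALSE,
                   labels = NULL) {
  stopifnot(inherits(cohort, "gait_cohort"))
  y_all <- labels %||% cohort$labels
  parts <- three_fold_partition(cohort, seed = seed, grouping = grouping)
  fold_ids <- names(parts)
  rows <- vector("list", 3)
  preds <- vector("list", 3)
  names(preds) <- fold_ids
  incomplete <- FALSE
  for (k in seq_len(3)) {
    test_idx <- parts[[k]]
    train_idx <- sort(unlist(parts[-k], use.names = FALSE))
    res <- tryCatch({
      S_tr <- S_te <- NULL
      if (spec$kind == "hybrid") {
        train_subj <- unique(cohort$meta$subject_id[train_idx])
        scaler <- fit_static_scaler(
          cohort$profiles[cohort$profiles$subject_id %in% train_subj, ,
                          drop = FALSE],
          include_rom_t3 = include_rom_t3)
        S_tr <- cohort_statics(cohort, scaler, train_idx)
        S_te <- cohort_statics(cohort, scaler, test_idx)
      }
      fit <- train_model(cohort$series[, , train_idx, drop = FALSE], S_tr,
                         y_all[train_idx], spec, config,
                         seed = derive_seed(seed, 10 + k))
      p_tr <- predict(fit, cohort$series[, , train_idx, drop = FALSE], S_tr)
      p_te <- predict(fit, cohort$series[, , test_idx, drop = FALSE], S_te)
      list(row = data.frame(fold_id = fold_ids[k],
                            n_train = length(train_idx),
                            n_test = length(test_idx),
                            train_r2 = r_squared(y_all[train_idx], p_tr),
                            test_r2 = r_squared(y_all[test_idx], p_te),
                            test_rmse = rmse(y_all[test_idx], p_te),
                            stringsAsFactors = FALSE),
           pred = data.frame(record_id = test_idx,
                             y = y_all[test_idx], yhat = p_te))
    }, error = function(e) {
      warning(sprintf("fold %s failed: %s", fold_ids[k],
                      conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (is.null(res)) {
      incomplete <- TRUE
      rows[[k]] <- data.frame(fold_id = fold_ids[k],
                              n_train = length(train_idx),
                              n_test = length(test_idx),
                              train_r2 = NA_real_, test_r2 = NA_real_,
                              test_rmse = NA_real_, stringsAsFactors = FALSE)
    } else {
      rows[[k]] <- res$row
      preds[[k]] <- res$pred
    }
  }
  out <- summarize_folds(do.call(rbind, rows), incomplete = incomplete)
  out$partition <- parts
  out$predictions <- preds
  out
}

#' Cross-validated comparison of the three architectures
#'
#' Evaluates several model specifications with [run_cv()] on the identical
#' partition and fold seeds, and tabulates the mean test R-squared of each
#' (sorted best first).
#'
#' @param cohort A `gait_cohort`.
#' @param specs Named list of [model_spec()]s (e.g. hybrid, tcn_only,
#'   lstm).
#' @param config A [train_config()].
#' @param seed Master seed shared by all models.
#' @param grouping Partition grouping.
#' @param include_rom_t3 Passed to [run_cv()].
#' @return List with `table` (model, mean_test_r2, mean_test_rmse) and
#'   `summaries` (per-model `cv_summary`).
#' @export
compare_models <- function(cohort, specs, config = train_config(), seed = 1,
                           grouping = "cycle", include_rom_t3 = FALSE) {
  stopifnot(is.list(specs), length(specs) >= 1)
  if (is.null(names(specs)) || any(names(specs) == ""))
    abort("specs must be a named list")
  summaries <- lapply(specs, function(sp)
    run_cv(cohort, sp, config, seed = seed, grouping = grouping,
           include_rom_t3 = include_rom_t3))
  tab <- data.frame(
    model = names(specs),
    mean_test_r2 = vapply(summaries, `[[`, numeric(1), "mean_test_r2"),
    mean_test_rmse = vapply(summaries, `[[`, numeric(1), "mean_test_rmse"),
    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$mean_test_r2), ]
  rownames(tab) <- NULL
  list(table = tab, summaries = summaries)
}
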