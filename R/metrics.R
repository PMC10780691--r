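#' Classification metrics
#'
#' Standard confusion-matrix metrics at a 0.5 threshold — precision,
#' sensitivity (recall), specificity, F1, accuracy — plus AUC ROC computed
#' by the rank statistic (Mann-Whitney), all reported as percentages.
#'
#' @param y_true binary labels (0/1), positive class 1.
#' @param y_prob probabilities of class 1, in `[0, 1]`.
#' @return a `metrics_report` list: `precision`, `sensitivity`,
#'   `specificity`, `f1`, `accuracy`, `auc_roc` (percent; `auc_roc` is `NA`
#'   with a warning when only one class is present).
#' @export
compute_metrics <- function(y_true, y_prob) {
  stopifnot(length(y_true) == length(y_prob),
            all(y_true %in% c(0, 1)),
            all(y_prob >= 0 & y_prob <= 1))
  y_hat <- as.integer(y_prob >= 0.5)
  tp <- sum(y_hat == 1 & y_true == 1)
  fp <- sum(y_hat == 1 & y_true == 0)
  fn <- sum(y_hat == 0 & y_true == 1)
  tn <- sum(y_hat == 0 & y_true == 0)
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(sens) && prec + sens > 0) {
    2 * prec * sens / (prec + sens)
  } else {
    NA_real_
  }
  acc <- (tp + tn) / length(y_true)
  n1 <- sum(y_true == 1)
  n0 <- sum(y_true == 0)
  if (n1 == 0 || n0 == 0) {
    warning("AUC undefined: only one class present")
    auc <- NA_real_
  } else {
    r <- rank(y_prob)
    auc <- (sum(r[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  structure(list(precision = 100 * prec, sensitivity = 100 * sens,
                 specificity = 100 * spec, f1 = 100 * f1,
                 accuracy = 100 * acc, auc_roc = 100 * auc),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  for (nm in names(x)) cat(sprintf("%-12s %6.2f%%\n", nm, x[[nm]]))
  invisible(x)
}

#' Plan an interpatient cross-validation
#'
#' Subject-disjoint folds: in every fold a class-balanced set of subjects
#' (14 + 14 when both classes have at least 15 subjects, otherwise a
#' documented proportional fallback of about 70% per class) is drawn for
#' training and all remaining subjects are tested. Folds are deterministic
#' given `seed`; each fold also carries its own projection-matrix seed so
#' the protected arm uses a fresh matrix per fold.
#'
#' @param n_folds number of folds (reference protocol: 20).
#' @param train_per_class training subjects per class (reference: 14);
#'   `NULL` selects 14 when possible, otherwise the proportional fallback.
#' @param seed plan seed.
#' @return a `cv_plan` list.
#' @export
cv_plan <- function(n_folds = 20L, train_per_class = NULL, seed = 1L) {
  structure(list(n_folds = as.integer(n_folds),
                 train_per_class = train_per_class,
                 seed = as.integer(seed)),
            class = "cv_plan")
}

#' Materialize subject-disjoint folds
#'
#' @param subject_labels named character vector: `class_label` per
#'   `subject_id` (names).
#' @param plan a [cv_plan()].
#' @return list of folds, each with `train`, `test` (subject ids) and
#'   `projection_seed`.
#' @export
interpatient_split <- function(subject_labels, plan = cv_plan()) {
  classes <- sort(unique(subject_labels))
  if (length(classes) != 2) stop("exactly two classes are required")
  by_class <- split(names(subject_labels), subject_labels)
  n_min <- min(lengths(by_class))
  tpc <- plan$train_per_class
  if (is.null(tpc)) {
    tpc <- if (n_min >= 15) 14L else max(1L, floor(0.7 * n_min))
  }
  if (tpc >= n_min) {
    stop("too few subjects: training would leave a class without test subjects")
  }
  with_local_seed(plan$seed, {
    fold_seeds <- sample.int(.Machine$integer.max %/% 4L, plan$n_folds)
    lapply(seq_len(plan$n_folds), function(f) {
      train <- unlist(lapply(by_class, function(ids) {
        sample(ids, tpc)
      }), use.names = FALSE)
      test <- setdiff(names(subject_labels), train)
      list(train = train, test = test,
           projection_seed = fold_seeds[f])
    })
  })
}

#' Metrics report serialization
#'
#' Per-fold metrics as CSV and the mean summary as JSON.
#' @param per_fold data frame of per-fold metrics.
#' @param path_csv,path_json output paths (either may be `NULL`).
#' @return mean metrics (named list), invisibly.
#' @export
write_metrics <- function(per_fold, path_csv = NULL, path_json = NULL) {
  means <- as.list(colMeans(per_fold[, setdiff(names(per_fold), "fold"),
                                     drop = FALSE], na.rm = TRUE))
  if (!is.null(path_csv)) utils::write.csv(per_fold, path_csv, row.names = FALSE)
  if (!is.null(path_json)) {
    jsonlite::write_json(list(mean = means, per_fold = per_fold),
                         path_json, auto_unbox = TRUE, digits = NA)
  }
  invisible(means)
}
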