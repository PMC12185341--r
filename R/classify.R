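#' Define a repeated random train/test split scheme
#'
#' @param train_fraction Fraction of cells used for training each repeat.
#' @param n_repeats Number of independent random splits.
#' @param stratified Stratify splits by class label (default) so both halves
#'   preserve class proportions.
#' @param group_aware Split at the subject level instead of the cell level.
#'   Cell-level splitting matches single-cell classification but lets a model
#'   exploit subject identity when cells of one subject land in both halves;
#'   subject-level splits close that leak at the cost of coarser granularity.
#' @param seed Integer seed; all per-repeat randomness derives from it.
#' @return An object of class `split_scheme`.
#' @export
split_scheme <- function(train_fraction = 0.7, n_repeats = 10L,
                         stratified = TRUE, group_aware = FALSE, seed = 1L) {
  check_number(train_fraction, "train_fraction")
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("`train_fraction` must be in (0, 1).")
  }
  check_number(n_repeats, "n_repeats", min = 1, integer = TRUE)
  check_number(seed, "seed", integer = TRUE)
  structure(
    list(train_fraction = train_fraction, n_repeats = as.integer(n_repeats),
         stratified = isTRUE(stratified), group_aware = isTRUE(group_aware),
         seed = as.integer(seed)),
    class = "split_scheme"
  )
}

# One train index vector; stratified by label unless disabled. Retries are
# bounded: a split that drops a class from the training half is redrawn.
draw_split <- function(labels, subjects, scheme) {
  n <- length(labels)
  for (attempt in 1:25) {
    if (scheme$group_aware) {
      subj <- unique(subjects)
      tr_subj <- sample(subj, max(1, round(scheme$train_fraction * length(subj))))
      idx <- which(subjects %in% tr_subj)
    } else if (scheme$stratified) {
      idx <- unlist(lapply(split(seq_len(n), labels), function(ii) {
        k <- max(1, round(scheme$train_fraction * length(ii)))
        sample(ii, k)
      }), use.names = FALSE)
    } else {
      idx <- sample(n, max(1, round(scheme$train_fraction * n)))
    }
    if (length(idx) < n &&
        all(levels(labels) %in% labels[idx]) &&
        all(levels(labels) %in% labels[-idx])) {
      return(idx)
    }
  }
  abort("Could not draw a split with every class in both halves.")
}

#' Repeated-holdout random-forest classification
#'
#' The evaluation harness behind every accuracy figure in the package: for
#' each of `n_repeats` repeats a fresh random train/test partition is drawn
#' (70/30 by default, stratified by class), a random forest is fit on the
#' training cells and its plain accuracy on the held-out cells is recorded.
#' The report aggregates per-repeat accuracies (mean and sample SD, in
#' percent), confusion matrices and mean feature importances, and is a pure
#' function of the data, the scheme and the model parameters.
#'
#' @param data Tibble with one row per cell: a label column, feature columns,
#'   and (for `group_aware` schemes) a `subject_id` column.
#' @param label_col Name of the label column.
#' @param scheme A [split_scheme()].
#' @param feature_cols Feature column names; defaults to every numeric column
#'   other than the label and identifiers.
#' @param ntree,mtry Random-forest size and per-split feature count
#'   (defaults: 500 trees, floor(sqrt(p))).
#' @return An object of class `rf_report`.
#' @export
repeated_holdout <- function(data, label_col = "label", scheme = split_scheme(),
                             feature_cols = NULL, ntree = 500L, mtry = NULL) {
  stopifnot(inherits(scheme, "split_scheme"))
  if (!label_col %in% names(data)) {
    abort(sprintf("Label column `%s` not found.", label_col))
  }
  labels <- factor(data[[label_col]])
  if (nlevels(labels) < 2) abort("Need at least 2 label classes.")
  if (min(table(labels)) < 4) abort("Need at least 4 cells per class.")
  if (is.null(feature_cols)) {
    drop_cols <- c(label_col, "cell_id", "subject_id", "diagnosis",
                   "treatment", "compartment")
    feature_cols <- setdiff(names(data)[vapply(data, is.numeric, TRUE)],
                            drop_cols)
  }
  if (length(feature_cols) == 0) abort("No feature columns found.")
  if (anyNA(data[feature_cols])) abort("Feature columns contain missing values.")
  X <- as.data.frame(data[feature_cols])
  subjects <- if ("subject_id" %in% names(data)) data$subject_id else
    as.character(seq_len(nrow(data)))
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(length(feature_cols))))

  seeds <- derive_seeds(scheme$seed, scheme$n_repeats)
  per_repeat <- vector("list", scheme$n_repeats)
  confusions <- vector("list", scheme$n_repeats)
  importances <- matrix(0, length(feature_cols), scheme$n_repeats,
                        dimnames = list(feature_cols, NULL))
  for (r in seq_len(scheme$n_repeats)) {
    res <- with_seed(seeds[r], {
      idx <- draw_split(labels, subjects, scheme)
      fit <- randomForest::randomForest(
        x = X[idx, , drop = FALSE], y = labels[idx],
        ntree = ntree, mtry = mtry)
      pred <- stats::predict(fit, X[-idx, , drop = FALSE])
      truth <- labels[-idx]
      cm <- table(truth = truth, predicted = pred)
      recalls <- diag(cm) / pmax(rowSums(cm), 1)
      list(acc = 100 * mean(pred == truth),
           bal = 100 * mean(recalls),
           cm = cm,
           imp = randomForest::importance(fit)[, 1])
    })
    per_repeat[[r]] <- tibble(repeat_id = r, accuracy = res$acc,
                              balanced_accuracy = res$bal)
    confusions[[r]] <- res$cm
    importances[, r] <- res$imp
  }
  per_repeat <- bind_rows(per_repeat)
  structure(
    list(
      per_repeat = per_repeat,
      mean_accuracy = mean(per_repeat$accuracy),
      sd_accuracy = sd(per_repeat$accuracy),
      confusion = confusions,
      importance = tibble(feature = feature_cols,
                          importance = rowMeans(importances)) %>%
        arrange(dplyr::desc(.data$importance)),
      classes = levels(labels),
      n_cells = nrow(data),
      scheme = scheme,
      model_params = list(ntree = ntree, mtry = mtry),
      task = NULL, subset = NULL
    ),
    class = "rf_report"
  )
}

#' Mean and SD of per-repeat test accuracies
#'
#' @param report An `rf_report`.
#' @return Named numeric vector `c(mean, sd)`, in percent; SD is the sample
#'   SD (n - 1) and `NA` for a single repeat.
#' @export
accuracy_summary <- function(report) {
  stopifnot(inherits(report, "rf_report"))
  c(mean = report$mean_accuracy, sd = report$sd_accuracy)
}

#' Run a named classification task on a feature table
#'
#' Builds the labelled dataset for a task — `"diagnosis"`, `"treatment"` or
#' `"diagnosis_x_treatment"` (the combined label) — after applying optional
#' metadata filters (e.g. restrict the diagnosis task to vehicle-treated
#' cells), and delegates to [repeated_holdout()].
#'
#' @param features Tibble from [dft_features()] or [texture_features_cohort()]
#'   (metadata + numeric feature columns).
#' @param task One of `"diagnosis"`, `"treatment"`, `"diagnosis_x_treatment"`.
#' @param filters Named character vector of metadata filters, e.g.
#'   `c(treatment = "DMSO")`.
#' @param scheme A [split_scheme()].
#' @param ... Passed to [repeated_holdout()] (e.g. `ntree`).
#' @return An `rf_report` annotated with the task and subset.
#' @export
run_task <- function(features, task = c("diagnosis", "treatment",
                                        "diagnosis_x_treatment"),
                     filters = NULL, scheme = split_scheme(), ...) {
  task <- match.arg(task)
  data <- features
  if (!is.null(filters)) {
    for (col in names(filters)) {
      if (!col %in% names(data)) abort(sprintf("Filter column `%s` missing.", col))
      data <- data[data[[col]] %in% filters[[col]], , drop = FALSE]
    }
  }
  if (nrow(data) == 0) abort("No cells remain after filtering.")
  data$label <- switch(
    task,
    diagnosis = data$diagnosis,
    treatment = data$treatment,
    diagnosis_x_treatment = paste(data$diagnosis, data$treatment, sep = ":")
  )
  if (length(unique(data$label)) < 2) {
    abort(sprintf("Task `%s` with filter [%s] yields a single class.", task,
                  paste(names(filters), filters, sep = "=", collapse = ", ")))
  }
  report <- repeated_holdout(data, label_col = "label", scheme = scheme, ...)
  report$task <- task
  report$subset <- filters
  report
}

#' @export
print.rf_report <- function(x, ...) {
  cat("<rf_report>", if (!is.null(x$task)) paste0(" task: ", x$task), "\n")
  if (!is.null(x$subset)) {
    cat("  subset: ", paste(names(x$subset), x$subset, sep = "=",
                            collapse = ", "), "\n")
  }
  cat(sprintf("  accuracy: %.1f%% +/- %.1f%% over %d repeats (%d cells, %d classes)\n",
              x$mean_accuracy, x$sd_accuracy, nrow(x$per_repeat), x$n_cells,
              length(x$classes)))
  if (!x$scheme$group_aware) {
    cat("  note: cell-level splits; cells of one subject can appear in both halves.\n")
  }
  invisible(x)
}
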