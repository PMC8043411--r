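#' Z-normalize a feature table
#'
#' Centers each feature column on its mean and divides by its sample SD
#' across all sounds. Constant columns cannot be scaled; they are set to all
#' zeros with a warning.
#'
#' @param table a [feature_table] with >= 2 rows.
#' @return The normalized [feature_table] (`normalized = TRUE`).
#' @export
znormalize <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (nrow(table$values) < 2) stop("need >= 2 sounds to normalize")
  v <- table$values
  mu <- colMeans(v)
  sdv <- apply(v, 2, stats::sd)
  const <- sdv == 0
  if (any(const)) {
    warning("constant feature columns set to zero: ",
            paste(table$feature_names[const], collapse = ", "))
    sdv[const] <- 1
  }
  v <- sweep(sweep(v, 2, mu), 2, sdv, "/")
  v[, const] <- 0
  out <- table
  out$values <- v
  out$normalized <- TRUE
  out
}

#' Cross-validated multiclass SVM classification
#'
#' Reproduces the acoustic-classification design: features z-normalized
#' across all sounds, a 1-vs-1 support vector machine with a third-order
#' inhomogeneous polynomial kernel `(gamma * u.v + 1)^3` (cost 1, coef0 1,
#' the kernel family of the reference toolbox), and stratified k-fold
#' cross-validation in which every sound serves exactly once as a test
#' point. Predictions from all folds are aggregated into one confusion
#' matrix. 1-vs-1 voting ties are broken by the earliest class in the
#' category order.
#'
#' @param table a [feature_table]; normalized automatically if not already.
#' @param n_folds number of folds (default 5); every class must have at
#'   least `n_folds` members.
#' @param kernel_degree polynomial kernel degree (default 3).
#' @param seed integer seed for the stratified fold assignment.
#' @param cost SVM regularization parameter (default 1).
#' @return A list of class `classification_result`: `confusion` (K x K
#'   counts, rows = true), `overall_accuracy`, `per_class_accuracy`,
#'   `chance_level` (1/K), `fold_assignment`, `seed`.
#' @export
crossval_classify <- function(table, n_folds = 5, kernel_degree = 3,
                              seed = 1L, cost = 1) {
  stopifnot(inherits(table, "feature_table"))
  if (!table$normalized) table <- znormalize(table)
  labels <- factor(table$class_labels, levels = class_levels(table$class_labels))
  counts <- table(labels)
  if (any(counts < n_folds)) {
    stop("every class needs >= n_folds members; smallest has ", min(counts))
  }
  n <- nrow(table$values)
  fold <- integer(n)
  withr::with_seed(as.integer(seed), {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
  })
  pred <- factor(rep(NA_character_, n), levels = levels(labels))
  for (f in seq_len(n_folds)) {
    test <- fold == f
    fit <- svm_fit(table$values[!test, , drop = FALSE], labels[!test],
                   kernel_degree, cost)
    pred[test] <- svm_predict(fit, table$values[test, , drop = FALSE])
  }
  res <- classification_result(true = labels, predicted = pred)
  res$fold_assignment <- stats::setNames(fold, table$sound_ids)
  res$seed <- as.integer(seed)
  res
}

#' Cross-corpus classification
#'
#' Fits the SVM on the full training table and evaluates it on the full test
#' table (e.g., train on screams, test on nonverbal affect bursts, and vice
#' versa). Feature names and label vocabularies must agree. Each table is
#' z-normalized within itself, matching the per-corpus normalization of the
#' feature extraction.
#'
#' @param train_table,test_table [feature_table]s with identical
#'   `feature_names` and label vocabularies.
#' @param kernel_degree,cost SVM settings as in [crossval_classify()].
#' @return A `classification_result` for the test table.
#' @export
cross_classify <- function(train_table, test_table, kernel_degree = 3,
                           cost = 1) {
  stopifnot(inherits(train_table, "feature_table"),
            inherits(test_table, "feature_table"))
  if (!identical(train_table$feature_names, test_table$feature_names)) {
    differing <- union(setdiff(train_table$feature_names, test_table$feature_names),
                       setdiff(test_table$feature_names, train_table$feature_names))
    stop("feature name mismatch: ", paste(differing, collapse = ", "))
  }
  if (!setequal(unique(train_table$class_labels), unique(test_table$class_labels))) {
    stop("label vocabularies differ between tables")
  }
  if (!train_table$normalized) train_table <- znormalize(train_table)
  if (!test_table$normalized) test_table <- znormalize(test_table)
  lv <- class_levels(train_table$class_labels)
  ytr <- factor(train_table$class_labels, levels = lv)
  yte <- factor(test_table$class_labels, levels = lv)
  fit <- svm_fit(train_table$values, ytr, kernel_degree, cost)
  pred <- svm_predict(fit, test_table$values)
  classification_result(true = yte, predicted = pred)
}

# canonical class ordering: taxonomy order for scream types, else sorted
class_levels <- function(labels) {
  u <- unique(labels)
  if (all(u %in% scream_types())) scream_types()[scream_types() %in% u] else sort(u)
}

svm_fit <- function(x, y, degree, cost) {
  # inhomogeneous polynomial kernel: coef0 = 1 admits linear terms, matching
  # the conventional (1 + u.v)^degree form
  e1071::svm(x = x, y = y, kernel = "polynomial", degree = degree,
             coef0 = 1, cost = cost, scale = FALSE)
}

svm_predict <- function(fit, x) stats::predict(fit, x)

#' Assemble a classification result
#'
#' @param true,predicted factors with identical levels.
#' @return A list of class `classification_result` with the confusion
#'   matrix (rows = true class), overall and per-class accuracy, and the
#'   analytic chance level 1/K.
#' @export
classification_result <- function(true, predicted) {
  stopifnot(identical(levels(true), levels(predicted)))
  conf <- table(true = true, predicted = predicted)
  conf <- unclass(conf)
  total <- sum(conf)
  row_tot <- rowSums(conf)
  structure(list(
    confusion = conf,
    overall_accuracy = sum(diag(conf)) / total,
    per_class_accuracy = ifelse(row_tot > 0, diag(conf) / row_tot, NA_real_),
    chance_level = 1 / nlevels(true),
    n = total), class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification_result> overall accuracy %.1f%% (chance %.1f%%), n = %d\n",
              100 * x$overall_accuracy, 100 * x$chance_level, x$n))
  invisible(x)
}

#' Read/write feature tables as delimited text
#'
#' Tab-separated with a header; first two columns `sound_id` and
#' `class_label`, remaining columns the features.
#'
#' @param table a [feature_table].
#' @param path file path.
#' @return `write_feature_table` returns `path` invisibly;
#'   `read_feature_table` returns a [feature_table].
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  df <- data.frame(sound_id = table$sound_ids, class_label = table$class_labels,
                   table$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("sound_id", "class_label") %in% names(df))) {
    stop("feature table file must have sound_id and class_label columns")
  }
  feats <- setdiff(names(df), c("sound_id", "class_label"))
  feature_table(as.matrix(df[feats]), df$sound_id, df$class_label, feats)
}
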