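# Feed-forward neural-network classification of feature vectors, stratified
# k-fold cross-validation, and the confusion-matrix metric suite.

#' @importFrom nnet nnet
NULL

#' Classifier training configuration
#'
#' @param hidden hidden-layer size; `NULL` (default) uses 8, which the
#'   quasi-Newton trainer handles comfortably (its memory and per-iteration
#'   cost grow with the square of the weight count).
#' @param epochs maximum training iterations (default 500).
#' @param decay L2 weight decay (default 1e-2); the network is fit by
#'   quasi-Newton optimization, so decay (not a step size) is the exposed
#'   regularization knob.
#' @param seed RNG seed for weight initialization.
#' @return an object of class `"classifier_config"`.
#' @export
classifier_config <- function(hidden = NULL, epochs = 500, decay = 1e-2,
                              seed = 1) {
  structure(list(hidden = hidden, epochs = epochs, decay = decay,
                 seed = seed),
            class = "classifier_config")
}

#' Label levels used throughout: normal = negative, abnormal = positive
#' @noRd
label_levels <- c("normal", "abnormal")

#' @noRd
feature_matrix <- function(data, feature_cols) {
  x <- as.matrix(data[feature_cols])
  if (!is.numeric(x)) stop("feature columns must be numeric", call. = FALSE)
  if (anyNA(x) || any(!is.finite(x))) {
    stop("features contain missing or non-finite values", call. = FALSE)
  }
  x
}

#' @noRd
infer_feature_cols <- function(data, label_col, id_col = "id") {
  setdiff(names(data), c(label_col, id_col))
}

#' Train the feed-forward network on a feature table
#'
#' Standardizes each feature (mean 0, sd 1; constant features are left
#' centred), then fits a single-hidden-layer feed-forward network with a
#' logistic output by back-propagated gradient optimization (via
#' [nnet::nnet()]) under a fixed seed. The scaler is frozen into the model and
#' re-applied at prediction time. A training set with no informative feature
#' (all constant) still returns a model, flagged `degenerate`.
#'
#' @param data tibble with feature columns and a binary label column with
#'   levels `"normal"`/`"abnormal"` (at least 2 samples of each).
#' @param config a [classifier_config()].
#' @param label_col,id_col column names (the id column is ignored if absent).
#' @return an object of class `"cervitex_model"`.
#' @export
fit_classifier <- function(data, config = classifier_config(),
                           label_col = "label", id_col = "id") {
  stopifnot(is.data.frame(data), label_col %in% names(data))
  y <- factor(as.character(data[[label_col]]), levels = label_levels)
  if (anyNA(y)) {
    stop("labels must be 'normal' or 'abnormal'", call. = FALSE)
  }
  if (any(table(y) < 2)) {
    stop("need at least 2 samples of each class", call. = FALSE)
  }
  feature_cols <- infer_feature_cols(data, label_col, id_col)
  x <- feature_matrix(data, feature_cols)
  center <- colMeans(x)
  scale_ <- apply(x, 2, stats::sd)
  constant <- scale_ < 1e-12
  scale_[constant] <- 1
  xs <- scale(x, center = center, scale = scale_)
  hidden <- config$hidden
  if (is.null(hidden)) hidden <- 8L
  set.seed(config$seed)
  net <- nnet::nnet(xs, as.numeric(y == "abnormal"), size = hidden,
                    maxit = config$epochs, decay = config$decay,
                    entropy = TRUE, trace = FALSE, MaxNWts = 1e7)
  structure(
    list(net = net, center = center, scale = scale_,
         feature_names = feature_cols,
         label_map = c(`0` = "normal", `1` = "abnormal"),
         config = config, degenerate = all(constant)),
    class = "cervitex_model"
  )
}

#' Predict scores and labels for new feature rows
#'
#' @param object a `"cervitex_model"`.
#' @param newdata tibble (or matrix) containing the model's feature columns.
#' @param ... unused.
#' @return a tibble with `.score` in `[0, 1]` and `.pred`
#'   (`"abnormal"` when `.score >= 0.5` -- ties favour the positive class).
#' @export
predict.cervitex_model <- function(object, newdata, ...) {
  if (is.matrix(newdata)) newdata <- as.data.frame(newdata)
  missing <- setdiff(object$feature_names, names(newdata))
  if (length(missing)) {
    stop("newdata lacks feature columns: ",
         paste(utils::head(missing, 3), collapse = ", "), call. = FALSE)
  }
  x <- feature_matrix(newdata, object$feature_names)
  xs <- scale(x, center = object$center, scale = object$scale)
  score <- as.numeric(stats::predict(object$net, xs))
  tibble::tibble(
    .score = score,
    .pred = factor(ifelse(score >= 0.5, "abnormal", "normal"),
                   levels = label_levels)
  )
}

#' @export
print.cervitex_model <- function(x, ...) {
  cat("Feed-forward classifier:", length(x$feature_names), "features ->",
      x$net$n[2], "hidden -> 1 logistic output\n")
  if (x$degenerate) cat("(degenerate: all features constant)\n")
  invisible(x)
}

#' Confusion-matrix metric suite from counts
#'
#' Derives the standard diagnostic-test metrics from the four confusion
#' counts ("abnormal" is the positive class): sensitivity `TP/(TP+FN)`,
#' specificity `TN/(TN+FP)`, accuracy, PPV (= precision) `TP/(TP+FP)`,
#' NPV `TN/(TN+FN)`, likelihood ratios `LR+ = sens/(1-spec)` and
#' `LR- = (1-sens)/spec`. Division by zero yields `NA` (an undefined marker),
#' never an error.
#'
#' @param tp,tn,fp,fn non-negative counts, total > 0.
#' @return a one-row tibble of class `"confusion_metrics"`.
#' @examples
#' metrics_from_counts(90, 95, 5, 10)
#' @export
metrics_from_counts <- function(tp, tn, fp, fn) {
  counts <- c(tp, tn, fp, fn)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (sum(counts) == 0) stop("total count must be positive", call. = FALSE)
  v <- metrics_vec(tp, tn, fp, fn)
  out <- tibble::tibble(
    tp = tp, tn = tn, fp = fp, fn = fn,
    sensitivity = v$sensitivity, specificity = v$specificity,
    accuracy = v$accuracy, ppv = v$ppv, npv = v$npv,
    precision = v$ppv, lr_pos = v$lr_pos, lr_neg = v$lr_neg
  )
  class(out) <- c("confusion_metrics", class(out))
  out
}

#' Vectorized metric core shared by metrics_from_counts
#' @noRd
metrics_vec <- function(tp, tn, fp, fn) {
  sdiv <- function(num, den) ifelse(den == 0, NA_real_, num / den)
  sens <- sdiv(tp, tp + fn)
  spec <- sdiv(tn, tn + fp)
  list(
    sensitivity = sens,
    specificity = spec,
    accuracy = (tp + tn) / (tp + tn + fp + fn),
    ppv = sdiv(tp, tp + fp),
    npv = sdiv(tn, tn + fn),
    lr_pos = ifelse(is.na(sens) | is.na(spec), NA_real_,
                    sdiv(sens, 1 - spec)),
    lr_neg = ifelse(is.na(sens) | is.na(spec), NA_real_,
                    sdiv(1 - sens, spec))
  )
}

#' Stratified fold assignment
#' @noRd
stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  set.seed(seed)
  for (cls in levels(y)) {
    idx <- which(y == cls)
    idx <- sample(idx)
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Stratified k-fold cross-validation of the classifier
#'
#' Splits the samples into `k` class-stratified folds, trains on each
#' complement and predicts the held-out fold. The per-fold error `C(k)` is the
#' held-out misclassification fraction, and the cross-validation error is
#' their mean `mu = (1/k) sum C(k)` (always in `[0, 1]`). Confusion counts are
#' pooled over all held-out predictions.
#'
#' @param data feature tibble with a label column (see [fit_classifier()]).
#' @param k number of folds (`2 <= k <= n`).
#' @param seed seed for the fold assignment.
#' @param config a [classifier_config()].
#' @param label_col,id_col column names.
#' @return an object of class `"cervitex_cv"`: list with `fold_errors`,
#'   `cv_error`, `counts`, `metrics` (a [metrics_from_counts()] row),
#'   `predictions` (per-sample tibble), `k`, `seed`, `config`.
#' @export
kfold_cv <- function(data, k = 2, seed = 1, config = classifier_config(),
                     label_col = "label", id_col = "id") {
  n <- nrow(data)
  if (k < 2) stop("`k` must be >= 2", call. = FALSE)
  if (k > n) stop("`k` cannot exceed the number of samples", call. = FALSE)
  y <- factor(as.character(data[[label_col]]), levels = label_levels)
  if (anyNA(y)) stop("labels must be 'normal' or 'abnormal'", call. = FALSE)
  fold <- stratified_folds(y, k, seed)
  preds <- vector("list", k)
  fold_errors <- numeric(k)
  for (i in seq_len(k)) {
    test_idx <- which(fold == i)
    train <- data[-test_idx, , drop = FALSE]
    model <- fit_classifier(train, config = config, label_col = label_col,
                            id_col = id_col)
    p <- predict(model, data[test_idx, , drop = FALSE])
    truth <- y[test_idx]
    fold_errors[i] <- mean(p$.pred != truth)
    preds[[i]] <- tibble::tibble(
      id = if (id_col %in% names(data)) data[[id_col]][test_idx] else
        test_idx,
      fold = i, truth = truth, .score = p$.score, .pred = p$.pred
    )
  }
  predictions <- dplyr::bind_rows(preds)
  tp <- sum(predictions$.pred == "abnormal" & predictions$truth == "abnormal")
  tn <- sum(predictions$.pred == "normal" & predictions$truth == "normal")
  fp <- sum(predictions$.pred == "abnormal" & predictions$truth == "normal")
  fn <- sum(predictions$.pred == "normal" & predictions$truth == "abnormal")
  structure(
    list(fold_errors = fold_errors, cv_error = mean(fold_errors),
         counts = c(tp = tp, tn = tn, fp = fp, fn = fn),
         metrics = metrics_from_counts(tp, tn, fp, fn),
         predictions = predictions, k = k, seed = seed, config = config),
    class = "cervitex_cv"
  )
}

#' @export
print.cervitex_cv <- function(x, ...) {
  cat(sprintf("%d-fold stratified CV: cv_error = %.4f (folds: %s)\n",
              x$k, x$cv_error,
              paste(sprintf("%.3f", x$fold_errors), collapse = ", ")))
  cat(sprintf("pooled accuracy %.4f, sensitivity %.4f, specificity %.4f\n",
              x$metrics$accuracy, x$metrics$sensitivity,
              x$metrics$specificity))
  invisible(x)
}
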