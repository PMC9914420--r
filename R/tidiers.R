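# broom-style tidiers for fitted objects and CV results.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-fold cross-validation errors
#'
#' @param x a `"cervitex_cv"` from [kfold_cv()].
#' @param ... unused.
#' @return a tibble with one row per fold: `fold`, `error`, `n_test`.
#' @export
tidy.cervitex_cv <- function(x, ...) {
  n_test <- as.integer(table(x$predictions$fold))
  tibble::tibble(fold = seq_len(x$k), error = x$fold_errors,
                 n_test = n_test)
}

#' One-row summary of a cross-validation run
#'
#' @inheritParams tidy.cervitex_cv
#' @return a one-row tibble: `k`, `cv_error`, pooled counts and metrics.
#' @export
glance.cervitex_cv <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(k = x$k, cv_error = x$cv_error),
                   x$metrics)
}

#' Tidy the network weights of a fitted classifier
#'
#' @param x a `"cervitex_model"` from [fit_classifier()].
#' @param ... unused.
#' @return a tibble with one row per connection weight.
#' @export
tidy.cervitex_model <- function(x, ...) {
  tibble::tibble(term = names(stats::coef(x$net)),
                 estimate = as.numeric(stats::coef(x$net)))
}

#' One-row summary of a fitted classifier
#'
#' @inheritParams tidy.cervitex_model
#' @return a one-row tibble: architecture, weight count, final objective,
#'   degeneracy flag.
#' @export
glance.cervitex_model <- function(x, ...) {
  tibble::tibble(
    n_features = length(x$feature_names),
    hidden = x$net$n[2],
    n_weights = length(x$net$wts),
    final_value = x$net$value,
    epochs = x$config$epochs,
    degenerate = x$degenerate
  )
}

#' Tidy the region table of a segmentation result
#'
#' @param x a `"segmentation_result"`.
#' @param ... unused.
#' @return the region tibble (one row per retained component).
#' @export
tidy.segmentation_result <- function(x, ...) x$regions

#' One-row summary of a segmentation result
#'
#' @inheritParams tidy.segmentation_result
#' @return a one-row tibble: region count, foreground area, Dice (NA if
#'   unscored).
#' @export
glance.segmentation_result <- function(x, ...) {
  tibble::tibble(n_regions = nrow(x$regions),
                 foreground = sum(x$mask),
                 min_area = x$min_area,
                 dice = x$dice_vs_truth)
}
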