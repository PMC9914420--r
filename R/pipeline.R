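# End-to-end pipeline: enhance -> transform -> extract -> classify (k-fold)
# -> segment abnormal calls. One configuration object drives all stages; its
# hash is stamped into every artifact so runs are reproducible and auditable.

#' Pipeline configuration
#'
#' Bundles the per-stage settings. The configuration round-trips losslessly
#' through YAML ([write_pipeline_config()] / [read_pipeline_config()]), and
#' [config_hash()] of the config is recorded in every output.
#'
#' @param features a [feature_config()].
#' @param classifier a [classifier_config()].
#' @param k,cv_seed cross-validation folds and fold-split seed.
#' @param se_shape,se_size,min_area,binarize_method segmentation settings.
#' @param segment_source image handed to the segmenter: `"grayscale"`
#'   (default; the un-enhanced luminance, whose global lesion/background
#'   contrast a global threshold can exploit) or `"enhanced"`.
#' @return an object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(features = feature_config(),
                            classifier = classifier_config(),
                            k = 2, cv_seed = 7,
                            se_shape = "disk", se_size = 3, min_area = 25,
                            binarize_method = "otsu",
                            segment_source = c("grayscale", "enhanced")) {
  structure(
    list(features = features, classifier = classifier,
         k = k, cv_seed = cv_seed,
         se_shape = se_shape, se_size = se_size, min_area = min_area,
         binarize_method = binarize_method,
         segment_source = match.arg(segment_source)),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param config a `"pipeline_config"`.
#' @param path file path for the YAML representation.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  plain <- unclass(config)
  plain$features <- unclass(plain$features)
  attr(plain$features, "hash") <- NULL
  plain$classifier <- unclass(plain$classifier)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  plain <- yaml::read_yaml(path)
  fc <- do.call(feature_config, plain$features)
  cc <- do.call(classifier_config,
                plain$classifier[!vapply(plain$classifier, is.null,
                                         logical(1))])
  if (is.null(plain$classifier$hidden)) cc$hidden <- NULL
  pipeline_config(
    features = fc, classifier = cc, k = plain$k, cv_seed = plain$cv_seed,
    se_shape = plain$se_shape, se_size = plain$se_size,
    min_area = plain$min_area, binarize_method = plain$binarize_method,
    segment_source = plain$segment_source
  )
}

#' @noRd
pipeline_hash <- function(config) {
  plain <- unclass(config)
  plain$features <- unclass(plain$features)
  attr(plain$features, "hash") <- NULL
  plain$classifier <- unclass(plain$classifier)
  rlang::hash(plain)
}

#' Run the full detection pipeline on a dataset
#'
#' Executes every stage on a dataset tibble (from [generate_cervigrams()] or
#' [read_cervigrams()]) or a dataset directory: feature extraction
#' (enhancement + transforms inside), stratified k-fold cross-validation when
#' labels are present, a final model fit on all data, and morphological
#' segmentation of the images the model calls abnormal (Dice-scored against
#' ground-truth masks when available). When `output_dir` is given, writes
#' `features.csv`, `metrics.json`, and one mask PNG per segmented image;
#' partial outputs are removed if a stage fails.
#'
#' @param input dataset tibble or directory path.
#' @param config a [pipeline_config()].
#' @param output_dir optional output directory.
#' @param force_segmentation segment every image, not only abnormal calls.
#' @param quiet suppress stage log messages.
#' @return an object of class `"cervitex_report"`: list with `config_hash`,
#'   `n`, `cv` (a `"cervitex_cv"` or NULL), `model`, `predictions`,
#'   `segmentations` (tibble: id, called label, region count, dice),
#'   `mean_dice_true_abnormal`.
#' @export
run_pipeline <- function(input, config = pipeline_config(),
                         output_dir = NULL, force_segmentation = FALSE,
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  hash <- pipeline_hash(config)
  say <- function(stage, ...) {
    if (!quiet) message(sprintf("[cervitex %s] %s", hash,
                                paste0(stage, ": ", ...)))
  }
  written <- character(0)
  on_fail <- function(stage, e) {
    if (length(written)) unlink(written, force = TRUE)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }
  data <- if (is.character(input)) read_cervigrams(input) else input
  if (!is.data.frame(data) || nrow(data) == 0) {
    stop("input contains no images", call. = FALSE)
  }
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  }

  say("features", "extracting from ", nrow(data), " images")
  feats <- tryCatch(extract_features(data, config = config$features),
                    error = function(e) on_fail("features", e))
  if (!is.null(output_dir)) {
    f <- file.path(output_dir, "features.csv")
    readr::write_csv(feats, f)
    written <- c(written, f)
  }

  cv <- NULL
  has_labels <- "label" %in% names(feats) &&
    length(unique(feats$label)) == 2
  if (has_labels) {
    say("cv", config$k, "-fold stratified cross-validation")
    cv <- tryCatch(
      kfold_cv(feats, k = config$k, seed = config$cv_seed,
               config = config$classifier),
      error = function(e) on_fail("cv", e)
    )
  }

  model <- NULL; preds <- NULL
  if (has_labels) {
    say("train", "final model on all samples")
    model <- tryCatch(fit_classifier(feats, config = config$classifier),
                      error = function(e) on_fail("train", e))
    preds <- dplyr::bind_cols(tibble::tibble(id = feats$id),
                              predict(model, feats))
  }

  say("segment", "morphological segmentation")
  se <- structuring_element(config$se_shape, config$se_size)
  seg_rows <- list()
  for (i in seq_len(nrow(data))) {
    called_abnormal <- if (!is.null(preds)) {
      preds$.pred[match(data$id[i], preds$id)] == "abnormal"
    } else TRUE
    if (!called_abnormal && !force_segmentation) next
    gray <- to_grayscale(data$image[[i]])
    src <- if (config$segment_source == "enhanced") {
      ahe_enhance(gray, window = config$features$enhance_window,
                  fusion = config$features$fusion)
    } else gray
    truth <- if ("mask" %in% names(data)) data$mask[[i]] else NULL
    res <- tryCatch(
      segment_lesion(src, se = se, min_area = config$min_area,
                     method = config$binarize_method, truth = truth),
      error = function(e) on_fail("segment", e)
    )
    if (!is.null(output_dir)) {
      f <- file.path(output_dir, paste0("mask_", data$id[i], ".png"))
      png::writePNG(res$mask * 1, f)
      written <- c(written, f)
    }
    seg_rows[[length(seg_rows) + 1]] <- tibble::tibble(
      id = data$id[i],
      label = if ("label" %in% names(data)) as.character(data$label[i]) else
        NA_character_,
      n_regions = nrow(res$regions),
      foreground = sum(res$mask),
      dice = res$dice_vs_truth
    )
  }
  segmentations <- if (length(seg_rows)) dplyr::bind_rows(seg_rows) else
    tibble::tibble(id = character(), label = character(),
                   n_regions = integer(), foreground = integer(),
                   dice = numeric())
  mean_dice <- {
    d <- segmentations$dice[segmentations$label %in% "abnormal"]
    if (length(d)) mean(d, na.rm = TRUE) else NA_real_
  }

  report <- structure(
    list(config_hash = hash, n = nrow(data), cv = cv, model = model,
         predictions = preds, segmentations = segmentations,
         mean_dice_true_abnormal = mean_dice),
    class = "cervitex_report"
  )
  if (!is.null(output_dir)) {
    metrics <- list(config_hash = hash, n = nrow(data))
    if (!is.null(cv)) {
      metrics$cv_error <- cv$cv_error
      metrics$fold_errors <- cv$fold_errors
      metrics$counts <- as.list(cv$counts)
      metrics$metrics <- as.list(cv$metrics)
    }
    metrics$mean_dice_true_abnormal <- mean_dice
    f <- file.path(output_dir, "metrics.json")
    jsonlite::write_json(metrics, f, auto_unbox = TRUE, digits = 10,
                         pretty = TRUE)
    written <- c(written, f)
  }
  say("done", "report ready")
  report
}

#' @export
print.cervitex_report <- function(x, ...) {
  cat("cervitex pipeline report (config", x$config_hash, ")\n")
  cat("images:", x$n, "\n")
  if (!is.null(x$cv)) print(x$cv)
  if (!is.na(x$mean_dice_true_abnormal)) {
    cat("mean Dice on true abnormal:",
        round(x$mean_dice_true_abnormal, 3), "\n")
  }
  invisible(x)
}
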