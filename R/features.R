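# Feature-vector assembly: fixed-order concatenation of GLRLM, ELTP, moment
# invariant and ridgelet-statistic blocks, extracted from the AHE-enhanced
# image (ridgelet statistics from its finite ridgelet transform).

#' Feature-extraction configuration
#'
#' Pins every parameter of the extraction stage so that feature vectors are
#' reproducible and comparable across a dataset. The configuration hash
#' (`rlang::hash` of the settings) is stamped on every extracted vector.
#'
#' @param feature_sets subset of `c("glrlm", "frt", "mif", "eltp")`; blocks
#'   are always concatenated in the fixed order GLRLM, ELTP, MIF, FRT.
#' @param levels gray levels of the input images.
#' @param enhance_window,fusion AHE window size and fusion rule.
#' @param glrlm_bins,glrlm_orientations run-length quantization and
#'   orientations.
#' @param eltp_rotation_invariant pool ELTP patterns into riu2 bins.
#' @param ridgelet_prime side of the prime grid the enhanced image is
#'   resampled to before the finite ridgelet transform (default 17, which
#'   keeps the ridgelet block at `(17 + 1) * (levels + 1) * 3` values).
#' @param ridgelet_wavelet,ridgelet_levels wavelet name and decomposition
#'   depth.
#' @return an object of class `"feature_config"`.
#' @export
feature_config <- function(feature_sets = c("glrlm", "frt", "mif", "eltp"),
                           levels = 256,
                           enhance_window = 3,
                           fusion = "max",
                           glrlm_bins = 16,
                           glrlm_orientations = c(0, 45, 90, 135),
                           eltp_rotation_invariant = TRUE,
                           ridgelet_prime = 17,
                           ridgelet_wavelet = "db4",
                           ridgelet_levels = 2) {
  feature_sets <- match.arg(feature_sets,
                            c("glrlm", "frt", "mif", "eltp"),
                            several.ok = TRUE)
  if (!is_prime(ridgelet_prime)) {
    stop("`ridgelet_prime` must be prime", call. = FALSE)
  }
  cfg <- list(
    feature_sets = feature_sets, levels = levels,
    enhance_window = enhance_window, fusion = fusion,
    glrlm_bins = glrlm_bins, glrlm_orientations = glrlm_orientations,
    eltp_rotation_invariant = eltp_rotation_invariant,
    ridgelet_prime = ridgelet_prime, ridgelet_wavelet = ridgelet_wavelet,
    ridgelet_levels = ridgelet_levels
  )
  structure(cfg, class = "feature_config", hash = rlang::hash(cfg))
}

#' Hash identifying a feature configuration
#' @param config a [feature_config()].
#' @return a character scalar.
#' @export
config_hash <- function(config) {
  h <- attr(config, "hash")
  if (is.null(h)) rlang::hash(unclass(config)) else h
}

#' Bilinear resampling of a gray image to a p x p grid (via EBImage)
#' @noRd
resample_to_prime <- function(image, p, levels = 256) {
  if (nrow(image) == p && ncol(image) == p) return(image)
  img <- EBImage::Image(t(image) / (levels - 1))
  res <- EBImage::resize(img, w = p, h = p)
  clamp(round_half_up(t(EBImage::imageData(res)) * (levels - 1)),
        0, levels - 1)
}

#' Assemble the fixed-order feature vector of one image
#'
#' Converts to grayscale, applies directional associated histogram
#' equalization, and extracts the configured feature blocks from the enhanced
#' image: run-length statistics (7 per orientation), ELTP histograms
#' (upper + lower), the 7 moment invariants, and per-sub-band ridgelet
#' statistics of the finite ridgelet transform of the enhanced image resampled
#' to the configured prime grid.
#'
#' @param image RGB array or grayscale matrix.
#' @param config a [feature_config()].
#' @return a named numeric vector with attribute `config_hash`.
#' @export
assemble_features <- function(image, config = feature_config()) {
  stopifnot(inherits(config, "feature_config"))
  gray <- to_grayscale(image, levels = config$levels)
  enhanced <- ahe_enhance(gray, window = config$enhance_window,
                          levels = config$levels, fusion = config$fusion)
  out <- numeric(0)
  if ("glrlm" %in% config$feature_sets) {
    for (o in config$glrlm_orientations) {
      f <- glrlm_features(glrlm(enhanced, o, gray_bins = config$glrlm_bins,
                                levels = config$levels))
      names(f) <- sprintf("glrlm_%s_%d", names(f), o)
      out <- c(out, f)
    }
  }
  if ("eltp" %in% config$feature_sets) {
    d <- eltp(enhanced,
              rotation_invariant = config$eltp_rotation_invariant,
              levels = config$levels)
    up <- d$upper; lo <- d$lower
    names(up) <- paste0("eltp_upper_", names(d$upper))
    names(lo) <- paste0("eltp_lower_", names(d$lower))
    out <- c(out, up, lo)
  }
  if ("mif" %in% config$feature_sets) {
    hu <- moment_invariants(enhanced)$hu
    names(hu) <- paste0("mif_", names(hu))
    out <- c(out, hu)
  }
  if ("frt" %in% config$feature_sets) {
    small <- resample_to_prime(enhanced, config$ridgelet_prime,
                               levels = config$levels)
    stats <- ridgelet_stats(frt(small, wavelet = config$ridgelet_wavelet,
                                levels = config$ridgelet_levels))
    out <- c(out, stats)
  }
  if (anyDuplicated(names(out))) {
    stop("internal error: duplicated feature names", call. = FALSE)
  }
  attr(out, "config_hash") <- config_hash(config)
  out
}

#' Extract a feature table from a dataset of images
#'
#' Maps [assemble_features()] over an image list-column and returns one row
#' per image: the id column, one column per feature, and (if present) the
#' label column last. Deterministic: identical inputs and configuration yield
#' an identical table.
#'
#' @param data a tibble with an image list-column (e.g. from
#'   [generate_cervigrams()]).
#' @param config a [feature_config()].
#' @param image_col,id_col,label_col column names; `label_col` is optional in
#'   `data`.
#' @return a tibble with attribute `config_hash`.
#' @export
extract_features <- function(data, config = feature_config(),
                             image_col = "image", id_col = "id",
                             label_col = "label") {
  stopifnot(is.data.frame(data), image_col %in% names(data))
  if (nrow(data) == 0) stop("`data` contains no images", call. = FALSE)
  feats <- purrr::map(data[[image_col]], assemble_features, config = config)
  mat <- do.call(rbind, feats)
  out <- tibble::as_tibble(as.data.frame(mat))
  ids <- if (id_col %in% names(data)) data[[id_col]] else
    sprintf("img_%03d", seq_len(nrow(data)))
  out <- dplyr::bind_cols(tibble::tibble(id = ids), out)
  if (label_col %in% names(data)) out[[label_col]] <- data[[label_col]]
  attr(out, "config_hash") <- config_hash(config)
  out
}
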