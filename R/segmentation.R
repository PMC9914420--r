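# Morphological lesion segmentation: binarization, opening/closing with a
# structuring element, connected-component ROI extraction, Dice scoring.
#
# Set operations use the zero-padding convention: pixels outside the image
# count as background, so erosion shrinks foreground touching the border
# ("fit inside" reading) and dilation never wraps.

#' Structuring element for binary morphology
#'
#' @param shape `"disk"` (pixels with squared distance `<= size^2` from the
#'   origin) or `"square"` (a `(2 size + 1)` square).
#' @param size radius in pixels (>= 1).
#' @return an object of class `"structuring_element"`: a two-column matrix of
#'   (dr, dc) offsets including the origin.
#' @export
structuring_element <- function(shape = c("disk", "square"), size = 3) {
  shape <- match.arg(shape)
  if (size < 1) stop("`size` must be >= 1", call. = FALSE)
  g <- expand.grid(dr = -size:size, dc = -size:size)
  if (shape == "disk") g <- g[g$dr^2 + g$dc^2 <= size^2, ]
  structure(as.matrix(g), class = "structuring_element",
            shape = shape, size = size)
}

#' @noRd
assert_se <- function(se) {
  if (!inherits(se, "structuring_element")) {
    stop("`se` must be a structuring_element()", call. = FALSE)
  }
  se
}

#' Binarize a grayscale image
#'
#' Default method is Otsu's threshold (maximizing the between-class variance
#' of the histogram); `method = "fixed"` uses the supplied threshold.
#' Foreground (`TRUE`) is the set of pixels strictly above the threshold. A
#' constant image yields an all-background mask with a warning.
#'
#' @param image grayscale matrix.
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold threshold intensity for `method = "fixed"`.
#' @param levels gray levels.
#' @return a logical mask with attribute `threshold`.
#' @export
binarize <- function(image, method = c("otsu", "fixed"), threshold = NULL,
                     levels = 256) {
  method <- match.arg(method)
  assert_gray_image(image, levels = levels)
  if (min(image) == max(image)) {
    warning("constant image: returning an all-background mask")
    return(structure(matrix(FALSE, nrow(image), ncol(image)),
                     threshold = NA_real_))
  }
  if (method == "fixed") {
    if (is.null(threshold)) {
      stop("`threshold` is required for method = 'fixed'", call. = FALSE)
    }
    thr <- threshold
  } else {
    thr <- EBImage::otsu(EBImage::Image(t(image) / (levels - 1)),
                         range = c(0, 1), levels = levels) * (levels - 1)
  }
  structure(image > thr, threshold = thr)
}

#' Binary dilation
#'
#' Set dilation: the union of structuring-element translates over the
#' foreground. Extensive for SEs containing the origin.
#'
#' @param mask binary matrix (logical or 0/1).
#' @param se a [structuring_element()].
#' @return a logical mask.
#' @export
dilate_mask <- function(mask, se = structuring_element("disk", 3)) {
  mask <- as_binary_mask(mask)
  assert_se(se)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(se))) {
    out <- out | shift_mask(mask, se[i, 1], se[i, 2])
  }
  out
}

#' Binary erosion
#'
#' Set erosion: keeps the pixels at which every structuring-element offset
#' lands on foreground; pixels outside the image count as background, so
#' foreground touching the border erodes.
#'
#' @inheritParams dilate_mask
#' @return a logical mask.
#' @export
erode_mask <- function(mask, se = structuring_element("disk", 3)) {
  mask <- as_binary_mask(mask)
  assert_se(se)
  out <- matrix(TRUE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(se))) {
    out <- out & shift_mask(mask, -se[i, 1], -se[i, 2])
  }
  out
}

#' Morphological opening, closing, or both
#'
#' Opening (erode then dilate) removes components smaller than the
#' structuring element; closing (dilate then erode) fills holes smaller than
#' it. The pipeline default (`"close_open"`) closes first and then opens:
#' thresholded lesion masks are speckled with interior holes, and eroding
#' before the holes are filled lets the erosion tunnel through the lesion,
#' whereas closing first restores a solid region that opening then cleans.
#'
#' @inheritParams dilate_mask
#' @param op `"close_open"` (default), `"open_close"`, `"open"` or `"close"`.
#' @return a logical mask.
#' @export
open_close <- function(mask, se = structuring_element("disk", 3),
                       op = c("close_open", "open_close", "open", "close")) {
  op <- match.arg(op)
  opening <- function(m) dilate_mask(erode_mask(m, se), se)
  closing <- function(m) erode_mask(dilate_mask(m, se), se)
  switch(op,
    open = opening(as_binary_mask(mask)),
    close = closing(as_binary_mask(mask)),
    open_close = closing(opening(as_binary_mask(mask))),
    close_open = opening(closing(as_binary_mask(mask)))
  )
}

#' 8-connected component labelling
#' @noRd
label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nbr <- expand.grid(dr = -1:1, dc = -1:1)
  nbr <- nbr[!(nbr$dr == 0 & nbr$dc == 0), ]
  current <- 0L
  todo <- which(mask & lab == 0L)
  for (seed in todo) {
    if (lab[seed] != 0L) next
    current <- current + 1L
    frontier <- seed
    lab[seed] <- current
    while (length(frontier)) {
      r <- (frontier - 1L) %% h + 1L
      c <- (frontier - 1L) %/% h + 1L
      nxt <- integer(0)
      for (i in seq_len(nrow(nbr))) {
        rr <- r + nbr$dr[i]; cc <- c + nbr$dc[i]
        ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
        if (!any(ok)) next
        idx <- (cc[ok] - 1L) * h + rr[ok]
        idx <- idx[mask[idx] & lab[idx] == 0L]
        if (length(idx)) {
          lab[idx] <- current
          nxt <- c(nxt, idx)
        }
      }
      frontier <- unique(nxt)
    }
  }
  lab
}

#' Extract regions of interest from a processed mask
#'
#' Labels 8-connected foreground components, drops those below `min_area`,
#' and tabulates the remaining regions.
#'
#' @param mask binary matrix.
#' @param min_area minimum component area in pixels (default 25).
#' @return an object of class `"segmentation_result"`: list with `mask` (the
#'   filtered logical mask), `regions` (tibble: `label`, `area`, bounding box,
#'   centroid), `min_area`, and `dice_vs_truth` (NA until scored).
#' @export
extract_roi <- function(mask, min_area = 25) {
  mask <- as_binary_mask(mask)
  lab <- label_components(mask)
  keep <- matrix(FALSE, nrow(mask), ncol(mask))
  rows <- list()
  if (max(lab) > 0) {
    next_label <- 0L
    for (l in seq_len(max(lab))) {
      idx <- which(lab == l)
      if (length(idx) < min_area) next
      next_label <- next_label + 1L
      r <- (idx - 1L) %% nrow(mask) + 1L
      c <- (idx - 1L) %/% nrow(mask) + 1L
      keep[idx] <- TRUE
      rows[[next_label]] <- tibble::tibble(
        label = next_label, area = length(idx),
        row_min = min(r), row_max = max(r),
        col_min = min(c), col_max = max(c),
        centroid_row = mean(r), centroid_col = mean(c)
      )
    }
  }
  regions <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(label = integer(), area = integer(),
                   row_min = integer(), row_max = integer(),
                   col_min = integer(), col_max = integer(),
                   centroid_row = numeric(), centroid_col = numeric())
  structure(list(mask = keep, regions = regions, min_area = min_area,
                 dice_vs_truth = NA_real_),
            class = "segmentation_result")
}

#' Dice overlap coefficient between two masks
#'
#' `2 |A intersect B| / (|A| + |B|)`; two empty masks score 1 by convention.
#'
#' @param pred,truth binary matrices of the same shape.
#' @return a number in `[0, 1]`.
#' @export
dice <- function(pred, truth) {
  pred <- as_binary_mask(pred, "pred")
  truth <- as_binary_mask(truth, "truth")
  if (!all(dim(pred) == dim(truth))) {
    stop("`pred` and `truth` must have the same shape", call. = FALSE)
  }
  denom <- sum(pred) + sum(truth)
  if (denom == 0) return(1)
  2 * sum(pred & truth) / denom
}

#' Full morphological segmentation of one image
#'
#' Binarizes the image ([binarize()]), cleans the mask with closing then
#' opening (see [open_close()]), extracts ROIs above `min_area`, and
#' (optionally) scores the final mask against a ground-truth mask with
#' [dice()].
#'
#' @param image grayscale matrix (the pipeline passes the grayscale cervigram;
#'   any gray image works).
#' @param se structuring element (default disk of radius 3).
#' @param min_area minimum region area (default 25 px).
#' @param method,threshold binarization settings (see [binarize()]).
#' @param op morphological cleanup order (see [open_close()]).
#' @param levels gray levels.
#' @param truth optional ground-truth mask for Dice scoring.
#' @return a `"segmentation_result"` (see [extract_roi()]) with
#'   `dice_vs_truth` filled in when `truth` is supplied.
#' @export
segment_lesion <- function(image, se = structuring_element("disk", 3),
                           min_area = 25, method = "otsu", threshold = NULL,
                           op = "close_open", levels = 256, truth = NULL) {
  mask <- binarize(image, method = method, threshold = threshold,
                   levels = levels)
  cleaned <- open_close(mask, se = se, op = op)
  res <- extract_roi(cleaned, min_area = min_area)
  if (!is.null(truth)) res$dice_vs_truth <- dice(res$mask, truth)
  res
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat("Segmentation:", nrow(x$regions), "region(s),",
      sum(x$mask), "foreground px")
  if (!is.na(x$dice_vs_truth)) cat(", Dice", round(x$dice_vs_truth, 3))
  cat("\n")
  if (nrow(x$regions)) print(x$regions)
  invisible(x)
}
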