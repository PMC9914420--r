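# Gray-level run-length matrices and the seven run-length statistics.

#' Re-quantize an 8-bit image into G uniform gray bins (1-based bin index)
#' @noRd
quantize_gray <- function(image, bins, levels = 256) {
  pmin(floor(image * bins / levels), bins - 1) + 1L
}

#' Decompose an image into the pixel sequences of one run orientation
#' @noRd
orientation_sequences <- function(q, orientation) {
  switch(as.character(orientation),
    "0"   = split(q, row(q)),                 # along rows, left to right
    "90"  = split(q, col(q)),                 # along columns
    "45"  = split(q, row(q) + col(q)),        # anti-diagonals (up-right)
    "135" = split(q, col(q) - row(q)),        # diagonals (down-right)
    stop("`orientation` must be one of 0, 45, 90, 135", call. = FALSE)
  )
}

#' Gray-level run-length matrix (GLRLM)
#'
#' Counts maximal runs of collinear, equal-valued pixels after uniform
#' re-quantization to `gray_bins` levels, along one of the four standard
#' orientations (0, 45, 90, 135 degrees). Every pixel belongs to exactly one
#' maximal run per orientation, so `sum(b * M[a, b])` equals the pixel count.
#'
#' @param image grayscale matrix.
#' @param orientation one of 0, 45, 90, 135 (degrees).
#' @param gray_bins number of gray bins `G >= 2` (default 16).
#' @param levels gray levels of the input (default 256).
#' @return a `G x q` integer matrix of run counts (`q` = longest possible run
#'   for the orientation) with attributes `orientation`, `num_runs`,
#'   `n_pixels`.
#' @examples
#' img <- rbind(c(0, 0, 1, 1), c(0, 0, 1, 1), c(2, 2, 2, 2), c(3, 3, 3, 3))
#' m <- glrlm(img, 0, gray_bins = 4, levels = 4)
#' attr(m, "num_runs") # 6
#' @export
glrlm <- function(image, orientation = 0, gray_bins = 16, levels = 256) {
  assert_gray_image(image, levels = levels)
  if (gray_bins < 2) stop("`gray_bins` must be >= 2", call. = FALSE)
  q <- quantize_gray(image, gray_bins, levels)
  seqs <- orientation_sequences(q, orientation)
  qmax <- switch(as.character(orientation),
    "0" = ncol(image), "90" = nrow(image),
    min(nrow(image), ncol(image))
  )
  vals <- integer(0); lens <- integer(0)
  for (s in seqs) {
    r <- rle(as.integer(s))
    vals <- c(vals, r$values)
    lens <- c(lens, r$lengths)
  }
  counts <- tabulate((lens - 1L) * gray_bins + vals, nbins = gray_bins * qmax)
  m <- matrix(counts, gray_bins, qmax)
  structure(m, orientation = orientation, num_runs = sum(m),
            n_pixels = length(image))
}

#' The seven run-length texture statistics of a GLRLM
#'
#' With `len` the total number of runs, `a` the (1-based) gray-bin index and
#' `b` the run length:
#' short-run emphasis `SHE = (1/len) sum M / b^2`,
#' long-run emphasis `LOE = (1/len) sum M b^2`,
#' gray-level non-uniformity `GLNU = (1/len) sum_a (sum_b M)^2`,
#' run-length non-uniformity `RLNU = (1/len) sum_b (sum_a M)^2`,
#' run percentage `RUP = len / n_pixels`,
#' low-gray-level run emphasis `LGLRE = (1/len) sum M / a^2`,
#' high-gray-level run emphasis `HGLRE = (1/len) sum M a^2`.
#'
#' @param m a run-length matrix from [glrlm()] (or any nonempty count matrix;
#'   `n_pixels` is taken from its attribute or from the conservation identity).
#' @return a named numeric vector `c(she, loe, glnu, rlnu, rup, lglre, hglre)`.
#' @export
glrlm_features <- function(m) {
  len <- sum(m)
  if (len <= 0) stop("empty run-length matrix", call. = FALSE)
  a <- row(m); b <- col(m)
  n_pixels <- attr(m, "n_pixels")
  if (is.null(n_pixels)) n_pixels <- sum(b * m)
  c(
    she   = sum(m / b^2) / len,
    loe   = sum(m * b^2) / len,
    glnu  = sum(rowSums(m)^2) / len,
    rlnu  = sum(colSums(m)^2) / len,
    rup   = len / n_pixels,
    lglre = sum(m / a^2) / len,
    hglre = sum(m * a^2) / len
  )
}

#' Run-length features for all four orientations as a tidy tibble
#'
#' @inheritParams glrlm
#' @param orientations orientations to include (default all four).
#' @return a tibble with columns `orientation`, `she`, ..., `hglre`.
#' @export
glrlm_feature_table <- function(image, orientations = c(0, 45, 90, 135),
                                gray_bins = 16, levels = 256) {
  purrr::map_dfr(orientations, function(o) {
    f <- glrlm_features(glrlm(image, o, gray_bins = gray_bins,
                              levels = levels))
    tibble::tibble(orientation = o, !!!as.list(f))
  })
}
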