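# Shared helpers: rounding convention, clamping, primality, image validation.

#' Round half away from zero (towards +Inf for positive values)
#'
#' Deterministic "round to nearest integer" used throughout the pipeline
#' (grayscale conversion, windowed equalization). Unlike base [round()], halves
#' always round up, so results do not depend on round-half-to-even parity.
#' @param x numeric
#' @return numeric of the same shape, integral-valued
#' @keywords internal
#' @noRd
round_half_up <- function(x) floor(x + 0.5)

#' @noRd
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Test primality of a scalar integer
#' @param n integer scalar
#' @return logical
#' @keywords internal
#' @noRd
is_prime <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) return(FALSE)
  if (n < 4L) return(TRUE)
  if (n %% 2L == 0L) return(FALSE)
  d <- 3L
  while (d * d <= n) {
    if (n %% d == 0L) return(FALSE)
    d <- d + 2L
  }
  TRUE
}

#' Largest prime less than or equal to n (NA if none)
#' @noRd
largest_prime_leq <- function(n) {
  n <- as.integer(n)
  while (n >= 2L) {
    if (is_prime(n)) return(n)
    n <- n - 1L
  }
  NA_integer_
}

#' Validate a grayscale image matrix
#'
#' A gray image is a plain numeric matrix of intensities in `[0, levels - 1]`.
#' @noRd
assert_gray_image <- function(image, levels = 256, min_dim = 1L,
                              arg = "image") {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop(sprintf("`%s` must be a numeric matrix (grayscale image)", arg),
         call. = FALSE)
  }
  if (nrow(image) < min_dim || ncol(image) < min_dim) {
    stop(sprintf("`%s` must be at least %dx%d", arg, min_dim, min_dim),
         call. = FALSE)
  }
  if (anyNA(image) || any(!is.finite(image))) {
    stop(sprintf("`%s` contains missing or non-finite values", arg),
         call. = FALSE)
  }
  if (min(image) < 0 || max(image) > levels - 1) {
    stop(sprintf("`%s` has intensities outside [0, %d]", arg, levels - 1),
         call. = FALSE)
  }
  invisible(image)
}

#' Validate a binary mask (logical or 0/1 matrix); returns a logical matrix
#' @noRd
as_binary_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask)) {
    stop(sprintf("`%s` must be a matrix", arg), call. = FALSE)
  }
  if (is.logical(mask)) {
    if (anyNA(mask)) stop(sprintf("`%s` contains NA", arg), call. = FALSE)
    return(mask)
  }
  if (!all(mask %in% c(0, 1))) {
    stop(sprintf("`%s` must be strictly binary (0/1 or logical)", arg),
         call. = FALSE)
  }
  mask > 0
}

#' Shift a logical matrix by (dr, dc), padding with FALSE (zero padding)
#' @noRd
shift_mask <- function(mask, dr, dc) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(FALSE, h, w)
  rs <- max(1, 1 + dr):min(h, h + dr)
  cs <- max(1, 1 + dc):min(w, w + dc)
  if (length(rs) && length(cs)) {
    out[rs, cs] <- mask[rs - dr, cs - dc]
  }
  out
}
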