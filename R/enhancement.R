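# Directional associated histogram equalization (AHE).
#
# Classic windowed histogram equalization re-values a pixel from the cumulative
# histogram of a window centred on it. The directional variant evaluated here
# additionally slides the window so that the processed pixel occupies each of
# the eight off-centre anchor positions of the window (TL, TC, TR, CL, CR, LL,
# LC, LR), giving eight directionally enhanced images that are fused per pixel.

#' Convert an RGB image to 8-bit grayscale
#'
#' Applies the ITU-R BT.601 luminance weights `0.299 R + 0.587 G + 0.114 B` and
#' rounds to the nearest integer (halves away from zero). A single-channel
#' (matrix) input is validated and passed through unchanged.
#'
#' @param image either an `h x w x 3` numeric array (channels in `[0, 255]`, or
#'   in `[0, 1]` as returned by [png::readPNG()], in which case values are
#'   rescaled to `[0, 255]`) or an already-gray numeric matrix.
#' @param levels number of gray levels (default 256).
#' @return an integer-valued matrix with intensities in `[0, levels - 1]`.
#' @examples
#' rgb <- array(c(255, 0, 0), dim = c(1, 1, 3))
#' to_grayscale(rgb) # 76
#' @export
to_grayscale <- function(image, levels = 256) {
  if (is.matrix(image)) {
    assert_gray_image(image, levels = levels)
    return(image)
  }
  if (!is.array(image) || length(dim(image)) != 3 || dim(image)[3] != 3) {
    stop("`image` must be a gray matrix or an h x w x 3 RGB array",
         call. = FALSE)
  }
  if (max(image) <= 1 && any(image != floor(image))) {
    image <- image * (levels - 1)
  }
  y <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  y <- matrix(y, dim(image)[1], dim(image)[2])
  clamp(round_half_up(y), 0, levels - 1)
}

#' The eight directional anchor offsets of the sliding window
#'
#' For an odd window size `n`, the anchor (the pixel being processed) is placed
#' at each of the eight non-central positions of the geometric 8-neighbourhood
#' of the window centre: corners and edge midpoints at offset
#' `m = (n - 1) / 2`. Offsets are (row, col) displacements of the anchor from
#' the window centre; "T"/"L" rows are up/down, e.g. TC is `(-m, 0)`.
#'
#' @param window odd window size `n` (default 3).
#' @return a tibble with columns `name`, `dr`, `dc`.
#' @export
anchor_offsets <- function(window = 3) {
  if (window %% 2 != 1 || window < 3) {
    stop("`window` must be an odd integer >= 3", call. = FALSE)
  }
  m <- (window - 1) / 2
  tibble::tibble(
    name = c("TL", "TC", "TR", "CL", "CR", "LL", "LC", "LR"),
    dr = c(-m, -m, -m, 0, 0, m, m, m),
    dc = c(-m, 0, m, -m, m, -m, 0, m)
  )
}

#' Windowed histogram equalization of a single pixel
#'
#' Re-values the pixel sitting at the anchor position of an `n x n` window as
#' `round((cdf(a) - cdf_min) / (n^2 - cdf_min) * (levels - 1))`, where `a` is
#' the anchor intensity, `cdf(a)` the number of window pixels with intensity
#' `<= a`, and `cdf_min` the smallest nonzero cumulative count (the count of
#' the window minimum). A constant window, for which the expression degenerates
#' to 0/0, passes the anchor value through unchanged.
#'
#' @param window an odd-sized square numeric matrix of intensities.
#' @param anchor anchor name (one of `anchor_offsets()$name`, or `"C"` for the
#'   window centre) or a length-2 `(dr, dc)` offset from the centre.
#' @param levels number of gray levels.
#' @return the equalized intensity, clamped to `[0, levels - 1]`.
#' @examples
#' w <- matrix(c(1, 2, 2, 3, 3, 3, 4, 4, 5), 3, 3)
#' ahe_pixel(w, "C", levels = 8) # 4 when the anchor holds a 3
#' @export
ahe_pixel <- function(window, anchor = "C", levels = 256) {
  n <- nrow(window)
  if (!is.matrix(window) || n != ncol(window) || n %% 2 != 1) {
    stop("`window` must be a square matrix of odd size", call. = FALSE)
  }
  m <- (n - 1) / 2
  if (is.character(anchor)) {
    if (identical(anchor, "C")) {
      off <- c(0, 0)
    } else {
      tab <- anchor_offsets(n)
      idx <- match(anchor, tab$name)
      if (is.na(idx)) stop("unknown anchor name: ", anchor, call. = FALSE)
      off <- c(tab$dr[idx], tab$dc[idx])
    }
  } else {
    off <- anchor
    if (length(off) != 2 || any(abs(off) > m)) {
      stop("anchor offset must lie inside the window", call. = FALSE)
    }
  }
  a <- window[m + 1 + off[1], m + 1 + off[2]]
  if (min(window) == max(window)) return(a)
  cdf_a <- sum(window <= a)
  cdf_min <- sum(window <= min(window))
  clamp(round_half_up((cdf_a - cdf_min) / (n * n - cdf_min) * (levels - 1)),
        0, levels - 1)
}

#' Directionally enhanced image stack
#'
#' For each of the eight anchor offsets, every pixel is re-valued by windowed
#' equalization over the `n x n` window positioned so that the pixel sits at
#' that anchor. Border windows use edge-replication padding. The result is a
#' stack of eight images, one per anchor, each the shape of the input.
#'
#' @param image grayscale matrix, at least 3x3.
#' @param window odd window size (default 3).
#' @param levels number of gray levels.
#' @return a named list of 8 matrices (names `TL`, `TC`, ..., `LR`), with
#'   attribute `window`.
#' @seealso [fuse_stack()], [ahe_enhance()]
#' @export
directional_enhance <- function(image, window = 3, levels = 256) {
  assert_gray_image(image, levels = levels, min_dim = 3L)
  if (window %% 2 != 1 || window < 3) {
    stop("`window` must be an odd integer >= 3", call. = FALSE)
  }
  n <- window
  m <- (n - 1) / 2
  h <- nrow(image); w <- ncol(image)
  # pad by 2m: the window centre is displaced by up to m from the pixel, and
  # the window extends m further
  pr <- clamp((1 - 2 * m):(h + 2 * m), 1, h)
  pc <- clamp((1 - 2 * m):(w + 2 * m), 1, w)
  padded <- image[pr, pc]
  offs <- anchor_offsets(n)
  out <- vector("list", 8)
  names(out) <- offs$name
  for (k in seq_len(8)) {
    dr <- offs$dr[k]; dc <- offs$dc[k]
    # window element (u, v) for pixel (i, j): padded[i - dr + u + 2m, ...]
    cdf_a <- matrix(0L, h, w)
    wmin <- NULL; wmax <- NULL
    shifts <- vector("list", n * n)
    s <- 0L
    for (u in -m:m) {
      for (v in -m:m) {
        s <- s + 1L
        shifts[[s]] <- padded[(1:h) - dr + u + 2 * m, (1:w) - dc + v + 2 * m,
                              drop = FALSE]
        wmin <- if (is.null(wmin)) shifts[[s]] else pmin(wmin, shifts[[s]])
        wmax <- if (is.null(wmax)) shifts[[s]] else pmax(wmax, shifts[[s]])
      }
    }
    cdf_min <- matrix(0L, h, w)
    for (s in seq_len(n * n)) {
      cdf_a <- cdf_a + (shifts[[s]] <= image)
      cdf_min <- cdf_min + (shifts[[s]] <= wmin)
    }
    enh <- clamp(
      round_half_up((cdf_a - cdf_min) / (n * n - cdf_min) * (levels - 1)),
      0, levels - 1
    )
    const <- wmin == wmax
    enh[const] <- image[const]
    out[[k]] <- enh
  }
  attr(out, "window") <- n
  out
}

#' Fuse a directional enhancement stack into one image
#'
#' Default fusion keeps, per pixel, the maximum across the eight directional
#' images ("higher-intensity pixels pick the best intensity"); `"mean"` fusion
#' averages and rounds.
#'
#' @param stack a list of 8 equally sized matrices from [directional_enhance()].
#' @param method `"max"` (default) or `"mean"`.
#' @return a single fused grayscale matrix.
#' @export
fuse_stack <- function(stack, method = c("max", "mean")) {
  method <- match.arg(method)
  if (!is.list(stack) || length(stack) != 8) {
    stop("`stack` must be a list of 8 directional images", call. = FALSE)
  }
  dims <- vapply(stack, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all stack images must share the same dimensions", call. = FALSE)
  }
  if (method == "max") {
    Reduce(pmax, stack)
  } else {
    round_half_up(Reduce(`+`, stack) / length(stack))
  }
}

#' Associated histogram equalization (directional enhance + fuse)
#'
#' Convenience wrapper: [directional_enhance()] followed by [fuse_stack()].
#'
#' @inheritParams directional_enhance
#' @param fusion fusion rule passed to [fuse_stack()].
#' @return an enhanced grayscale matrix of the input's shape.
#' @examples
#' img <- matrix(rep(c(40, 200), each = 18), 6, 6)
#' enh <- ahe_enhance(img)
#' @export
ahe_enhance <- function(image, window = 3, levels = 256,
                        fusion = c("max", "mean")) {
  fuse_stack(directional_enhance(image, window = window, levels = levels),
             method = match.arg(fusion))
}
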