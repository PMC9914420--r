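# Enhanced local ternary pattern (ELTP).
#
# Each 3x3 patch is coded against data-driven statistics of the patch itself:
# the centre reference `ace` is the patch mean and the tolerance `we` is the
# patch mean absolute deviation, so the code adapts to local contrast. The
# ternary code is split into its positive and negative binary halves, each
# histogrammed (with an optional rotation-invariant uniform-pattern mapping).

# circular neighbour order for P = 8, R = 1: E, NE, N, NW, W, SW, S, SE
eltp_offsets <- function() {
  cbind(dr = c(0, -1, -1, -1, 0, 1, 1, 1),
        dc = c(1, 1, 0, -1, -1, -1, 0, 1))
}

#' Ternary code of a pixel neighbourhood
#'
#' Codes each neighbour `ap` against the local mean `ace` and tolerance `we`
#' (floored at `eps` so a zero deviation never collapses the dead zone):
#' `+1` if `ap - ace >= we`, `-1` if `ap - ace <= -we`, else `0`.
#'
#' @param neighbors numeric vector of neighbour intensities (length >= 4).
#' @param ace local reference (patch mean).
#' @param we local tolerance (patch mean absolute deviation).
#' @param eps lower floor for `we` (default 1e-6).
#' @return integer vector of codes in `{-1, 0, 1}`.
#' @examples
#' eltp_code(c(10, 2, 6, 6, 6, 6, 6, 6), ace = 6, we = 1)
#' @export
eltp_code <- function(neighbors, ace, we, eps = 1e-6) {
  if (length(neighbors) < 4) {
    stop("`neighbors` must have at least 4 elements", call. = FALSE)
  }
  we <- max(we, eps)
  d <- neighbors - ace
  ifelse(d >= we, 1L, ifelse(d <= -we, -1L, 0L))
}

# number of ones and circular 0/1 transitions for each 8-bit pattern,
# giving the rotation-invariant uniform ("riu2") bin: uniform patterns
# (<= 2 transitions) map to their popcount (bins 1..9), others to bin 10
riu2_map <- function() {
  patterns <- 0:255
  bits <- t(vapply(patterns, function(p) as.integer(intToBits(p)[1:8]),
                   integer(8)))
  ones <- rowSums(bits)
  trans <- rowSums(bits != bits[, c(2:8, 1)])
  ifelse(trans <= 2, ones + 1L, 10L)
}

#' Enhanced local ternary pattern descriptor of an image
#'
#' Codes every interior pixel's 8-neighbourhood (radius 1) with [eltp_code()],
#' using the 3x3 patch (centre included) for `ace` and `we`. The positive half
#' (`code == +1`) and negative half (`code == -1`) each form an 8-bit binary
#' pattern; their histograms over the image are the descriptor. With
#' `rotation_invariant = TRUE` patterns are pooled into the 10
#' rotation-invariant uniform bins (popcount 0-8 for uniform patterns plus a
#' non-uniform bin), which makes the histograms invariant to image rotation by
#' multiples of 90 degrees.
#'
#' Comparisons are carried out in exact integer arithmetic (both sides scaled
#' by 81) so the inclusive `>=` boundary and the upper/lower swap under
#' intensity inversion are exact for integer images.
#'
#' @param image grayscale matrix, at least 3x3.
#' @param P,R neighbourhood geometry; only the 8-neighbour, radius-1 ring is
#'   supported.
#' @param rotation_invariant pool patterns into riu2 bins (default TRUE).
#' @param levels gray levels (used only for validation).
#' @return an object of class `"eltp"`: list with `upper`, `lower` (named
#'   histogram vectors), `P`, `R`, `rotation_invariant`, `n_coded`.
#' @export
eltp <- function(image, P = 8, R = 1, rotation_invariant = TRUE,
                 levels = 256) {
  assert_gray_image(image, levels = levels, min_dim = 3L)
  if (P != 8 || R != 1) {
    stop("only the (P = 8, R = 1) neighbourhood is supported", call. = FALSE)
  }
  h <- nrow(image); w <- ncol(image)
  if (h < 2 * R + 1 || w < 2 * R + 1) {
    stop("image too small for radius ", R, call. = FALSE)
  }
  ri <- 2:(h - 1); ci <- 2:(w - 1)
  # patch sum S over the 3x3 neighbourhood of each interior pixel
  S <- matrix(0, length(ri), length(ci))
  for (u in -1:1) for (v in -1:1) {
    S <- S + image[ri + u, ci + v]
  }
  # B = sum_q |9 x_q - S| = 81 * we; codes compare 9 * (9 x_p - S) against B
  B <- matrix(0, length(ri), length(ci))
  for (u in -1:1) for (v in -1:1) {
    B <- B + abs(9 * image[ri + u, ci + v] - S)
  }
  B <- pmax(B, 81 * 9 * 1e-6)  # floor we at 1e-6
  offs <- eltp_offsets()
  upper_pat <- matrix(0L, length(ri), length(ci))
  lower_pat <- matrix(0L, length(ri), length(ci))
  for (p in seq_len(8)) {
    Dp <- 9 * (9 * image[ri + offs[p, 1], ci + offs[p, 2]] - S)
    upper_pat <- upper_pat + (Dp >= B) * 2L^(p - 1L)
    lower_pat <- lower_pat + (Dp <= -B) * 2L^(p - 1L)
  }
  if (rotation_invariant) {
    map <- riu2_map()
    bins <- 10L
    bin_names <- c(paste0("u", 0:8), "nonuniform")
    upper_idx <- map[upper_pat + 1L]
    lower_idx <- map[lower_pat + 1L]
  } else {
    bins <- 256L
    bin_names <- sprintf("p%03d", 0:255)
    upper_idx <- upper_pat + 1L
    lower_idx <- lower_pat + 1L
  }
  upper <- tabulate(upper_idx, nbins = bins)
  lower <- tabulate(lower_idx, nbins = bins)
  names(upper) <- names(lower) <- bin_names
  structure(
    list(upper = upper, lower = lower, P = P, R = R,
         rotation_invariant = rotation_invariant,
         n_coded = length(upper_idx)),
    class = "eltp"
  )
}

#' @export
print.eltp <- function(x, ...) {
  cat("ELTP descriptor (P =", x$P, ", R =", x$R,
      if (x$rotation_invariant) ", riu2 bins" else ", raw patterns",
      "), ", x$n_coded, "coded pixels\n")
  cat("upper:", x$upper, "\n")
  cat("lower:", x$lower, "\n")
  invisible(x)
}
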