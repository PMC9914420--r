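# Central image moments and the seven classical rotation invariants.

#' Central moments and Hu moment invariants of an image
#'
#' Computes the geometric central moments `mu[a, b] = sum (r - rbar)^a *
#' (c - cbar)^b f(r, c)` up to order 3 about the intensity centroid, the
#' scale-normalized moments `eta[a, b] = mu[a, b] / mu[0, 0]^(1 + (a + b) / 2)`,
#' and the seven classical rotation/translation/scale invariants derived from
#' them. Central moments are exactly translation invariant; the invariants are
#' additionally invariant to rotation (and reflection, up to the sign of the
#' seventh).
#'
#' @param image numeric matrix with non-negative values and nonzero mass.
#' @return an object of class `"moment_invariants"`: list with `central`
#'   (4x4 matrix, orders 0..3), `eta`, `hu` (named `phi1`..`phi7`),
#'   `centroid`, `mass`.
#' @examples
#' img <- matrix(0, 9, 9); img[4:6, 4:6] <- 1
#' moment_invariants(img)$hu[["phi1"]]
#' @export
moment_invariants <- function(image) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("`image` must be a numeric matrix", call. = FALSE)
  }
  if (min(image) < 0) stop("`image` must be non-negative", call. = FALSE)
  mass <- sum(image)
  if (mass <= 0) stop("zero-mass image", call. = FALSE)
  r <- row(image) - 1; c <- col(image) - 1
  rbar <- sum(r * image) / mass
  cbar <- sum(c * image) / mass
  dr <- r - rbar; dc <- c - cbar
  mu <- matrix(0, 4, 4, dimnames = list(paste0("a", 0:3), paste0("b", 0:3)))
  for (a in 0:3) for (b in 0:3) {
    if (a + b <= 3) mu[a + 1, b + 1] <- sum(dr^a * dc^b * image)
  }
  eta <- mu
  for (a in 0:3) for (b in 0:3) {
    if (a + b >= 2 && a + b <= 3) {
      eta[a + 1, b + 1] <- mu[a + 1, b + 1] / mass^(1 + (a + b) / 2)
    }
  }
  e <- function(a, b) eta[a + 1, b + 1]
  hu <- c(
    phi1 = e(2, 0) + e(0, 2),
    phi2 = (e(2, 0) - e(0, 2))^2 + 4 * e(1, 1)^2,
    phi3 = (e(3, 0) - 3 * e(1, 2))^2 + (3 * e(2, 1) - e(0, 3))^2,
    phi4 = (e(3, 0) + e(1, 2))^2 + (e(2, 1) + e(0, 3))^2,
    phi5 = (e(3, 0) - 3 * e(1, 2)) * (e(3, 0) + e(1, 2)) *
             ((e(3, 0) + e(1, 2))^2 - 3 * (e(2, 1) + e(0, 3))^2) +
           (3 * e(2, 1) - e(0, 3)) * (e(2, 1) + e(0, 3)) *
             (3 * (e(3, 0) + e(1, 2))^2 - (e(2, 1) + e(0, 3))^2),
    phi6 = (e(2, 0) - e(0, 2)) *
             ((e(3, 0) + e(1, 2))^2 - (e(2, 1) + e(0, 3))^2) +
           4 * e(1, 1) * (e(3, 0) + e(1, 2)) * (e(2, 1) + e(0, 3)),
    phi7 = (3 * e(2, 1) - e(0, 3)) * (e(3, 0) + e(1, 2)) *
             ((e(3, 0) + e(1, 2))^2 - 3 * (e(2, 1) + e(0, 3))^2) -
           (e(3, 0) - 3 * e(1, 2)) * (e(2, 1) + e(0, 3)) *
             (3 * (e(3, 0) + e(1, 2))^2 - (e(2, 1) + e(0, 3))^2)
  )
  structure(
    list(central = mu, eta = eta, hu = hu,
         centroid = c(row = rbar, col = cbar), mass = mass),
    class = "moment_invariants"
  )
}

#' @export
print.moment_invariants <- function(x, ...) {
  cat("Image moments: mass", format(x$mass), "centroid (",
      format(x$centroid[1]), ",", format(x$centroid[2]), ")\n")
  print(signif(x$hu, 6))
  invisible(x)
}
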