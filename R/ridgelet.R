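# Finite ridgelet transform: finite Radon transform over the prime grid
# Z_p x Z_p followed by a periodized 1-D Daubechies wavelet transform along
# each projection. Both stages are exactly invertible, so the composite is a
# non-redundant line-singularity representation with perfect reconstruction.

# --- finite Radon transform ------------------------------------------------

#' Finite Radon transform (FRAT) over the prime grid
#'
#' For a `p x p` image with `p` prime, sums pixels along the `p + 1` pencils of
#' parallel "lines" of the finite geometry `Z_p x Z_p`: for each slope
#' `k = 0, ..., p - 1` the lines `{(i, (k i + t) mod p)}` indexed by offset
#' `t`, plus the pencil of image rows. Every pixel lies on exactly one line per
#' direction, so each projection (row of the output) sums to the total image
#' mass.
#'
#' @param image a `p x p` numeric matrix, `p` prime.
#' @return a `(p + 1) x p` matrix of class `"frat"`; row `k + 1` holds slope
#'   `k`'s projection (slope 0 = column sums), row `p + 1` the row sums.
#' @seealso [frat_inverse()]
#' @export
frat <- function(image) {
  if (!is.matrix(image) || nrow(image) != ncol(image)) {
    stop("`image` must be a square matrix", call. = FALSE)
  }
  p <- nrow(image)
  if (!is_prime(p)) {
    stop("`image` side length must be prime (got ", p, ")", call. = FALSE)
  }
  i0 <- rep(0:(p - 1), times = p)  # row index, fast
  t0 <- rep(0:(p - 1), each = p)   # offset index, slow
  rows <- rep(1:p, times = p)
  proj <- matrix(0, p + 1, p)
  for (k in 0:(p - 1)) {
    cols <- (k * i0 + t0) %% p + 1L
    proj[k + 1, ] <- colSums(matrix(image[cbind(rows, cols)], p, p))
  }
  proj[p + 1, ] <- rowSums(image)
  structure(proj, class = "frat", p = p)
}

#' Exact inverse of the finite Radon transform
#'
#' Back-projects the `p + 1` projections through each pixel and removes the
#' total-mass bias: since the lines through a pixel cover every other pixel
#' exactly once, `x[i, j] = (sum of the p + 1 line sums through (i, j) -
#' mass) / p`, which reconstructs the image exactly.
#'
#' @param radon a `(p + 1) x p` projection matrix from [frat()].
#' @param tol relative tolerance for the projection-sum consistency check.
#' @return the reconstructed `p x p` matrix.
#' @export
frat_inverse <- function(radon, tol = 1e-8) {
  if (!is.matrix(radon) || nrow(radon) != ncol(radon) + 1) {
    stop("`radon` must be a (p + 1) x p projection matrix", call. = FALSE)
  }
  p <- ncol(radon)
  if (!is_prime(p)) stop("projection length must be prime", call. = FALSE)
  mass <- sum(radon[1, ])
  sums <- rowSums(radon)
  if (any(abs(sums - mass) > tol * max(1, abs(mass)))) {
    stop("inconsistent projections: rows do not share the same total mass",
         call. = FALSE)
  }
  i0 <- rep(0:(p - 1), times = p)
  j0 <- rep(0:(p - 1), each = p)
  s <- matrix(0, p, p)
  for (k in 0:(p - 1)) {
    t_idx <- (j0 - k * i0) %% p + 1L
    s <- s + matrix(radon[k + 1, ][t_idx], p, p)
  }
  s <- s + matrix(radon[p + 1, ], p, p)  # row pencil: constant along each row
  (s - mass) / p
}

# --- periodized orthogonal Daubechies DWT ----------------------------------

#' Scaling/wavelet filter pair for the supported Daubechies wavelets
#' @noRd
wavelet_filters <- function(wavelet) {
  h <- switch(wavelet,
    haar = ,
    db1 = c(1, 1) / sqrt(2),
    db2 = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2)),
    db4 = c(0.230377813308855230, 0.714846570552541500,
            0.630880767929590400, -0.027983769416983850,
            -0.187034811718881140, 0.030841381835986965,
            0.032883011666982945, -0.010597401784997278),
    stop("unknown wavelet: ", wavelet,
         " (supported: haar/db1, db2, db4)", call. = FALSE)
  )
  L <- length(h)
  g <- rev(h) * (-1)^(0:(L - 1))
  list(h = h, g = g)
}

#' One level of the periodized orthogonal DWT (even-length input)
#' @noRd
dwt_step <- function(x, filt) {
  m <- length(x)
  half <- m / 2
  a <- numeric(half); d <- numeric(half)
  base <- 2 * (0:(half - 1))
  for (n in seq_along(filt$h)) {
    idx <- (base + n - 1) %% m + 1
    a <- a + filt$h[n] * x[idx]
    d <- d + filt$g[n] * x[idx]
  }
  list(a = a, d = d)
}

#' @noRd
idwt_step <- function(a, d, filt) {
  half <- length(a)
  m <- 2 * half
  x <- numeric(m)
  base <- 2 * (0:(half - 1))
  for (n in seq_along(filt$h)) {
    idx <- (base + n - 1) %% m + 1
    x[idx] <- x[idx] + filt$h[n] * a + filt$g[n] * d
  }
  x
}

#' Multi-level periodized DWT of a vector whose length is a multiple of
#' 2^levels. Returns list(a = approximation, d = list(d1 finest ... dL)).
#' @noRd
dwt_periodic <- function(x, wavelet = "db4", levels = 1) {
  if (length(x) %% 2^levels != 0) {
    stop("input length must be divisible by 2^levels", call. = FALSE)
  }
  filt <- wavelet_filters(wavelet)
  d <- vector("list", levels)
  a <- x
  for (l in seq_len(levels)) {
    s <- dwt_step(a, filt)
    a <- s$a
    d[[l]] <- s$d
  }
  list(a = a, d = d)
}

#' @noRd
idwt_periodic <- function(coeffs, wavelet = "db4") {
  filt <- wavelet_filters(wavelet)
  a <- coeffs$a
  for (l in rev(seq_along(coeffs$d))) {
    a <- idwt_step(a, coeffs$d[[l]], filt)
  }
  a
}

# --- finite ridgelet transform ---------------------------------------------

#' Finite ridgelet transform (FRT)
#'
#' Computes [frat()] and applies an independent periodized 1-D Daubechies
#' wavelet transform along each of the `p + 1` projections. Projections (length
#' `p`, odd) are zero-padded at the end to the smallest multiple of
#' `2^levels`; the padded length is retained so the transform inverts exactly.
#'
#' @param image a `p x p` numeric matrix with `p` prime.
#' @param wavelet one of `"haar"`/`"db1"`, `"db2"`, `"db4"` (default).
#' @param levels decomposition depth (default 2).
#' @return an object of class `"frt_coeffs"`: a list with `coeffs` (one
#'   `list(a, d)` per direction), `wavelet`, `levels`, `p`, `padded_len`.
#' @seealso [frt_inverse()], [ridgelet_stats()]
#' @export
frt <- function(image, wavelet = "db4", levels = 2) {
  if (levels < 1) stop("`levels` must be >= 1", call. = FALSE)
  wavelet_filters(wavelet)  # validate name early
  radon <- frat(image)
  p <- attr(radon, "p")
  m <- as.integer(ceiling(p / 2^levels) * 2^levels)
  coeffs <- lapply(seq_len(p + 1), function(dir) {
    x <- c(radon[dir, ], numeric(m - p))
    dwt_periodic(x, wavelet = wavelet, levels = levels)
  })
  structure(
    list(coeffs = coeffs, wavelet = wavelet, levels = levels,
         p = p, padded_len = m),
    class = "frt_coeffs"
  )
}

#' Exact inverse of the finite ridgelet transform
#'
#' Inverts the per-direction wavelet transforms, truncates the zero padding,
#' and applies [frat_inverse()].
#'
#' @param x an object of class `"frt_coeffs"`.
#' @return the reconstructed `p x p` image matrix.
#' @export
frt_inverse <- function(x) {
  if (!inherits(x, "frt_coeffs")) {
    stop("`x` must be an object returned by frt()", call. = FALSE)
  }
  p <- x$p
  radon <- matrix(0, p + 1, p)
  for (dir in seq_len(p + 1)) {
    rec <- idwt_periodic(x$coeffs[[dir]], wavelet = x$wavelet)
    radon[dir, ] <- rec[1:p]
  }
  frat_inverse(structure(radon, p = p))
}

#' Per-sub-band summary statistics of ridgelet coefficients
#'
#' For every direction and every sub-band (approximation, then details from
#' coarsest to finest) computes the energy (sum of squares), mean absolute
#' coefficient, and population standard deviation. Flattened direction-major;
#' names follow `frt_d<dir>_<band>_<stat>` with `band` in
#' `a<L>, d<L>, ..., d1` and `dir` in `0..p` (`p` = the row pencil).
#'
#' @param x an object of class `"frt_coeffs"`.
#' @return a named numeric vector of length `(p + 1) * (levels + 1) * 3`.
#' @export
ridgelet_stats <- function(x) {
  if (!inherits(x, "frt_coeffs")) {
    stop("`x` must be an object returned by frt()", call. = FALSE)
  }
  L <- x$levels
  band_stats <- function(v) {
    mu <- mean(v)
    c(energy = sum(v^2), mean_abs = mean(abs(v)),
      sd = sqrt(mean((v - mu)^2)))
  }
  out <- numeric(0)
  for (dir in seq_along(x$coeffs)) {
    cf <- x$coeffs[[dir]]
    bands <- c(list(cf$a), rev(cf$d))  # a_L, d_L, ..., d_1
    band_names <- c(paste0("a", L), paste0("d", L:1))
    for (b in seq_along(bands)) {
      s <- band_stats(bands[[b]])
      names(s) <- sprintf("frt_d%d_%s_%s", dir - 1, band_names[b], names(s))
      out <- c(out, s)
    }
  }
  out
}
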