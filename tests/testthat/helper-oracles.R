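# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use different formulations (explicit loops, cumulative
# histograms, run walking) from the vectorized package code.

# rotate a matrix 90 degrees counter-clockwise
rot90 <- function(m) t(m)[ncol(m):1, , drop = FALSE]

# per-pixel windowed equalization via an explicit cumulative histogram table
oracle_ahe <- function(image, window = 3, dr = 0, dc = 0, levels = 256) {
  n <- window; m <- (n - 1) / 2
  h <- nrow(image); w <- ncol(image)
  out <- matrix(0, h, w)
  for (i in 1:h) {
    for (j in 1:w) {
      ci <- i - dr; cj <- j - dc  # window centre so pixel sits at the anchor
      vals <- numeric(0)
      for (u in -m:m) {
        for (v in -m:m) {
          ri <- min(max(ci + u, 1), h)
          rj <- min(max(cj + v, 1), w)
          vals <- c(vals, image[ri, rj])
        }
      }
      a <- image[i, j]
      if (min(vals) == max(vals)) {
        out[i, j] <- a
        next
      }
      hist_counts <- tabulate(vals + 1, nbins = levels)
      cum <- cumsum(hist_counts)
      cdf_a <- cum[a + 1]
      cdf_min <- min(cum[cum > 0])
      s <- floor((cdf_a - cdf_min) / (n * n - cdf_min) * (levels - 1) + 0.5)
      out[i, j] <- min(max(s, 0), levels - 1)
    }
  }
  out
}

# walk every line of an orientation, recording maximal runs; compute the
# seven statistics directly from the run list
oracle_glrlm_features <- function(image, orientation, gray_bins, levels) {
  q <- pmin(floor(image * gray_bins / levels), gray_bins - 1) + 1
  h <- nrow(q); w <- ncol(q)
  step <- switch(as.character(orientation),
                 "0" = c(0, 1), "90" = c(1, 0),
                 "45" = c(-1, 1), "135" = c(1, 1))
  starts <- list()
  for (i in 1:h) for (j in 1:w) {
    pi <- i - step[1]; pj <- j - step[2]
    if (pi < 1 || pi > h || pj < 1 || pj > w) {
      starts[[length(starts) + 1]] <- c(i, j)
    }
  }
  grays <- integer(0); lens <- integer(0)
  for (s in starts) {
    i <- s[1]; j <- s[2]
    cur <- q[i, j]; run <- 0L
    while (i >= 1 && i <= h && j >= 1 && j <= w) {
      if (q[i, j] == cur) {
        run <- run + 1L
      } else {
        grays <- c(grays, cur); lens <- c(lens, run)
        cur <- q[i, j]; run <- 1L
      }
      i <- i + step[1]; j <- j + step[2]
    }
    grays <- c(grays, cur); lens <- c(lens, run)
  }
  len <- length(lens)
  by_gray <- table(grays)
  by_len <- table(lens)
  c(she = sum(1 / lens^2) / len,
    loe = sum(lens^2) / len,
    glnu = sum(as.numeric(by_gray)^2) / len,
    rlnu = sum(as.numeric(by_len)^2) / len,
    rup = len / (h * w),
    lglre = sum(1 / grays^2) / len,
    hglre = sum(grays^2) / len)
}

# definitional confusion-matrix formulas, vectorized
oracle_metrics <- function(tp, tn, fp, fn) {
  sdiv <- function(a, b) ifelse(b == 0, NA_real_, a / b)
  sens <- sdiv(tp, tp + fn)
  spec <- sdiv(tn, tn + fp)
  list(
    sensitivity = sens,
    specificity = spec,
    accuracy = (tp + tn) / (tp + tn + fp + fn),
    ppv = sdiv(tp, tp + fp),
    npv = sdiv(tn, tn + fn),
    lr_pos = ifelse(is.na(sens) | is.na(spec), NA_real_,
                    sdiv(sens, 1 - spec)),
    lr_neg = ifelse(is.na(sens) | is.na(spec), NA_real_,
                    sdiv(1 - sens, spec))
  )
}

# double-loop set morphology with zero padding
naive_dilate <- function(mask, se) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(FALSE, h, w)
  for (i in 1:h) for (j in 1:w) {
    for (s in seq_len(nrow(se))) {
      ri <- i - se[s, 1]; rj <- j - se[s, 2]
      if (ri >= 1 && ri <= h && rj >= 1 && rj <= w && mask[ri, rj]) {
        out[i, j] <- TRUE
        break
      }
    }
  }
  out
}

naive_erode <- function(mask, se) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(TRUE, h, w)
  for (i in 1:h) for (j in 1:w) {
    for (s in seq_len(nrow(se))) {
      ri <- i + se[s, 1]; rj <- j + se[s, 2]
      if (ri < 1 || ri > h || rj < 1 || rj > w || !mask[ri, rj]) {
        out[i, j] <- FALSE
        break
      }
    }
  }
  out
}

# exhaustive between-class-variance threshold sweep
oracle_otsu <- function(image, levels = 256) {
  best_t <- NA; best_v <- -Inf
  v <- as.vector(image)
  for (t in 0:(levels - 2)) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (!length(lo) || !length(hi)) next
    bc <- length(lo) * length(hi) * (mean(lo) - mean(hi))^2
    if (bc > best_v) {
      best_v <- bc
      best_t <- t
    }
  }
  best_t
}

# deterministic random gray image
rand_gray <- function(h, w, levels = 256, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(sample(0:(levels - 1), h * w, replace = TRUE), h, w)
}
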