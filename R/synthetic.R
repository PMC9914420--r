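# Deterministic synthetic cervigram generator. Emulates the regime of a
# colposcopy image bank at fixture scale: red-cast RGB images with a smooth
# illumination vignette and sensor noise; abnormal images additionally carry
# an elliptical lesion whose intensity, local contrast and run-length
# anisotropy differ from the background, with an exact ground-truth mask.

#' @noRd
ellipse_mask <- function(h, w, center, axes, angle) {
  r <- row(matrix(0, h, w)) - center[1]
  c <- col(matrix(0, h, w)) - center[2]
  u <- r * cos(angle) + c * sin(angle)
  v <- -r * sin(angle) + c * cos(angle)
  (u / axes[1])^2 + (v / axes[2])^2 <= 1
}

#' Generate a labelled synthetic cervigram dataset
#'
#' Produces `n` RGB images with a dominant red cast, a smooth radial
#' illumination vignette and Gaussian pixel noise. With probability
#' `lesion_prob` an image is abnormal: an ellipse (random centre, semi-axes
#' and angle, always fully inside the frame) is brightened by `lesion_offset`
#' and overlaid with horizontally smoothed speckle, so lesion texture differs
#' from background in local contrast and in run-length structure (elongated
#' horizontal runs). The ground-truth mask delimits the ellipse exactly;
#' normal images have empty masks. Generation is fully determined by `seed`.
#'
#' @param n number of images (>= 1).
#' @param image_size `c(rows, cols)` (default 64 x 64).
#' @param lesion_prob probability an image is abnormal (default 0.5).
#' @param base_intensity background luminance base (default 110).
#' @param vignette_amplitude amplitude of the radial illumination field
#'   (default 25; centre brighter).
#' @param noise_sd background Gaussian noise sd (default 8).
#' @param lesion_offset lesion luminance offset (default 55).
#' @param speckle_sd lesion speckle amplitude after directional smoothing
#'   (default 25).
#' @param major_axis,minor_axis ranges (length-2) of the lesion semi-axes in
#'   pixels; the defaults give lesions occupying roughly a quarter of the
#'   frame, large enough that image-level texture statistics separate the
#'   classes by construction.
#' @param seed RNG seed (required for reproducibility; default 1).
#' @return a tibble with columns `id`, `image` (list of `h x w x 3` arrays,
#'   values 0-255), `mask` (list of logical matrices), `label` (factor
#'   normal/abnormal).
#' @examples
#' d <- generate_cervigrams(4, seed = 7)
#' table(d$label)
#' @export
generate_cervigrams <- function(n,
                                image_size = c(64, 64),
                                lesion_prob = 0.5,
                                base_intensity = 110,
                                vignette_amplitude = 25,
                                noise_sd = 8,
                                lesion_offset = 55,
                                speckle_sd = 25,
                                major_axis = c(14, 22),
                                minor_axis = c(10, 16),
                                seed = 1) {
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  h <- image_size[1]; w <- image_size[2]
  if (2 * max(major_axis) + 6 > min(h, w)) {
    stop("infeasible geometry: lesion axes too large for the image",
         call. = FALSE)
  }
  set.seed(seed)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    # smooth radial vignette with a jittered optical centre
    cy <- h / 2 + stats::runif(1, -h / 10, h / 10)
    cx <- w / 2 + stats::runif(1, -w / 10, w / 10)
    d2 <- ((row(matrix(0, h, w)) - cy) / (h / 2))^2 +
      ((col(matrix(0, h, w)) - cx) / (w / 2))^2
    y <- base_intensity + vignette_amplitude * (1 - pmin(d2, 1)) +
      matrix(stats::rnorm(h * w, 0, noise_sd), h, w)
    abnormal <- stats::runif(1) < lesion_prob
    mask <- matrix(FALSE, h, w)
    if (abnormal) {
      a <- stats::runif(1, major_axis[1], major_axis[2])
      b <- stats::runif(1, minor_axis[1], minor_axis[2])
      ang <- stats::runif(1, 0, pi)
      margin <- ceiling(max(a, b)) + 2
      ctr <- c(stats::runif(1, margin + 1, h - margin),
               stats::runif(1, margin + 1, w - margin))
      mask <- ellipse_mask(h, w, ctr, c(a, b), ang)
      # horizontally smoothed speckle: elongated runs inside the lesion
      sp <- matrix(stats::rnorm(h * w), h, w)
      k <- 5
      sm <- t(apply(sp, 1, function(v) {
        f <- stats::filter(v, rep(1 / k, k), sides = 2, circular = TRUE)
        as.numeric(f)
      }))
      sm <- sm / stats::sd(sm) * speckle_sd
      y[mask] <- y[mask] + lesion_offset + sm[mask]
    }
    y <- clamp(y, 0, 255)
    img <- array(0, dim = c(h, w, 3))
    img[, , 1] <- clamp(round_half_up(
      y + 35 + matrix(stats::rnorm(h * w, 0, 3), h, w)), 0, 255)
    img[, , 2] <- clamp(round_half_up(
      0.78 * y + matrix(stats::rnorm(h * w, 0, 3), h, w)), 0, 255)
    img[, , 3] <- clamp(round_half_up(
      0.62 * y + matrix(stats::rnorm(h * w, 0, 3), h, w)), 0, 255)
    rows[[i]] <- tibble::tibble(
      id = sprintf("img_%04d", i),
      image = list(img),
      mask = list(mask),
      label = factor(if (abnormal) "abnormal" else "normal",
                     levels = c("normal", "abnormal"))
    )
  }
  dplyr::bind_rows(rows)
}

#' Write a synthetic dataset to disk (PNG images + masks + labels.csv)
#'
#' Lays out `dir/images/<id>.png`, `dir/masks/<id>.png` (0/255) and
#' `dir/labels.csv` so that directory-based pipeline runs and the CLI can
#' round-trip generated data.
#'
#' @param data tibble from [generate_cervigrams()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cervigrams <- function(data, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(data))) {
    png::writePNG(data$image[[i]] / 255,
                  file.path(dir, "images", paste0(data$id[i], ".png")))
    png::writePNG(data$mask[[i]] * 1,
                  file.path(dir, "masks", paste0(data$id[i], ".png")))
  }
  readr::write_csv(tibble::tibble(id = data$id,
                                  label = as.character(data$label)),
                   file.path(dir, "labels.csv"))
  invisible(dir)
}

#' Read a dataset directory written by [write_cervigrams()]
#'
#' @param dir directory containing `images/` (PNG/TIFF/JPEG) and optionally
#'   `masks/` and `labels.csv`.
#' @return a tibble with `id`, `image`, and where available `mask`, `label`.
#' @export
read_cervigrams <- function(dir) {
  img_dir <- file.path(dir, "images")
  if (!dir.exists(img_dir)) img_dir <- dir
  files <- list.files(img_dir, pattern = "\\.(png|tif|tiff|jpg|jpeg)$",
                      ignore.case = TRUE, full.names = TRUE)
  if (!length(files)) stop("no images found under ", dir, call. = FALSE)
  read_one <- function(f) {
    if (grepl("\\.png$", f, ignore.case = TRUE)) {
      x <- png::readPNG(f)
    } else {
      x <- t_ebimage(EBImage::readImage(f))
    }
    if (length(dim(x)) == 3 && dim(x)[3] >= 3) {
      x <- x[, , 1:3]
    }
    round_half_up(x * 255)
  }
  ids <- sub("\\.[^.]+$", "", basename(files))
  out <- tibble::tibble(id = ids, image = lapply(files, read_one))
  mask_dir <- file.path(dir, "masks")
  if (dir.exists(mask_dir)) {
    mask_files <- file.path(mask_dir, paste0(ids, ".png"))
    if (all(file.exists(mask_files))) {
      out$mask <- lapply(mask_files, function(f) png::readPNG(f) > 0.5)
    }
  }
  labels_file <- file.path(dir, "labels.csv")
  if (file.exists(labels_file)) {
    lab <- readr::read_csv(labels_file, show_col_types = FALSE)
    out$label <- factor(lab$label[match(out$id, lab$id)],
                        levels = c("normal", "abnormal"))
  }
  out
}

#' Transpose EBImage data (width x height [x ch]) to row x col [x ch]
#' @noRd
t_ebimage <- function(img) {
  x <- EBImage::imageData(img)
  if (length(dim(x)) == 2) t(x) else aperm(x, c(2, 1, 3))
}
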