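# ggplot2 visualisations for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-fold cross-validation errors
#'
#' @param object a `"cervitex_cv"` from [kfold_cv()].
#' @param ... unused.
#' @return a ggplot: fold errors as columns with the mean as a dashed line.
#' @export
autoplot.cervitex_cv <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$fold), y = .data$error)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$cv_error, linetype = "dashed") +
    ggplot2::labs(x = "fold", y = "held-out error",
                  title = sprintf("%d-fold CV error (mean %.3f)",
                                  object$k, object$cv_error)) +
    ggplot2::theme_minimal()
}

#' Plot an ELTP descriptor's positive/negative histograms
#'
#' @param object an `"eltp"` descriptor.
#' @param ... unused.
#' @return a ggplot with one facet per channel.
#' @export
autoplot.eltp <- function(object, ...) {
  d <- dplyr::bind_rows(
    tibble::tibble(channel = "upper (+1)", bin = names(object$upper),
                   count = as.numeric(object$upper)),
    tibble::tibble(channel = "lower (-1)", bin = names(object$lower),
                   count = as.numeric(object$lower))
  )
  d$bin <- factor(d$bin, levels = names(object$upper))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bin, y = .data$count)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::facet_wrap(~channel, ncol = 1) +
    ggplot2::labs(x = "pattern bin", y = "pixels",
                  title = "Enhanced local ternary pattern histograms") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Overlay a segmentation mask on its source image
#'
#' @param image grayscale matrix the segmentation was computed from.
#' @param result a `"segmentation_result"` (or any binary mask).
#' @param levels gray levels of `image`.
#' @return a ggplot raster with the mask tinted red.
#' @export
plot_segmentation <- function(image, result, levels = 256) {
  mask <- if (inherits(result, "segmentation_result")) result$mask else
    as_binary_mask(result)
  d <- tibble::tibble(
    row = as.vector(row(image)),
    col = as.vector(col(image)),
    intensity = as.vector(image) / (levels - 1),
    lesion = as.vector(mask)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 guide = "none") +
    ggplot2::geom_tile(data = dplyr::filter(d, .data$lesion),
                       fill = "red", alpha = 0.35) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = "Segmented lesion", x = NULL, y = NULL) +
    ggplot2::theme_void()
}
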