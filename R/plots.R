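# ggplot2 views of the pipeline's result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a DNA-content histogram
#'
#' @param object A [build_histogram()] result.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.cc_histogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_col(width = object$bin_hi[1] - object$bin_lo[1],
                      fill = "steelblue") +
    ggplot2::labs(x = "DNA-stain intensity (a.u.)", y = "Cells",
                  title = paste0("DNA-content histogram",
                                 if (!is.na(attr(object, "well_id")))
                                   paste0(" - well ", attr(object, "well_id"))
                                 else "")) +
    ggplot2::theme_minimal()
}

#' Plot a fitted dose-response curve with its data
#'
#' @param object A `"cc_drfit"` from [fit_dose_response()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.cc_drfit <- function(object, ...) {
  d <- object$data
  rng <- range(d$dose_uM)
  grid <- tibble::tibble(
    dose_uM = 10^seq(log10(rng[1]), log10(rng[2]), length.out = 200)
  )
  grid$response <- four_param_logistic(grid$dose_uM, object$ec50, object$hill,
                                       object$top, object$bottom)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$dose_uM, y = .data$response)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Dose (uM)", y = "Response (% viability)",
                  title = sprintf("4PL fit: EC50 = %.3g uM, hill = %.2f",
                                  object$ec50, object$hill)) +
    ggplot2::theme_minimal()
}

#' CCI hit plot
#'
#' CCI per compound with the hit cutoff marked, the screen-level view of the
#' cell-cycle perturbation landscape.
#'
#' @param ccis Tibble with `compound` and `cci` (e.g. `run_screen()$cci`).
#' @param cutoff CCI cutoff drawn as a horizontal line (default 10).
#' @return A ggplot object.
#' @export
plot_cci <- function(ccis, cutoff = 10) {
  d <- dplyr::arrange(ccis, dplyr::desc(.data$cci))
  d$rank <- seq_len(nrow(d))
  d$hit <- d$cci > cutoff
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data$cci,
                                  colour = .data$hit)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = cutoff, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "blue", `FALSE` = "grey60"),
                                 name = paste0("CCI > ", cutoff)) +
    ggplot2::labs(x = "Compound rank", y = "Cell Cycle Index") +
    ggplot2::theme_minimal()
}

#' Dendrogram plot for a fingerprint cluster tree
#'
#' @param x A `"cc_tree"`.
#' @param ... Passed to [plot.hclust()].
#' @export
plot.cc_tree <- function(x, ...) {
  hc <- x$hclust
  if (is.null(hc$labels)) hc$labels <- x$labels
  plot(hc, xlab = "", sub = "", main = "Complete-linkage fingerprint tree", ...)
}
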