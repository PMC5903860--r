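# ggplot2 visualisations for memflex result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a density profile along the membrane normal
#'
#' @param object A [density_profile()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot density_profile
#' @export
autoplot.density_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$z_mid, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "z relative to midplane (nm)",
                  y = "number density (per nm)",
                  title = sprintf("Density profile: %s", attr(object, "selection")))
}

#' Plot per-block permeation statistics
#'
#' @param object A [permeation_summary()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot permeation_summary
#' @export
autoplot.permeation_summary <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object),
                              c("n_crossings", "n_rebounds"),
                              names_to = "class", values_to = "count")
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$block), y = .data$count,
                                     fill = .data$class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "block", y = "events",
                  title = "Water slab visits per block")
}

#' Plot a quench trace with its percentage axis
#'
#' @param object A [nbd_quench_percent()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot quench_trace
#' @export
autoplot.quench_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$quench_pct)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 50, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "time (s)", y = "NBD quenching (%)")
}

#' Plot a packing-defect grid
#'
#' @param object A `defect_grid` (one leaflet of a [scan_defects()] result).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot defect_grid
#' @export
autoplot.defect_grid <- function(object, ...) {
  df <- tidyr::expand_grid(i = seq_len(object$nx), j = seq_len(object$ny))
  df$flag <- as.vector(object$flag)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j, fill = .data$flag)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(none = "grey90", shallow = "orange",
                                          deep = "firebrick")) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("%s leaflet packing defects", object$leaflet),
                  x = NULL, y = NULL)
}

#' Plot relative bending rigidities
#'
#' @param object A [relative_rigidity()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rigidity_estimate
#' @export
autoplot.rigidity_estimate <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = stats::reorder(.data$composition, -.data$relative_kb),
                               y = .data$relative_kb)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "relative bending modulus (% of reference)")
}
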