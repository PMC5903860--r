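# broom-style tidiers for memflex result objects.

#' @method tidy rigidity_estimate
#' @export
tidy.rigidity_estimate <- function(x, ...) {
  tibble(composition = x$composition, lr_ratio = x$lr_ratio,
         relative_kb = x$relative_kb)
}

#' @method glance rigidity_estimate
#' @export
glance.rigidity_estimate <- function(x, ...) {
  tibble(reference = attr(x, "reference"),
         n_compositions = nrow(x),
         min_relative_kb = min(x$relative_kb),
         max_relative_kb = max(x$relative_kb))
}

#' @method tidy tube_shape
#' @export
tidy.tube_shape <- function(x, ...) {
  tibble(term = c("length_L", "radius_R", "lr_ratio"),
         estimate = c(x$length_L, x$radius_R, x$lr_ratio))
}

#' @method glance tube_shape
#' @export
glance.tube_shape <- function(x, ...) {
  tibble(length_L = x$length_L, radius_R = x$radius_R, lr_ratio = x$lr_ratio,
         flat = x$flat, n_tube_lipids = x$n_tube_lipids)
}

#' @method tidy scission_call
#' @export
tidy.scission_call <- function(x, ...) {
  dplyr::count(x$components, .data$component, name = "n_lipids")
}

#' @method glance scission_call
#' @export
glance.scission_call <- function(x, ...) {
  tibble(outcome = x$outcome, n_components = x$n_components,
         rupture_location = x$rupture_location)
}

#' @method tidy defect_summary
#' @export
tidy.defect_summary <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(as_tibble(x), .data$leaflet, .data$class),
    mean_n_defects = mean(.data$n_defects),
    mean_area = mean(.data$total_area),
    sd_area = sd_or_zero(.data$total_area),
    .groups = "drop")
}
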