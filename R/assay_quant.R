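# Wet-assay quantification: dithionite/NBD quenching, GUV permeability and
# shrinkage, apparent radius from projected area, and GTPase rates from
# malachite-green phosphate series.

#' NBD quenching percentage over time
#'
#' Converts a dithionite quenching fluorescence trace to
#' `Quenching (%) = (F_i - F_0) / (F_T - F_0) * 100`, where `F_0` is the
#' pre-dithionite baseline (mean fluorescence over `f0_window`, default the
#' 0-30 s span before dithionite addition), `F_i` the fluorescence at time i
#' and `F_T` the full-quench value after detergent solubilises the vesicles.
#' The fast phase reports the externally oriented probe fraction (about 50%
#' when the probe distributes evenly over both leaflets); the slow phase
#' reports quencher permeation. The result is invariant under affine
#' rescaling (gain/offset) of the fluorescence axis.
#'
#' @param trace Data frame with columns `time_s` and `fluorescence`.
#' @param f0_window Length-2 numeric, time span (s) averaged for `F_0`.
#' @param ft Full-quench fluorescence `F_T`; when `NULL` it is taken as the
#'   mean fluorescence at `time_s >= triton_time`.
#' @param triton_time Time (s) of detergent addition, used when `ft` is NULL.
#' @return A tibble of class `quench_trace`: `time_s`, `fluorescence`,
#'   `quench_pct`.
#' @export
nbd_quench_percent <- function(trace, f0_window = c(0, 30), ft = NULL,
                               triton_time = NULL) {
  trace <- as_tibble(trace)
  in_w <- trace$time_s >= f0_window[1] & trace$time_s <= f0_window[2]
  if (!any(in_w)) abort("no points in the F0 window.")
  f0 <- mean(trace$fluorescence[in_w])
  if (is.null(ft)) {
    if (is.null(triton_time)) abort("supply `ft` or `triton_time`.")
    post <- trace$time_s >= triton_time
    if (!any(post)) abort("no points at or after `triton_time`.")
    ft <- mean(trace$fluorescence[post])
  }
  if (ft == f0) abort("no dynamic range: F0 equals FT.")
  out <- dplyr::mutate(trace,
                       quench_pct = (.data$fluorescence - f0) / (ft - f0) * 100)
  class(out) <- c("quench_trace", class(out))
  attr(out, "f0") <- f0
  attr(out, "ft") <- ft
  out
}

#' Quenching plateau at a stated time
#'
#' Reads the quench percentage at the time point closest to `at` — used to
#' extract the fast-phase plateau (e.g. at 300 s) from a quench trace.
#'
#' @param quench A [nbd_quench_percent()] result.
#' @param at Time (s) at which to read the plateau.
#' @return The quench percentage (scalar).
#' @export
quench_plateau <- function(quench, at = 300) {
  quench$quench_pct[which.min(abs(quench$time_s - at))]
}

#' GUV permeability percentage
#'
#' `Permeability (%) = I_in / I_ex * 100`, where `I_in` is the mean probe
#' fluorescence inside an individual giant vesicle and `I_ex` the mean
#' external fluorescence of the probe in solution. 100% means the probe has
#' fully equilibrated across the membrane.
#'
#' @param measurements Data frame with columns `i_in` and `i_ex` (one row
#'   per vesicle), or two numeric vectors via `i_in`/`i_ex`.
#' @return The input tibble with a `permeability_pct` column.
#' @export
guv_permeability <- function(measurements) {
  m <- as_tibble(measurements)
  if (any(m$i_ex <= 0)) abort("`i_ex` must be positive.")
  if (any(m$i_in < 0)) abort("intensities must be non-negative.")
  dplyr::mutate(m, permeability_pct = 100 * .data$i_in / .data$i_ex)
}

#' GUV shrinkage percentage
#'
#' The printed assay formula is `Shrinking (%) = 100 * A_0 / A_i` with `A_0`
#' the vesicle area at time zero and `A_i` the area after incubation; it
#' grows above 100% as vesicles shrink. The documented alternative
#' `ratio = "consumed"` reports `100 * (1 - A_i / A_0)`, the percentage of
#' initial area consumed, which stays in [0, 100] for shrinking vesicles.
#'
#' @param measurements Data frame with columns `a0` and `ai` (areas, same
#'   units, both positive).
#' @param ratio `"printed"` (default, `100 * A0/Ai`) or `"consumed"`.
#' @return The input tibble with a `shrinkage_pct` column.
#' @export
guv_shrinkage <- function(measurements, ratio = c("printed", "consumed")) {
  ratio <- match.arg(ratio)
  m <- as_tibble(measurements)
  if (any(m$ai <= 0) || any(m$a0 <= 0)) abort("areas must be positive.")
  if (ratio == "printed") {
    dplyr::mutate(m, shrinkage_pct = 100 * .data$a0 / .data$ai)
  } else {
    dplyr::mutate(m, shrinkage_pct = 100 * (1 - .data$ai / .data$a0))
  }
}

#' Apparent radius from a projected area
#'
#' `R = sqrt(A / pi)`: the radius of the circle with the measured apparent
#' area, as used to size vesicle profiles on electron micrographs.
#'
#' @param area Projected area(s); the radius is returned in the matching
#'   length unit (nm^2 in, nm out).
#' @return Numeric vector of radii.
#' @export
apparent_radius <- function(area) {
  if (any(area < 0)) abort("`area` must be non-negative.")
  sqrt(area / pi)
}

#' GTPase rate from a malachite-green phosphate series
#'
#' Calibrates 650 nm absorbances to phosphate concentration with a
#' least-squares line through the standards (intercept included, absorbing
#' background), fits the calibrated early time course with a least-squares
#' line over `fit_window`, and reports the hydrolysis rate
#' `slope / [dynamin]` in s^-1. The result is invariant under any affine
#' absorbance transformation applied consistently to series and standards.
#'
#' @param series Data frame with columns `time_s` and `abs650`.
#' @param standards Data frame with columns `conc_um` (0-200 uM range
#'   typical) and `abs`; must be strictly monotone in absorbance and span at
#'   least three concentrations.
#' @param dynamin_um Enzyme concentration in uM (> 0).
#' @param fit_window Length-2 time span (s) of the fitted linear phase;
#'   default 15-120 s.
#' @return A list of class `gtpase_fit`: `rate_per_s`, `slope_um_per_s`,
#'   `calibration` (intercept/slope of conc ~ abs), `fit_window`, and
#'   `series` (tibble with the calibrated `conc_um` column).
#' @export
gtpase_rate <- function(series, standards, dynamin_um,
                        fit_window = c(15, 120)) {
  if (dynamin_um <= 0) abort("`dynamin_um` must be positive.")
  standards <- as_tibble(standards)
  if (dplyr::n_distinct(standards$conc_um) < 3L) {
    abort("standards must span at least 3 concentrations.")
  }
  ord <- order(standards$conc_um)
  d_abs <- diff(standards$abs[ord])
  if (!(all(d_abs > 0) || all(d_abs < 0))) {
    abort("standards are not monotone in absorbance.")
  }
  cal <- stats::lm(conc_um ~ abs, data = standards)
  series <- as_tibble(series)
  series$conc_um <- as.numeric(stats::predict(cal, tibble(abs = series$abs650)))
  in_w <- series$time_s >= fit_window[1] & series$time_s <= fit_window[2]
  if (sum(in_w) < 3L) abort("fewer than 3 points in the fit window.")
  fit <- stats::lm(conc_um ~ time_s, data = series[in_w, ])
  slope <- unname(coef(fit)[["time_s"]])
  out <- list(
    rate_per_s = slope / dynamin_um,
    slope_um_per_s = slope,
    calibration = coef(cal),
    fit_window = fit_window,
    series = series
  )
  class(out) <- "gtpase_fit"
  out
}

#' @export
print.gtpase_fit <- function(x, ...) {
  cat(sprintf("<gtpase_fit> rate %.3f s^-1 (slope %.3f uM/s, window %g-%g s)\n",
              x$rate_per_s, x$slope_um_per_s, x$fit_window[1], x$fit_window[2]))
  invisible(x)
}

#' @method tidy gtpase_fit
#' @export
tidy.gtpase_fit <- function(x, ...) {
  tibble(term = c("rate_per_s", "slope_um_per_s"),
         estimate = c(x$rate_per_s, x$slope_um_per_s))
}

#' @method glance gtpase_fit
#' @export
glance.gtpase_fit <- function(x, ...) {
  tibble(rate_per_s = x$rate_per_s, slope_um_per_s = x$slope_um_per_s,
         n_points = sum(x$series$time_s >= x$fit_window[1] &
                          x$series$time_s <= x$fit_window[2]))
}
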