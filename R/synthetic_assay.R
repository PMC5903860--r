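# Synthetic assay traces with planted parameters: dithionite/NBD quenching,
# GUV permeability/shrinkage measurements, and malachite-green GTPase series.

#' Generate a synthetic assay dataset with planted truth
#'
#' * `kind = "quench"` — a dithionite quenching fluorescence trace: baseline
#'   until `dithionite_time`, then a two-phase decay in which the externally
#'   oriented probe fraction (`outer_fraction`) quenches at `k_fast` (the
#'   default `Inf` is instantaneous) and the remaining probes quench at
#'   `k_slow` (permeation; 0 plants a pure plateau at
#'   `100 * outer_fraction` %), and full quench after `triton_time`.
#' * `kind = "guv"` — per-vesicle intensity and area records with planted
#'   permeability (%) and area ratio.
#' * `kind = "gtpase"` — linear phosphate accrual at `rate_per_s * dynamin_um`
#'   uM/s sampled on the standard time grid (15, 45, 75, 120, 180, 240,
#'   360 s), mapped to 650 nm absorbance through a linear standard response
#'   and corrupted by Gaussian concentration noise `noise_um`; a standards
#'   table over 0-200 uM is generated with the same response.
#'
#' @param kind `"quench"`, `"guv"` or `"gtpase"`.
#' @param params Named list overriding the per-kind defaults listed above.
#' @param seed Integer seed; fully determines the output.
#' @return A list with `data` (tibble; for `"gtpase"` also `standards` and
#'   `dynamin_um`) and `truth` (class `ground_truth`).
#' @export
make_assay_series <- function(kind = c("quench", "guv", "gtpase"),
                              params = list(), seed = 1L) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    quench = list(f0 = 1000, ft = 50, outer_fraction = 0.5, k_fast = Inf,
                  k_slow = 0, dithionite_time = 30, triton_time = 350,
                  t_end = 400, dt_s = 1, noise_sd = 0),
    guv = list(n_guv = 20, permeability_pct = 10, i_ex = 300,
               a0 = 1000, area_ratio = 0.5, noise_frac = 0),
    gtpase = list(rate_per_s = 2, dynamin_um = 0.3, noise_um = 0,
                  times = c(15, 45, 75, 120, 180, 240, 360),
                  abs_slope = 0.005, abs_intercept = 0.05,
                  standards_conc = seq(0, 200, by = 50))
  )
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown) > 0L) {
    abort(sprintf("unknown parameter(s) for kind '%s': %s", kind,
                  paste(unknown, collapse = ", ")))
  }
  p <- utils::modifyList(defaults, params)
  for (ns in c("noise_sd", "noise_frac", "noise_um")) {
    if (!is.null(p[[ns]]) && p[[ns]] < 0) abort("negative noise scale.")
  }
  with_seed(seed, switch(kind,
    quench = make_quench(p),
    guv = make_guv(p),
    gtpase = make_gtpase(p)
  ))
}

make_quench <- function(p) {
  times <- seq(0, p$t_end, by = p$dt_s)
  el <- pmax(0, times - p$dithionite_time)
  # quenching acts strictly after the dithionite addition time, so the
  # pre-addition window (including t = dithionite_time) is pure baseline
  fast_q <- if (is.infinite(p$k_fast)) as.numeric(times > p$dithionite_time)
            else (1 - exp(-p$k_fast * el)) * (times > p$dithionite_time)
  slow_q <- (1 - exp(-p$k_slow * el)) * (times > p$dithionite_time)
  quenched <- p$outer_fraction * fast_q + (1 - p$outer_fraction) * slow_q
  quenched[times >= p$triton_time] <- 1
  f <- p$ft + (p$f0 - p$ft) * (1 - quenched)
  if (p$noise_sd > 0) f <- f + rnorm(length(f), 0, p$noise_sd)
  truth <- structure(list(
    kind = "quench", outer_fraction = p$outer_fraction, k_slow = p$k_slow,
    fast_plateau_pct = 100 * p$outer_fraction,
    expected_quench_at = function(t) {
      100 * (p$outer_fraction + (1 - p$outer_fraction) *
               (1 - exp(-p$k_slow * max(0, t - p$dithionite_time))))
    }
  ), class = "ground_truth")
  list(data = tibble(time_s = times, fluorescence = f), truth = truth)
}

make_guv <- function(p) {
  i_in <- p$i_ex * p$permeability_pct / 100
  ai <- p$a0 * p$area_ratio
  jitter <- function(x) {
    if (p$noise_frac > 0) x * (1 + rnorm(p$n_guv, 0, p$noise_frac)) else rep(x, p$n_guv)
  }
  dat <- tibble(
    guv_id = seq_len(p$n_guv),
    i_in = jitter(i_in), i_ex = rep(p$i_ex, p$n_guv),
    a0 = rep(p$a0, p$n_guv), ai = jitter(ai)
  )
  truth <- structure(list(
    kind = "guv", permeability_pct = p$permeability_pct,
    shrinkage_printed_pct = 100 / p$area_ratio,
    shrinkage_consumed_pct = 100 * (1 - p$area_ratio)
  ), class = "ground_truth")
  list(data = dat, truth = truth)
}

make_gtpase <- function(p) {
  conc_true <- p$rate_per_s * p$dynamin_um * p$times
  conc_obs <- conc_true + if (p$noise_um > 0) rnorm(length(p$times), 0, p$noise_um) else 0
  dat <- tibble(time_s = p$times,
                abs650 = p$abs_intercept + p$abs_slope * conc_obs)
  standards <- tibble(conc_um = p$standards_conc,
                      abs = p$abs_intercept + p$abs_slope * p$standards_conc)
  truth <- structure(list(
    kind = "gtpase", rate_per_s = p$rate_per_s, dynamin_um = p$dynamin_um,
    noise_um = p$noise_um
  ), class = "ground_truth")
  list(data = dat, standards = standards, dynamin_um = p$dynamin_um,
       truth = truth)
}

#' Serialise ground truth to JSON
#'
#' Ground-truth objects accompany every generated dataset and are written as
#' plain JSON so fixtures stay diffable; closures (derived-value helpers)
#' are dropped on write.
#'
#' @param truth A `ground_truth` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  drop_funs <- function(x) {
    if (is.list(x) && !is.data.frame(x)) {
      lapply(x[!vapply(x, is.function, logical(1))], drop_funs)
    } else x
  }
  jsonlite::write_json(drop_funs(unclass(truth)), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "columns", null = "null")
  invisible(path)
}

#' Read serialised ground truth
#'
#' @param path Path written by [write_ground_truth()].
#' @return A `ground_truth` object (tables restored as tibbles).
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(x$permeation)) x$permeation <- as_tibble(x$permeation)
  structure(x, class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> kind: %s\n", x$kind))
  invisible(x)
}
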