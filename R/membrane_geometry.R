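# Per-frame bilayer reference geometry and density profiles along the
# membrane normal (z).

#' Per-frame bilayer reference geometry
#'
#' Splits the phosphate z distribution of a frame into two leaflets
#' (deterministic two-means split), and derives the bilayer thickness
#' (distance between the mean phosphate heights of the two leaflets), the
#' midplane (their midpoint) and the hydrophobic slab, a band centred on the
#' midplane whose width is `slab_fraction` of the thickness. The 0.65 default
#' defines the membrane centre region used to score water visits.
#'
#' A phosphate z distribution whose two-means split separates by less than
#' 1 nm is rejected as "not a planar bilayer" (tubes and micelles fail here).
#' A lipid whose phosphate sits exactly on the midplane is assigned by its
#' glycerol z instead.
#'
#' @param frame An [md_frame()].
#' @param topo An [apply_lipid_templates()] result.
#' @param slab_fraction Fraction of the thickness spanned by the hydrophobic
#'   slab (dimensionless, default 0.65).
#' @return An object of class `membrane_ref`: list with `midplane_z`,
#'   `thickness`, `slab_lo`, `slab_hi`, `slab_fraction` (nm where relevant)
#'   and `leaflets`, a tibble (residue_id, leaflet).
#' @export
membrane_reference <- function(frame, topo, slab_fraction = 0.65) {
  stopifnot_scalar_number(slab_fraction, "slab_fraction")
  if (nrow(topo$lipids) < 2L) abort("need at least 2 lipids with phosphates.")
  pz <- frame$coords[topo$lipids$phosphate_id, 3]
  km <- two_means_1d(pz)
  if (diff(km$centers) < 1) {
    abort("not a planar bilayer: phosphate z distribution is unimodal.")
  }
  lower_mean <- mean(pz[km$cluster == 1L])
  upper_mean <- mean(pz[km$cluster == 2L])
  thickness <- upper_mean - lower_mean
  midplane <- (upper_mean + lower_mean) / 2
  half_slab <- slab_fraction * thickness / 2

  leaflet <- ifelse(pz > midplane, "upper", "lower")
  at_mid <- which(pz == midplane)
  if (length(at_mid) > 0L) {
    gz <- frame$coords[topo$lipids$glycerol_id[at_mid], 3]
    leaflet[at_mid] <- ifelse(gz > midplane, "upper", "lower")
    warn(sprintf("%d lipid(s) with phosphate exactly at midplane assigned by glycerol z.",
                 length(at_mid)))
  }

  structure(list(
    midplane_z = midplane,
    thickness = thickness,
    slab_lo = midplane - half_slab,
    slab_hi = midplane + half_slab,
    slab_fraction = slab_fraction,
    leaflets = tibble(residue_id = topo$lipids$residue_id, leaflet = leaflet)
  ), class = "membrane_ref")
}

#' @export
print.membrane_ref <- function(x, ...) {
  cat(sprintf("<membrane_ref> midplane %.3f nm, thickness %.3f nm, slab [%.3f, %.3f] nm (fraction %.2f)\n",
              x$midplane_z, x$thickness, x$slab_lo, x$slab_hi, x$slab_fraction))
  invisible(x)
}

#' Bilayer reference geometry for every frame of a trajectory
#'
#' Slab bounds are computed per frame (not trajectory-averaged) so that
#' membrane drift and undulation do not smear the slab; permeation
#' bookkeeping tracks these per-frame bounds. The leaflet assignment of the
#' first frame is attached as attribute `"leaflets"` (lipids are assumed not
#' to flip on analysis timescales).
#'
#' @param traj An [md_trajectory()].
#' @param topo An [apply_lipid_templates()] result.
#' @param slab_fraction Slab width as a fraction of the thickness.
#' @return A tibble with one row per frame: `frame`, `time`, `midplane_z`,
#'   `thickness`, `slab_lo`, `slab_hi`; attribute `leaflets`.
#' @export
membrane_reference_traj <- function(traj, topo, slab_fraction = 0.65) {
  refs <- lapply(seq_along(traj$times), function(i) {
    membrane_reference(traj_frame(traj, i), topo, slab_fraction)
  })
  out <- tibble(
    frame = seq_along(traj$times),
    time = traj$times,
    midplane_z = vapply(refs, `[[`, numeric(1), "midplane_z"),
    thickness = vapply(refs, `[[`, numeric(1), "thickness"),
    slab_lo = vapply(refs, `[[`, numeric(1), "slab_lo"),
    slab_hi = vapply(refs, `[[`, numeric(1), "slab_hi")
  )
  attr(out, "leaflets") <- refs[[1]]$leaflets
  attr(out, "slab_fraction") <- slab_fraction
  out
}

resolve_selection <- function(topo, selection) {
  lip <- topo$lipids
  ids <- switch(selection,
    sn1 = unlist(lip$sn1_ids),
    sn2 = unlist(lip$sn2_ids),
    water = topo$water_oxygens,
    phosphate = lip$phosphate_id,
    glycerol = lip$glycerol_id,
    sn1_terminal = lip$sn1_terminal,
    sn2_terminal = lip$sn2_terminal,
    aliphatic = unlist(lip$aliphatic_ids),
    abort(sprintf("unknown selection '%s'.", selection))
  )
  ids <- as.integer(ids)
  if (length(ids) == 0L) abort(sprintf("selection '%s' resolves to no atoms.", selection))
  ids
}

#' Number-density profile along the membrane normal
#'
#' Histograms the z coordinates of a selection, measured relative to the
#' per-frame midplane and averaged over frames. The profile is normalised as
#' a number density per nm so that `sum(density * bin_width)` equals the mean
#' selected-atom count per frame.
#'
#' @param traj An [md_trajectory()].
#' @param topo An [apply_lipid_templates()] result.
#' @param selection One of `"sn1"`, `"sn2"`, `"water"`, `"phosphate"`,
#'   `"glycerol"`, `"sn1_terminal"`, `"sn2_terminal"`, `"aliphatic"`.
#' @param n_bins Number of histogram bins (default 100).
#' @param range Half-open z range (nm, midplane-relative); default
#'   `c(-thickness, thickness)` using the mean thickness.
#' @param refs Optional precomputed [membrane_reference_traj()] table.
#' @return A tibble of class `density_profile`: `z_lo`, `z_hi`, `z_mid` (nm),
#'   `count` (mean per frame in bin), `density` (per nm);
#'   attribute `selection`.
#' @export
density_profile <- function(traj, topo, selection, n_bins = 100,
                            range = NULL, refs = NULL) {
  ids <- resolve_selection(topo, selection)
  if (is.null(refs)) refs <- membrane_reference_traj(traj, topo)
  # traj_axis_matrix returns n_frames x n_ids; subtract per-frame midplane
  zm <- sweep(traj_axis_matrix(traj, ids), 1, refs$midplane_z)
  if (is.null(range)) {
    th <- mean(refs$thickness)
    range <- c(-th, th)
  }
  edges <- seq(range[1], range[2], length.out = n_bins + 1L)
  width <- diff(edges)[1]
  counts <- tabulate(findInterval(as.vector(zm), edges,
                                  rightmost.closed = TRUE, left.open = FALSE),
                     nbins = n_bins + 1L)[seq_len(n_bins)]
  mean_counts <- counts / length(traj$times)
  out <- tibble(
    z_lo = edges[-(n_bins + 1L)],
    z_hi = edges[-1L],
    z_mid = (edges[-(n_bins + 1L)] + edges[-1L]) / 2,
    count = mean_counts,
    density = mean_counts / width
  )
  class(out) <- c("density_profile", class(out))
  attr(out, "selection") <- selection
  out
}
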