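# Tether/tube geometry, relative bending rigidity from L/R at equal force,
# and scission-outcome classification for pulled-membrane configurations.
#
# The bending energy of a membrane tube is E_b = pi * K_b * L / R, so tubes
# pulled to the same stored curvature energy at the same force report the
# inverse of their relative bending modulus through L/R.

#' Extract tube geometry from a pulled-membrane frame
#'
#' Assumes a flat base bilayer plus (possibly) a cylindrical protrusion along
#' `axis` (default +z). The flat-region headgroup level `base_z` is found
#' from the two dominant peaks of the phosphate height histogram (the base
#' bilayer's two leaflets); `base_z` is the upper one. Tube beads are lipid
#' atoms higher than `base_z` plus twice the base roughness (SD of the base
#' headgroup heights); if none exist the frame is flat (`L = 0`, `R` is NA).
#' `L` is the maximal tube-bead height above `base_z` minus `base_offset`;
#' `R` is the midsurface radius: tube headgroup radial distances from the
#' tube's own axis are split into inner/outer leaflet groups (two-means) and
#' the two mean radii averaged. The cap and junction regions (within
#' `end_margin` of either tube end) are excluded from the radius estimate.
#'
#' @param frame An [md_frame()].
#' @param topo An [apply_lipid_templates()] result.
#' @param axis Pulling axis; only the default `c(0, 0, 1)` is supported.
#' @param base_offset Height offset subtracted from L (nm, default 0).
#' @param end_margin Axial margin excluded from the radius fit (nm).
#' @param force_label,time_label Optional metadata carried into the result
#'   (kJ mol^-1 nm^-1 and ns).
#' @return A one-row tibble of class `tube_shape`: `length_L`, `radius_R`,
#'   `lr_ratio`, `base_z` (nm), `flat` (logical), `axis_x`, `axis_y`,
#'   `force_label`, `time_label`, `n_tube_lipids`.
#' @export
fit_tube <- function(frame, topo, axis = c(0, 0, 1), base_offset = 0,
                     end_margin = 1.0, force_label = NA_real_,
                     time_label = NA_real_) {
  if (!isTRUE(all.equal(as.numeric(axis), c(0, 0, 1)))) {
    abort("only the +z pulling axis is supported.")
  }
  head_z <- frame$coords[topo$lipids$phosphate_id, 3]

  # base levels: the two most populated 0.25 nm bins of the headgroup height
  # histogram are the flat bilayer's two leaflets
  br <- seq(min(head_z) - 0.25, max(head_z) + 0.5, by = 0.25)
  h <- tabulate(findInterval(head_z, br), nbins = length(br))
  peak1 <- which.max(h)
  # second peak: at least two bins away from the first
  h2 <- h
  h2[pmax(1, peak1 - 1):pmin(length(h), peak1 + 1)] <- -1L
  peak2 <- which.max(h2)
  lo_bin <- min(peak1, peak2); hi_bin <- max(peak1, peak2)
  hi_centre <- br[hi_bin] + 0.125
  base_heads <- head_z[abs(head_z - hi_centre) <= 0.3]
  base_z <- stats::median(base_heads)
  roughness <- max(stats::sd(base_heads), 0.05)

  lipid_atom_ids <- unlist(lapply(seq_len(nrow(topo$lipids)), function(i) {
    c(topo$lipids$phosphate_id[i], topo$lipids$glycerol_id[i],
      topo$lipids$sn1_ids[[i]], topo$lipids$sn2_ids[[i]])
  }))
  bead_z <- frame$coords[lipid_atom_ids, 3]
  thr <- base_z + 2 * roughness
  tube_beads <- lipid_atom_ids[bead_z > thr]

  mk <- function(L, R, flat, n_tube) {
    out <- tibble(
      length_L = L, radius_R = R,
      lr_ratio = ifelse(flat, NA_real_, L / R),
      base_z = base_z, flat = flat,
      axis_x = NA_real_, axis_y = NA_real_,
      force_label = force_label, time_label = time_label,
      n_tube_lipids = n_tube
    )
    class(out) <- c("tube_shape", class(out))
    out
  }
  # a "protrusion" shorter than a monolayer (or a handful of jitter
  # outliers) is still a flat membrane
  if (length(tube_beads) == 0L ||
      max(frame$coords[tube_beads, 3]) - base_z < 1.5) {
    return(mk(0, NA_real_, TRUE, 0L))
  }

  L <- max(frame$coords[tube_beads, 3]) - base_z - base_offset

  tube_heads <- topo$lipids$phosphate_id[
    frame$coords[topo$lipids$phosphate_id, 3] > thr]
  if (length(tube_heads) < 4L) {
    return(mk(0, NA_real_, TRUE, 0L))
  }
  hx <- frame$coords[tube_heads, 1]
  hy <- frame$coords[tube_heads, 2]
  hz <- frame$coords[tube_heads, 3]
  keep <- hz > base_z + end_margin & hz < base_z + L - end_margin
  if (sum(keep) < 4L) keep <- rep(TRUE, length(hz))
  cx <- mean(hx[keep]); cy <- mean(hy[keep])
  rad <- sqrt((hx[keep] - cx)^2 + (hy[keep] - cy)^2)
  km <- two_means_1d(rad)
  R <- mean(km$centers) # midsurface: average of inner and outer leaflet radii
  out <- mk(L, R, FALSE, length(tube_heads))
  out$axis_x <- cx
  out$axis_y <- cy
  out
}

#' Relative bending rigidity from L/R at equal force
#'
#' Tubes pulled to the same stored curvature energy satisfy
#' `E_b = pi * K_b * L/R` with equal `E_b`, so the bending modulus of a
#' composition relative to a reference is the inverse ratio of their
#' length-to-radius ratios: `relative_Kb = 100 * LR(reference) / LR(c)` (%).
#'
#' @param lr_table Data frame with columns `composition` and `lr_ratio`
#'   (nm/nm; alternatively `L_nm` and `R_nm`), and optionally `force` and
#'   `time_ns`, which must then be constant across rows.
#' @param reference Composition label serving as the 100% reference.
#' @return A tibble of class `rigidity_estimate`: `composition`, `lr_ratio`,
#'   `relative_kb` (% of reference); attribute `reference`.
#' @export
relative_rigidity <- function(lr_table, reference) {
  lr_table <- as_tibble(lr_table)
  if (!"lr_ratio" %in% names(lr_table)) {
    if (!all(c("L_nm", "R_nm") %in% names(lr_table))) {
      abort("`lr_table` needs `lr_ratio` or `L_nm` and `R_nm` columns.")
    }
    lr_table$lr_ratio <- lr_table$L_nm / lr_table$R_nm
  }
  if (any(!is.finite(lr_table$lr_ratio)) || any(lr_table$lr_ratio <= 0)) {
    abort("all L/R ratios must be positive.")
  }
  for (col in c("force", "time_ns")) {
    if (col %in% names(lr_table) &&
        length(unique(lr_table[[col]])) > 1L) {
      abort(sprintf("mismatched `%s` labels: all tubes must share one.", col))
    }
  }
  if (!reference %in% lr_table$composition) {
    abort(sprintf("reference composition '%s' not present.", reference))
  }
  lr_ref <- lr_table$lr_ratio[match(reference, lr_table$composition)]
  out <- tibble(
    composition = lr_table$composition,
    lr_ratio = lr_table$lr_ratio,
    relative_kb = 100 * lr_ref / lr_table$lr_ratio
  )
  class(out) <- c("rigidity_estimate", class(out))
  attr(out, "reference") <- reference
  out
}

# Single-linkage connected components over points at `cutoff`, periodic in
# x-y only. Neighbour pairs come from cell binning; the component search is
# delegated to igraph.
point_components <- function(xyz, box, cutoff) {
  n <- nrow(xyz)
  xw <- wrap_box(xyz[, 1], box[1])
  yw <- wrap_box(xyz[, 2], box[2])
  zz <- xyz[, 3]
  ncx <- max(1L, floor(box[1] / cutoff))
  ncy <- max(1L, floor(box[2] / cutoff))
  cix <- pmin(ncx, floor(xw / (box[1] / ncx)) + 1L)
  ciy <- pmin(ncy, floor(yw / (box[2] / ncy)) + 1L)
  ciz <- as.integer(floor(zz / cutoff))
  ciz <- ciz - min(ciz) + 1L
  ncz <- max(ciz)
  code <- cix + ncx * (ciy - 1L) + ncx * ncy * (ciz - 1L)
  cells <- split(seq_len(n), code)
  cell_code <- as.integer(names(cells))
  cell_ix <- (cell_code - 1L) %% ncx + 1L
  cell_iy <- ((cell_code - 1L) %/% ncx) %% ncy + 1L
  cell_iz <- (cell_code - 1L) %/% (ncx * ncy) + 1L
  offsets <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offsets <- offsets[offsets$dz > 0 | (offsets$dz == 0 & (offsets$dy > 0 |
                       (offsets$dy == 0 & offsets$dx >= 0))), ] # half-shell
  from <- vector("list", length(cells) * nrow(offsets))
  to <- vector("list", length(cells) * nrow(offsets))
  k <- 0L
  for (o in seq_len(nrow(offsets))) {
    nx2 <- (cell_ix + offsets$dx[o] - 1L) %% ncx + 1L
    ny2 <- (cell_iy + offsets$dy[o] - 1L) %% ncy + 1L
    nz2 <- cell_iz + offsets$dz[o]
    valid <- nz2 >= 1L & nz2 <= ncz
    nb_code <- nx2 + ncx * (ny2 - 1L) + ncx * ncy * (nz2 - 1L)
    nb <- match(nb_code, cell_code)
    for (ci in which(valid & !is.na(nb))) {
      pts <- cells[[ci]]
      qts <- cells[[nb[ci]]]
      dx <- min_image(outer(xw[pts], xw[qts], "-"), box[1])
      dy <- min_image(outer(yw[pts], yw[qts], "-"), box[2])
      dz <- outer(zz[pts], zz[qts], "-")
      close <- which(dx^2 + dy^2 + dz^2 <= cutoff^2, arr.ind = TRUE)
      if (nrow(close) > 0L) {
        k <- k + 1L
        from[[k]] <- pts[close[, 1]]
        to[[k]] <- qts[close[, 2]]
      }
    }
  }
  if (k == 0L) return(seq_len(n))
  g <- igraph::graph_from_edgelist(
    cbind(unlist(from[seq_len(k)]), unlist(to[seq_len(k)])), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  comp <- igraph::components(g)$membership[seq_len(n)]
  match(comp, unique(comp))
}

#' Classify a scission outcome
#'
#' Builds single-linkage connected components over all lipid beads at
#' `cutoff` (periodic in x-y) and classifies the configuration:
#' * `intact` — one component;
#' * `breakage` — the component holding the pulled patch contains (beyond a
#'   `margin`) no lipids other than the patch: the rupture happened at the
#'   lipids where the force is applied;
#' * `fission` — the pulled-patch component also carries tube-body lipids
#'   separated from the base membrane: the rupture happened at the neck.
#'
#' @param frame An [md_frame()].
#' @param topo An [apply_lipid_templates()] result.
#' @param pulled_lipids Residue ids of the lipids the pulling force acts on.
#' @param cutoff Single-linkage distance cutoff in nm (default 1.2,
#'   appropriate for coarse-grained beads).
#' @param margin Maximum number of non-patch lipids tolerated in the pulled
#'   component for a `breakage` call (default 10).
#' @return A list of class `scission_call`: `outcome` (`intact`/`fission`/
#'   `breakage`/`indeterminate`), `n_components`, `rupture_location`
#'   (`neck`/`pulled_patch`/`none`), and `components`, a tibble
#'   (residue_id, component).
#' @export
detect_scission <- function(frame, topo, pulled_lipids, cutoff = 1.2,
                            margin = 10L) {
  lip <- topo$lipids
  atom_ids <- unlist(lapply(seq_len(nrow(lip)), function(i) {
    c(lip$phosphate_id[i], lip$glycerol_id[i], lip$sn1_ids[[i]], lip$sn2_ids[[i]])
  }))
  owner <- rep(lip$residue_id, vapply(seq_len(nrow(lip)), function(i) {
    2L + length(lip$sn1_ids[[i]]) + length(lip$sn2_ids[[i]])
  }, integer(1)))
  comp_bead <- point_components(frame$coords[atom_ids, , drop = FALSE],
                                frame$box, cutoff)
  # a lipid joins the component holding most of its beads
  comp_lipid <- vapply(split(comp_bead, owner), function(cc) {
    as.integer(names(which.max(table(cc))))
  }, integer(1))
  comps <- tibble(residue_id = as.integer(names(comp_lipid)),
                  component = unname(comp_lipid))
  n_comp <- dplyr::n_distinct(comps$component)

  if (length(pulled_lipids) == 0L) {
    out <- list(outcome = "indeterminate", n_components = n_comp,
                rupture_location = "none", components = comps)
    class(out) <- "scission_call"
    return(out)
  }
  if (n_comp == 1L) {
    out <- list(outcome = "intact", n_components = 1L,
                rupture_location = "none", components = comps)
    class(out) <- "scission_call"
    return(out)
  }
  pulled_comps <- comps$component[comps$residue_id %in% pulled_lipids]
  pc <- as.integer(names(which.max(table(pulled_comps))))
  in_pc <- comps$residue_id[comps$component == pc]
  n_non_patch <- sum(!in_pc %in% pulled_lipids)
  outcome <- if (n_non_patch <= margin) "breakage" else "fission"
  out <- list(
    outcome = outcome, n_components = n_comp,
    rupture_location = if (outcome == "breakage") "pulled_patch" else "neck",
    components = comps
  )
  class(out) <- "scission_call"
  out
}

#' @export
print.scission_call <- function(x, ...) {
  cat(sprintf("<scission_call> %s (%d component(s), rupture: %s)\n",
              x$outcome, x$n_components, x$rupture_location))
  invisible(x)
}
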