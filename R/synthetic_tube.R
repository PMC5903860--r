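# Synthetic tubulated coarse-grained configurations with known length,
# radius and topology (intact / severed at mid-tube / pulled patch detached).

#' Coarse-grained lipid template used by the tube generator
#'
#' Bead names stand in for carbons: `PO4` head bead, `GL` glycerol bead and
#' two four-bead tails (`A1..A4`, `B1..B4`); the terminal tail bead plays
#' the part of the terminal CH3.
#'
#' @return A [lipid_template()] for residue name `"CGL"`.
#' @export
cg_lipid_template <- function() {
  lipid_template(
    residue_name = "CGL",
    phosphate = "PO4",
    glycerol = "GL",
    sn1 = sprintf("A%d", 1:4),
    sn2 = sprintf("B%d", 1:4)
  )
}

# One CG lipid as a radial/vertical bead string from the head inward.
# `head` is the head-bead position, `dir` the inward unit vector.
cg_lipid_beads <- function(head, dir, mono_thickness = 1.0) {
  steps <- seq(0, mono_thickness, length.out = 6L) # P, GL, 4 tail beads
  t(vapply(steps, function(s) head + s * dir, numeric(3)))
}

#' Generate a tubulated membrane frame with planted geometry
#'
#' Builds a flat coarse-grained base bilayer plus a cylindrical protrusion
#' along +z with midsurface radius `R` and height `L`: the outer-leaflet
#' head beads sit at radius `R + 1` nm, the inner-leaflet head beads at
#' `R - 1` nm, and tails meet at the midsurface. `topology` plants the
#' scission outcome: `"severed"` removes a > 1.5 nm axial band of tube
#' lipids at mid-height (rupture at the neck side of the pulled patch);
#' `"patch_detached"` displaces only the pulled-patch lipids (the top 2 nm
#' of the tube) upward beyond any linkage cutoff. `L = 0` produces a flat
#' bilayer.
#'
#' @param R Midsurface radius (nm), > 1.2.
#' @param L Tube height (nm), >= 0.
#' @param topology `"intact"`, `"severed"` or `"patch_detached"`.
#' @param bead_spacing Lateral lipid spacing (nm, default 0.8).
#' @param seed Integer seed (positional jitter).
#' @param jitter SD of Gaussian positional jitter (nm).
#' @return A list with `topo`, `frame`, `truth` (class `ground_truth`;
#'   carries `R`, `L`, `topology` and `pulled_lipids`, the residue ids of
#'   the pulled patch).
#' @export
make_tube_frame <- function(R, L, topology = c("intact", "severed", "patch_detached"),
                            bead_spacing = 0.8, seed = 1L, jitter = 0.04) {
  topology <- match.arg(topology)
  if (L > 0 && R <= 1.2) abort("infeasible packing: R must exceed 1.2 nm.")
  if (L < 0) abort("L must be >= 0.")
  with_seed(seed, build_tube(R, L, topology, bead_spacing, jitter))
}

build_tube <- function(R, L, topology, s, jitter) {
  mono <- 1.0            # monolayer head-to-tail-end depth (nm)
  base_mid <- 4.0        # base bilayer mid-plane height
  base_top <- base_mid + mono * 2 # upper head level of the base
  R_out <- if (L > 0) R + mono else 0
  R_in <- if (L > 0) R - mono else 0
  side <- max(3 * R_out, 2 * R_out + 6, 12)
  box <- c(side, side, base_top + L + 4)
  cx <- side / 2; cy <- side / 2

  heads <- list()  # each: list(pos, dir)
  grid <- seq(s / 2, side - s / 2, by = s)
  gxy <- expand.grid(x = grid, y = grid)
  rad <- sqrt((gxy$x - cx)^2 + (gxy$y - cy)^2)
  # base upper leaflet: annulus outside the tube wall
  keep_up <- if (L > 0) rad > R_out + 0.4 else rep(TRUE, nrow(gxy))
  for (i in which(keep_up)) {
    heads[[length(heads) + 1L]] <-
      list(pos = c(gxy$x[i], gxy$y[i], base_top), dir = c(0, 0, -1))
  }
  # base lower leaflet: complete
  for (i in seq_len(nrow(gxy))) {
    heads[[length(heads) + 1L]] <-
      list(pos = c(gxy$x[i], gxy$y[i], base_mid - mono), dir = c(0, 0, 1))
  }
  tube_start <- length(heads) + 1L
  if (L > 0) {
    ring_z <- seq(base_top + s / 2, base_top + L, by = s)
    for (z in ring_z) {
      n_out <- max(6L, round(2 * pi * R_out / s))
      ang <- 2 * pi * (seq_len(n_out) - 0.5) / n_out
      for (a in ang) {
        u <- c(cos(a), sin(a), 0)
        heads[[length(heads) + 1L]] <-
          list(pos = c(cx, cy, z) + R_out * u, dir = -u)
      }
      n_in <- max(4L, round(2 * pi * R_in / s))
      ang <- 2 * pi * (seq_len(n_in) - 0.25) / n_in
      for (a in ang) {
        u <- c(cos(a), sin(a), 0)
        heads[[length(heads) + 1L]] <-
          list(pos = c(cx, cy, z) + R_in * u, dir = u)
      }
    }
    # top rim: close the outer and inner walls so the cap region is marked
    # by the pulled patch (topmost 2 nm of the tube)
  }
  n_lip <- length(heads)
  # each lipid carries 10 beads: P, GL and two 4-bead tails offset sideways
  coords <- do.call(rbind, lapply(heads, function(h) {
    b <- cg_lipid_beads(h$pos, h$dir)
    tails <- b[3:6, , drop = FALSE]
    side_off <- 0.1 * perpendicular_unit(h$dir)
    rbind(b[1:2, , drop = FALSE],
          sweep(tails, 2, side_off, "+"),
          sweep(tails, 2, side_off, "-")) +
      matrix(rnorm(30, 0, jitter), 10, 3)
  }))
  atoms <- new_atoms_tibble(
    rep(c("PO4", "GL", sprintf("A%d", 1:4), sprintf("B%d", 1:4)), n_lip),
    rep("CGL", 10L * n_lip),
    rep(seq_len(n_lip), each = 10L)
  )

  head_z <- coords[(seq_len(n_lip) - 1L) * 10L + 1L, 3]
  is_tube <- seq_len(n_lip) >= tube_start
  pulled <- which(is_tube & head_z > base_top + L - 2)
  if (L > 0 && length(pulled) == 0L) pulled <- which(is_tube & head_z ==
                                                       max(head_z[is_tube]))

  drop_lipids <- integer(0)
  if (topology == "severed") {
    if (L < 6) abort("severed topology needs L >= 6 nm.")
    z_cut <- base_top + L / 2
    drop_lipids <- which(is_tube & abs(head_z - z_cut) < 0.9) # gap > 1.5 nm
  } else if (topology == "patch_detached") {
    rows <- as.vector(outer(1:10, (pulled - 1L) * 10L, "+"))
    coords[rows, 3] <- coords[rows, 3] + 3.0
  }
  if (length(drop_lipids) > 0L) {
    keep_rows <- !(rep(seq_len(n_lip), each = 10L) %in% drop_lipids)
    coords <- coords[keep_rows, , drop = FALSE]
    atoms <- atoms[keep_rows, ]
    atoms$atom_id <- seq_len(nrow(atoms))
    # renumber residues compactly and remap the pulled set
    old_res <- unique(atoms$residue_id)
    pulled <- match(pulled[!pulled %in% drop_lipids], old_res)
    atoms$residue_id <- match(atoms$residue_id, old_res)
  }

  frame <- md_frame(coords, box)
  topo <- apply_lipid_templates(atoms, cg_lipid_template())
  truth <- structure(list(
    kind = "tube",
    R = R, L = L, topology = topology,
    base_z = base_top,
    pulled_lipids = as.integer(pulled),
    n_lipids = dplyr::n_distinct(atoms$residue_id)
  ), class = "ground_truth")
  list(topo = topo, frame = frame, truth = truth)
}

perpendicular_unit <- function(dir) {
  # any unit vector perpendicular to `dir`
  v <- if (abs(dir[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  p <- v - sum(v * dir) * dir
  p / sqrt(sum(p^2))
}
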