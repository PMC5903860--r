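# Fixtures are built in code; nothing binary is stored.

# A minimal hand-built planar bilayer: `n_side^2` lipids per leaflet with
# 5-carbon chains, phosphates at z_mid +/- pz. Returns list(atoms, frame,
# topo).
manual_bilayer <- function(pz = 2, box = c(5, 5, 10), n_side = 2,
                           sn1_len = 5, sn2_len = 5) {
  z_mid <- box[3] / 2
  tmpl <- lipid_template("LIP", "P", "GL",
                         sprintf("A%02d", seq_len(sn1_len)),
                         sprintf("B%02d", seq_len(sn2_len)))
  names_one <- c("P", "GL", sprintf("A%02d", seq_len(sn1_len)),
                 sprintf("B%02d", seq_len(sn2_len)))
  n_lip <- 2 * n_side^2
  atom_name <- rep(names_one, n_lip)
  residue_id <- rep(seq_len(n_lip), each = length(names_one))
  atoms <- tibble::tibble(
    atom_id = seq_along(atom_name),
    atom_name = atom_name,
    residue_name = "LIP",
    residue_id = residue_id,
    element = ifelse(atom_name %in% c("P"), "P", "C")
  )
  coords <- matrix(0, nrow(atoms), 3)
  i <- 0
  for (leaf in c(1, -1)) {
    for (gx in seq_len(n_side)) {
      for (gy in seq_len(n_side)) {
        o <- i * length(names_one)
        x0 <- (gx - 0.5) * box[1] / n_side
        y0 <- (gy - 0.5) * box[2] / n_side
        p_z <- z_mid + leaf * pz
        gl_z <- z_mid + leaf * (pz - 0.2)
        coords[o + 1, ] <- c(x0, y0, p_z)
        coords[o + 2, ] <- c(x0, y0, gl_z)
        coords[o + 2 + seq_len(sn1_len), ] <-
          cbind(x0 + 0.1, y0, gl_z - leaf * seq_len(sn1_len) * 0.3)
        coords[o + 2 + sn1_len + seq_len(sn2_len), ] <-
          cbind(x0 - 0.1, y0, gl_z - leaf * seq_len(sn2_len) * 0.25)
        i <- i + 1
      }
    }
  }
  frame <- md_frame(coords, box)
  list(atoms = atoms, frame = frame, topo = apply_lipid_templates(atoms, tmpl),
       template = tmpl)
}

# Static trajectory replicating one frame nf times at spacing dt (ps).
static_traj <- function(frame, nf = 3, dt = 10) {
  md_trajectory(lapply(seq_len(nf), function(i) {
    md_frame(frame$coords, frame$box, time = (i - 1) * dt)
  }))
}

# Brute-force single-linkage components: full pairwise distances, periodic
# in x-y. Independent of the cell-binned implementation.
brute_components <- function(coords, box, cutoff) {
  n <- nrow(coords)
  dx <- outer(coords[, 1], coords[, 1], "-")
  dx <- dx - box[1] * round(dx / box[1])
  dy <- outer(coords[, 2], coords[, 2], "-")
  dy <- dy - box[2] * round(dy / box[2])
  dz <- outer(coords[, 3], coords[, 3], "-")
  adj <- (dx^2 + dy^2 + dz^2) <= cutoff^2
  comp <- rep(0L, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

# Tiny GRO fixture: one lipid-like residue plus two waters in a 5x5x10 box.
write_tiny_gro <- function(path) {
  lines <- c(
    "tiny fixture t= 0.000",
    "    9",
    "    1LIP      P    1   1.000   1.000   7.000",
    "    1LIP     GL    2   1.000   1.000   6.800",
    "    1LIP    A01    3   1.100   1.000   6.500",
    "    1LIP    A02    4   1.100   1.000   6.200",
    "    1LIP    B01    5   0.900   1.000   6.500",
    "    1LIP    B02    6   0.900   1.000   6.250",
    "    2SOL     OW    7   2.000   2.000   9.000",
    "    2SOL    HW1    8   2.050   2.000   9.050",
    "    3SOL     OW    9   3.000   3.000   1.000",
    "   5.00000   5.00000  10.00000"
  )
  writeLines(lines, path)
  path
}


# Scratch file path under the session tempdir.
local_file <- function(name) file.path(tempdir(), name)

# Constructed interfacial patch with exact geometry for the defect scanner.
#
# The upper leaflet carries a dense layer of head atoms (radius 0.25 nm,
# lateral spacing 0.2 nm) at z = 3.0 and glycerol carbons at z = 2.7.
# Inside a `window` nm square centred in the box the head/glycerol cover is
# removed; every scanner grid point left uncovered receives one exposed
# aliphatic atom placed so its first-contact height is exactly `depth` nm
# below the glycerol level (the atoms sit on scanner grid points, so the
# measured depth is exact).
defect_patch <- function(depth = 0.15, window = 0.5, box = c(3, 3, 8),
                         expose = TRUE) {
  spacing <- 0.2
  gpts <- seq(spacing / 2, box[1] - spacing / 2, by = spacing)
  pts <- expand.grid(x = gpts, y = gpts)
  cx <- box[1] / 2; cy <- box[2] / 2
  in_window <- abs(pts$x - cx) < window / 2 & abs(pts$y - cy) < window / 2

  head_z <- 3.0
  gly_z <- 2.7
  r_atom <- 0.17  # carbon vdW radius used by the scanner
  r_head <- 0.25

  rows <- list()
  add <- function(name, x, y, z, res) rows[[length(rows) + 1L]] <<-
    data.frame(atom_name = name, x = x, y = y, z = z, residue_id = res)

  res <- 0
  # covered region: one mini-lipid (head + glycerol + buried tail) per point
  for (i in which(!in_window)) {
    res <- res + 1
    add("HD", pts$x[i], pts$y[i], head_z, res)
    add("GL", pts$x[i], pts$y[i], gly_z, res)
    add("C1", pts$x[i], pts$y[i], 2.0, res)
    add("C2", pts$x[i], pts$y[i], 1.8, res)
    add("C3", pts$x[i], pts$y[i], 1.6, res)
  }
  # exposure: one tilted lipid per uncovered scanner grid point, its C1
  # surfaced at that point and its head/glycerol parked away from the window
  exposed_res <- integer(0)
  if (expose && window > 0) {
    scan_pts <- seq(0.05, box[1] - 0.05, by = 0.1)
    spxy <- expand.grid(x = scan_pts, y = scan_pts)
    cover_x <- pts$x[!in_window]; cover_y <- pts$y[!in_window]
    uncovered <- vapply(seq_len(nrow(spxy)), function(i) {
      all((spxy$x[i] - cover_x)^2 + (spxy$y[i] - cover_y)^2 >= r_head^2)
    }, logical(1))
    for (i in which(uncovered)) {
      res <- res + 1
      exposed_res <- c(exposed_res, res)
      add("HD", 0.3, 0.3, head_z, res)
      add("GL", 0.3, 0.3, gly_z, res)
      add("C1", spxy$x[i], spxy$y[i], gly_z - depth - r_atom, res)
      add("C2", spxy$x[i], spxy$y[i], gly_z - depth - r_atom - 0.3, res)
      add("C3", spxy$x[i], spxy$y[i], gly_z - depth - r_atom - 0.6, res)
    }
  }
  # a minimal lower leaflet so leaflet splitting works
  for (k in 1:4) {
    res <- res + 1
    x0 <- (k %% 2) * 2 + 0.5; y0 <- (k %/% 2) * 2 + 0.5
    add("HD", x0, y0, 0.5, res)
    add("GL", x0, y0, 0.8, res)
    add("C1", x0, y0, 1.2, res)
    add("C2", x0, y0, 1.4, res)
    add("C3", x0, y0, 1.6, res)
  }
  df <- do.call(rbind, rows)
  atoms <- tibble::tibble(
    atom_id = seq_len(nrow(df)),
    atom_name = df$atom_name,
    residue_name = "MLP",
    residue_id = df$residue_id,
    element = "C"
  )
  tmpl <- lipid_template("MLP", phosphate = "HD", glycerol = "GL",
                         sn1 = c("C1", "C2"), sn2 = c("C3"),
                         aliphatic = c("C1", "C2", "C3"))
  topo <- apply_lipid_templates(atoms, tmpl)
  frame <- md_frame(as.matrix(df[, c("x", "y", "z")]), box)
  list(topo = topo, frame = frame, exposed_res = exposed_res,
       ref = membrane_reference(frame, topo, slab_fraction = 0.65))
}

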