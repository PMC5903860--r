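# Synthetic planar-bilayer trajectories with planted ground truth.
#
# The generator is a fixture factory, not a simulator: no forces are
# computed. Lipids are idealised rigid conformers except for explicitly
# scripted chains, and planted waters follow deterministic z paths realising
# an exact number of crossings and rebounds through the hydrophobic slab.
# Everything is a pure function of (config, seed).

# Evaluate `expr` under a given seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Describe scripted acyl-chain motion for the generator
#'
#' @param kind `"static"` (rigid chain), `"walk"` (terminal carbon performs
#'   a Gaussian random walk, for velocity recovery), `"torsion"` (the chain
#'   folds at its mid carbon on a Bernoulli schedule, planting 3-point
#'   angles), or `"protrusion"` (the terminal carbon follows a square wave
#'   across its glycerol, planting protrusion events).
#' @param step_sd Per-axis SD of the per-frame walk step (nm).
#' @param torsion_rate Per-frame probability that a chain is folded.
#' @param torsion_angle Planted fold angle in degrees (< the 100 deg
#'   threshold by default).
#' @param protrusion_period Square-wave period in frames.
#' @param protrusion_amplitude Outward excursion past the glycerol (nm).
#' @return A list of class `chain_motion`.
#' @export
chain_motion <- function(kind = c("static", "walk", "torsion", "protrusion"),
                         step_sd = 0.05, torsion_rate = 0.2,
                         torsion_angle = 60, protrusion_period = 50,
                         protrusion_amplitude = 0.3) {
  kind <- match.arg(kind)
  structure(list(kind = kind, step_sd = step_sd, torsion_rate = torsion_rate,
                 torsion_angle = torsion_angle,
                 protrusion_period = protrusion_period,
                 protrusion_amplitude = protrusion_amplitude),
            class = "chain_motion")
}

#' Generator configuration for planar-bilayer trajectories
#'
#' Defaults reproduce the simulated study conditions: 2 x 144 phospholipids
#' (two leaflets of 144), an 18-carbon saturated sn1 chain and a 22-carbon
#' polyunsaturated-like sn2 chain per lipid, frames every 10 ps, and about
#' 30 waters per lipid. The `ci` preset (2 x 16 lipids, fewer waters) is the
#' scaled-down fixture used throughout the test-suite.
#'
#' @param n_lipids_per_leaflet Lipids per leaflet (default 144).
#' @param sn1_length,sn2_length Carbons per chain (defaults 18 and 22).
#' @param waters_per_lipid Background waters per lipid (default 30).
#' @param n_frames Number of frames (default 1000).
#' @param dt Frame spacing in ps (default 10).
#' @param thickness Planted phosphate-to-phosphate thickness (nm).
#' @param slab_fraction Hydrophobic-slab fraction used to script permeation
#'   paths (default 0.65).
#' @param box Optional box (nm); default x = y sized to 0.65 nm^2 per lipid,
#'   z = 9.
#' @param n_cross,n_rebound Planted permeation event counts.
#' @param sn1_motion,sn2_motion [chain_motion()] specs per chain label.
#' @param seed Integer seed; fully determines the output.
#' @return A list of class `bilayer_config`.
#' @export
bilayer_config <- function(n_lipids_per_leaflet = 144,
                           sn1_length = 18, sn2_length = 22,
                           waters_per_lipid = 30,
                           n_frames = 1000, dt = 10,
                           thickness = 3.8, slab_fraction = 0.65,
                           box = NULL,
                           n_cross = 0, n_rebound = 0,
                           sn1_motion = chain_motion("static"),
                           sn2_motion = chain_motion("static"),
                           seed = 1L) {
  if (n_lipids_per_leaflet < 2 || sn1_length < 5 || sn2_length < 5) {
    abort("need >= 2 lipids per leaflet and chains of >= 5 carbons.")
  }
  if (any(c(n_cross, n_rebound, waters_per_lipid, n_frames) < 0)) {
    abort("counts must be non-negative.")
  }
  if (is.null(box)) {
    side <- sqrt(2 * n_lipids_per_leaflet * 0.65 / 2)
    box <- c(side, side, 9)
  }
  structure(list(
    n_lipids_per_leaflet = n_lipids_per_leaflet,
    sn1_length = sn1_length, sn2_length = sn2_length,
    waters_per_lipid = waters_per_lipid,
    n_frames = n_frames, dt = dt,
    thickness = thickness, slab_fraction = slab_fraction,
    box = box, n_cross = n_cross, n_rebound = n_rebound,
    sn1_motion = sn1_motion, sn2_motion = sn2_motion,
    seed = as.integer(seed)
  ), class = "bilayer_config")
}

#' Lipid template matching the generator's synthetic lipids
#'
#' @param sn1_length,sn2_length Carbons per chain.
#' @return A [lipid_template()] for residue name `"LIP"`.
#' @export
bilayer_lipid_template <- function(sn1_length = 18, sn2_length = 22) {
  lipid_template(
    residue_name = "LIP",
    phosphate = "P",
    glycerol = "GL",
    sn1 = sprintf("A%02d", seq_len(sn1_length)),
    sn2 = sprintf("B%02d", seq_len(sn2_length))
  )
}

#' Generate a planar-bilayer trajectory with planted ground truth
#'
#' Builds two leaflets of idealised lipids around the box mid-plane with
#' bulk water above and below, then scripts: (a) planted waters whose z
#' paths realise exactly `n_cross` full crossings and `n_rebound` same-side
#' rebounds through the hydrophobic slab (background waters jitter in the
#' bulk and never approach the slab); (b) per-label chain motion per the
#' [chain_motion()] specs. The returned ground truth predicts the exact
#' output of the matching analysis: the planted event table for
#' [detect_permeation_events()], realised velocity/torsion/protrusion values
#' for the chain metrics.
#'
#' @param cfg A [bilayer_config()].
#' @return A list with `topo` ([apply_lipid_templates()] result), `traj`
#'   ([md_trajectory()]) and `truth` (class `ground_truth`).
#' @export
make_bilayer_trajectory <- function(cfg) {
  stopifnot(inherits(cfg, "bilayer_config"))
  with_seed(cfg$seed, build_bilayer(cfg))
}

build_bilayer <- function(cfg) {
  box <- cfg$box
  z_mid <- box[3] / 2
  th <- cfg$thickness
  half_slab <- cfg$slab_fraction * th / 2
  slab_lo <- z_mid - half_slab
  slab_hi <- z_mid + half_slab
  n_lip <- cfg$n_lipids_per_leaflet
  len1 <- cfg$sn1_length
  len2 <- cfg$sn2_length
  nf <- cfg$n_frames

  # ---- topology -------------------------------------------------------
  per_lipid <- 2L + len1 + len2
  grid_n <- ceiling(sqrt(n_lip))
  sx <- box[1] / grid_n
  sy <- box[2] / grid_n
  lip_xy <- cbind(((seq_len(n_lip) - 1L) %% grid_n + 0.5) * sx,
                  ((seq_len(n_lip) - 1L) %/% grid_n + 0.5) * sy)

  lipid_names <- c("P", "GL", sprintf("A%02d", seq_len(len1)),
                   sprintf("B%02d", seq_len(len2)))
  n_bg <- cfg$waters_per_lipid * 2L * n_lip
  n_planted <- cfg$n_cross + cfg$n_rebound
  n_waters <- n_bg + n_planted

  atom_name <- c(rep(lipid_names, 2L * n_lip), rep("OW", n_waters))
  residue_name <- c(rep("LIP", 2L * n_lip * per_lipid), rep("SOL", n_waters))
  residue_id <- c(rep(seq_len(2L * n_lip), each = per_lipid),
                  2L * n_lip + seq_len(n_waters))
  atoms <- new_atoms_tibble(atom_name, residue_name, residue_id)

  # ---- base coordinates ----------------------------------------------
  base <- matrix(0, nrow(atoms), 3)
  chain_z <- function(gl_z, len, end_z) {
    gl_z + (end_z - gl_z) * seq_len(len) / len
  }
  for (leaf in 1:2) { # 1 = upper, 2 = lower
    sgn <- if (leaf == 1L) 1 else -1
    p_z <- z_mid + sgn * th / 2
    gl_z <- z_mid + sgn * (th / 2 - 0.25)
    # sn1 reaches just past the mid-plane (density peak in the centre);
    # sn2 stops short of it (central dip)
    sn1_end <- z_mid - sgn * 0.1
    sn2_end <- z_mid + sgn * 0.55
    for (i in seq_len(n_lip)) {
      res <- (leaf - 1L) * n_lip + i
      o <- (res - 1L) * per_lipid
      x0 <- lip_xy[i, 1]; y0 <- lip_xy[i, 2]
      base[o + 1L, ] <- c(x0, y0, p_z)
      base[o + 2L, ] <- c(x0, y0, gl_z)
      base[o + 2L + seq_len(len1), ] <-
        cbind(x0 + 0.15, y0, chain_z(gl_z, len1, sn1_end))
      base[o + 2L + len1 + seq_len(len2), ] <-
        cbind(x0 - 0.15, y0, chain_z(gl_z, len2, sn2_end))
    }
  }

  water_rows <- 2L * n_lip * per_lipid + seq_len(n_waters)
  upper_band <- c(slab_hi + 0.4, box[3] - 0.2)
  lower_band <- c(0.2, slab_lo - 0.4)
  bg_upper <- seq_len(n_bg) %% 2L == 0L
  base[water_rows, 1] <- runif(n_waters, 0, box[1])
  base[water_rows, 2] <- runif(n_waters, 0, box[2])
  bg_z0 <- ifelse(bg_upper,
                  runif(n_bg, upper_band[1] + 0.1, upper_band[2] - 0.1),
                  runif(n_bg, lower_band[1] + 0.1, lower_band[2] - 0.1))
  base[water_rows[seq_len(n_bg)], 3] <- bg_z0

  # ---- scripted water z paths ----------------------------------------
  window <- 30L
  if (n_planted > 0L && nf < window + 12L) {
    abort("planted events exceed the frame budget: increase n_frames.")
  }
  planted_rows <- water_rows[n_bg + seq_len(n_planted)]
  planted_resid <- residue_id[planted_rows]
  classes <- c(rep("crossing", cfg$n_cross), rep("rebound", cfg$n_rebound))
  wz <- matrix(0, nf, max(n_planted, 1L))
  truth_events <- NULL
  if (n_planted > 0L) {
    starts <- round(seq(5L, nf - window - 5L, length.out = n_planted))
    truth_events <- purrr::map_dfr(seq_len(n_planted), function(k) {
      from_upper <- k %% 2L == 1L
      z_out <- if (from_upper) slab_hi + 0.8 else slab_lo - 0.8
      z_opp <- if (from_upper) slab_lo - 0.8 else slab_hi + 0.8
      s <- starts[k]
      path <- rep(z_out, nf)
      if (classes[k] == "crossing") {
        path[s:(s + window)] <- seq(z_out, z_opp, length.out = window + 1L)
        path[(s + window):nf] <- z_opp
      } else {
        half <- window %/% 2L
        path[s:(s + half)] <- seq(z_out, z_mid, length.out = half + 1L)
        path[(s + half):(s + 2L * half)] <- seq(z_mid, z_out, length.out = half + 1L)
      }
      wz[, k] <<- path
      inside <- which(path > slab_lo & path < slab_hi)
      side <- if (from_upper) "upper" else "lower"
      tibble(
        water_id = planted_rows[k],
        residue_id = planted_resid[k],
        event_class = classes[k],
        entry_side = side,
        exit_side = if (classes[k] == "crossing")
          ifelse(from_upper, "lower", "upper") else side,
        t_entry = (min(inside) - 1L) * cfg$dt,
        t_exit = (max(inside) - 1L) * cfg$dt
      )
    })
  }

  # background jitter: iid uniform, bounded so the bulk bands are never left
  bg_jitter <- matrix(runif(nf * n_bg, -0.05, 0.05), nf, n_bg)

  # ---- scripted chain motion -----------------------------------------
  lip_tbl <- tibble(
    res = seq_len(2L * n_lip),
    leaf = rep(1:2, each = n_lip),
    offset = (seq_len(2L * n_lip) - 1L) * per_lipid
  )
  motions <- list(sn1 = cfg$sn1_motion, sn2 = cfg$sn2_motion)
  chain_info <- list(
    sn1 = list(first = 3L, len = len1),
    sn2 = list(first = 3L + len1, len = len2)
  )
  scripts <- list()
  truth_chain <- list()
  for (lab in c("sn1", "sn2")) {
    mo <- motions[[lab]]
    ci <- chain_info[[lab]]
    term_rows <- lip_tbl$offset + ci$first + ci$len - 1L
    if (mo$kind == "walk") {
      steps <- array(rnorm(nf * length(term_rows) * 3, 0, mo$step_sd),
                     dim = c(nf, length(term_rows), 3))
      steps[1, , ] <- 0
      disp <- apply(steps, c(2, 3), cumsum)
      scripts[[lab]] <- list(kind = "walk", term_rows = term_rows, disp = disp)
      dz <- steps[-1, , 3, drop = FALSE]
      dx <- steps[-1, , 1, drop = FALSE]
      dy <- steps[-1, , 2, drop = FALSE]
      dt_ns <- cfg$dt / 1000
      truth_chain[[lab]] <- list(
        kind = "walk", step_sd = mo$step_sd,
        expected_velocity_z = mo$step_sd * sqrt(2 / pi) / cfg$dt * 1000,
        expected_velocity_xy = mo$step_sd * sqrt(pi / 2) / cfg$dt * 1000,
        realized_velocity_z = mean(abs(dz)) / cfg$dt * 1000,
        realized_velocity_xy = mean(sqrt(dx^2 + dy^2)) / cfg$dt * 1000,
        se_velocity_z = stats::sd(abs(dz)) / sqrt(length(dz)) / cfg$dt * 1000
      )
    } else if (mo$kind == "torsion") {
      n_ch <- nrow(lip_tbl)
      bent <- matrix(runif(nf * n_ch) < mo$torsion_rate, nf, n_ch)
      scripts[[lab]] <- list(kind = "torsion", bent = bent, ci = ci, mo = mo)
      truth_chain[[lab]] <- list(
        kind = "torsion", torsion_rate = mo$torsion_rate,
        torsion_angle = mo$torsion_angle,
        realized_torsion_frequency = mean(bent)
      )
    } else if (mo$kind == "protrusion") {
      n_ch <- nrow(lip_tbl)
      half <- max(1L, mo$protrusion_period %/% 2L)
      phase <- sample.int(mo$protrusion_period, n_ch, replace = TRUE)
      prot <- vapply(seq_len(n_ch), function(j) {
        ((seq_len(nf) - 1L + phase[j]) %/% half) %% 2L == 1L
      }, logical(nf))
      scripts[[lab]] <- list(kind = "protrusion", prot = prot, ci = ci, mo = mo,
                             term_rows = term_rows)
      edges <- !prot[-nf, , drop = FALSE] & prot[-1, , drop = FALSE]
      truth_chain[[lab]] <- list(
        kind = "protrusion", period = mo$protrusion_period,
        amplitude = mo$protrusion_amplitude,
        planted_events_total = sum(edges),
        planted_events_per_chain = sum(edges) / n_ch
      )
    } else {
      truth_chain[[lab]] <- list(kind = "static")
    }
  }

  # ---- assemble frames ------------------------------------------------
  gl_rows <- lip_tbl$offset + 2L
  sgn_leaf <- ifelse(lip_tbl$leaf == 1L, 1, -1)
  frames <- vector("list", nf)
  for (f in seq_len(nf)) {
    m <- base
    if (n_bg > 0L) {
      m[water_rows[seq_len(n_bg)], 3] <- bg_z0 + bg_jitter[f, ]
    }
    if (n_planted > 0L) {
      m[planted_rows, 3] <- wz[f, seq_len(n_planted)]
    }
    for (lab in names(scripts)) {
      sc <- scripts[[lab]]
      if (sc$kind == "walk") {
        m[sc$term_rows, ] <- m[sc$term_rows, ] + sc$disp[f, , ]
      } else if (sc$kind == "torsion") {
        bent_ch <- which(sc$bent[f, ])
        for (j in bent_ch) {
          ci <- sc$ci
          rows <- lip_tbl$offset[j] + ci$first - 1L + seq_len(ci$len)
          n_fold <- ci$len %/% 2L
          b <- sqrt(sum((m[rows[2], ] - m[rows[1], ])^2))
          sgn <- sgn_leaf[j]
          theta <- sc$mo$torsion_angle * pi / 180
          w_dir <- c(sin(theta), 0, sgn * cos(theta))
          kk <- (n_fold + 1L):ci$len
          m[rows[kk], ] <- matrix(m[rows[n_fold], ], length(kk), 3,
                                  byrow = TRUE) +
            outer(kk - n_fold, w_dir) * b
        }
      } else if (sc$kind == "protrusion") {
        up <- which(sc$prot[f, ])
        if (length(up) > 0L) {
          m[sc$term_rows[up], 3] <- m[gl_rows[up], 3] +
            sgn_leaf[up] * sc$mo$protrusion_amplitude
        }
      }
    }
    frames[[f]] <- md_frame(m, box, time = (f - 1L) * cfg$dt)
  }

  topo <- apply_lipid_templates(atoms, bilayer_lipid_template(len1, len2))
  truth <- structure(list(
    kind = "bilayer",
    config = cfg[c("n_lipids_per_leaflet", "sn1_length", "sn2_length",
                   "n_frames", "dt", "thickness", "slab_fraction",
                   "n_cross", "n_rebound", "seed")],
    n_waters = n_waters,
    slab = c(lo = slab_lo, hi = slab_hi),
    permeation = truth_events,
    chains = truth_chain
  ), class = "ground_truth")

  list(topo = topo, traj = md_trajectory(frames), truth = truth)
}
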