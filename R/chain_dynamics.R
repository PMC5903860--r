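# Per-acyl-chain dynamics: terminal-CH3 velocity rates, 3-point torsion
# frequency and protrusion events past the glycerol.

block_index <- function(times_ps, block_ns) {
  if (is.null(block_ns)) return(rep(1L, length(times_ps)))
  t0 <- min(times_ps)
  pmax(1L, as.integer(floor((times_ps - t0) / (block_ns * 1000))) + 1L)
}

chain_terminal_ids <- function(topo) {
  list(sn1 = topo$lipids$sn1_terminal, sn2 = topo$lipids$sn2_terminal)
}

#' Terminal-CH3 velocity rates
#'
#' For each acyl chain, the displacement of the terminal carbon is sampled
#' every `step_ps` (default 10 ps) with minimum-image correction per axis,
#' and velocity rates are the summed distances divided by total time:
#' `velocity_z = sum(|dz|)/T` along the membrane normal and
#' `velocity_xy = sum(sqrt(dx^2 + dy^2))/T` in the membrane plane (per-axis
#' `velocity_x`/`velocity_y` from summed `|dx|`, `|dy|` are also emitted).
#' Values are averaged over chains carrying the same label and reported in
#' nm/ns per block.
#'
#' An interval whose corrected displacement reaches a quarter of the box
#' edge on any axis is untrackable and skipped (with a warning).
#'
#' @param traj An [md_trajectory()].
#' @param topo An [apply_lipid_templates()] result.
#' @param step_ps Sampling interval (ps); must be a multiple of the frame
#'   spacing and at least one frame.
#' @param block_ns Optional block length (ns) for block-wise reporting;
#'   `NULL` treats the whole trajectory as one block.
#' @return Tibble: `chain_label`, `block`, `velocity_z`, `velocity_xy`,
#'   `velocity_x`, `velocity_y` (nm/ns), `n_chains`, `n_intervals`.
#' @export
terminal_velocity <- function(traj, topo, step_ps = 10, block_ns = NULL) {
  if (is.na(traj$dt)) abort("trajectory has no frame spacing (single frame).")
  if (step_ps < traj$dt) abort("`step_ps` must not be smaller than the frame spacing.")
  stride <- step_ps / traj$dt
  if (abs(stride - round(stride)) > 1e-9) {
    abort("`step_ps` must be an integer multiple of the frame spacing.")
  }
  stride <- as.integer(round(stride))
  idx <- seq(1L, length(traj$times), by = stride)
  if (length(idx) < 2L) abort("trajectory too short for the requested step.")

  terms <- chain_terminal_ids(topo)
  purrr::map_dfr(c("sn1", "sn2"), function(lab) {
    ids <- terms[[lab]]
    d <- lapply(1:3, function(ax) {
      m <- traj_axis_matrix(traj, ids, ax)[idx, , drop = FALSE]
      dm <- diff(m)
      bx <- traj$box[idx[-1L], ax]
      dm - bx * round(sweep(dm, 1, bx, "/"))
    })
    bx_mat <- traj$box[idx[-1L], , drop = FALSE]
    bad <- (abs(d[[1]]) >= bx_mat[, 1] / 4) |
           (abs(d[[2]]) >= bx_mat[, 2] / 4) |
           (abs(d[[3]]) >= bx_mat[, 3] / 4)
    if (any(bad)) {
      warn(sprintf("%s: %d untrackable chain interval(s) skipped.", lab, sum(bad)))
    }
    ok <- !bad
    blocks <- block_index(traj$times[idx[-length(idx)]], block_ns)
    purrr::map_dfr(sort(unique(blocks)), function(b) {
      sel <- blocks == b
      n_int <- sum(ok[sel, , drop = FALSE])
      tt <- n_int * step_ps # ps of tracked motion summed over chains
      sum_ok <- function(m) sum(m[sel, , drop = FALSE][ok[sel, , drop = FALSE]])
      dxy <- sqrt(d[[1]]^2 + d[[2]]^2)
      tibble(
        chain_label = lab, block = b,
        velocity_z = if (tt > 0) sum_ok(abs(d[[3]])) / tt * 1000 else 0,
        velocity_xy = if (tt > 0) sum_ok(dxy) / tt * 1000 else 0,
        velocity_x = if (tt > 0) sum_ok(abs(d[[1]])) / tt * 1000 else 0,
        velocity_y = if (tt > 0) sum_ok(abs(d[[2]])) / tt * 1000 else 0,
        n_chains = length(ids), n_intervals = n_int
      )
    })
  })
}

# Build triplet index tables (vertex n with endpoints n-2, n+2) for all
# chains of one label; chains shorter than 5 carbons are excluded.
torsion_triplets <- function(topo, label) {
  ids_col <- if (label == "sn1") topo$lipids$sn1_ids else topo$lipids$sn2_ids
  short <- vapply(ids_col, length, integer(1)) < 5L
  if (any(short)) {
    warn(sprintf("%s: %d chain(s) shorter than 5 carbons excluded from torsions.",
                 label, sum(short)))
  }
  keep <- which(!short)
  a <- v <- b <- integer(0)
  chain <- integer(0)
  for (k in seq_along(keep)) {
    ids <- ids_col[[keep[k]]]
    L <- length(ids)
    n <- 3:(L - 2L)
    a <- c(a, ids[n - 2L]); v <- c(v, ids[n]); b <- c(b, ids[n + 2L])
    chain <- c(chain, rep(k, length(n)))
  }
  list(a = a, v = v, b = b, chain = chain, n_chains = length(keep))
}

#' Acyl-chain torsion frequency
#'
#' A torsion is a frame in which the angle at carbon n, subtended by carbons
#' n-2 and n+2 of the same chain, falls strictly below `angle_threshold`
#' (default 100 degrees). All interior carbons (3 <= n <= L-2) are scored in
#' every frame; the frequency is the count of sub-threshold angles per chain
#' per frame, averaged over chains of the same label, reported per block.
#'
#' @inheritParams terminal_velocity
#' @param angle_threshold Angle threshold in degrees (strict `<`).
#' @return Tibble: `chain_label`, `block`, `torsion_frequency`, `n_chains`,
#'   `n_frames`.
#' @export
torsion_frequency <- function(traj, topo, angle_threshold = 100,
                              block_ns = NULL) {
  nf <- length(traj$times)
  blocks <- block_index(traj$times, block_ns)
  purrr::map_dfr(c("sn1", "sn2"), function(lab) {
    tp <- torsion_triplets(topo, lab)
    if (tp$n_chains == 0L) return(tibble())
    counts <- numeric(nf) # sub-threshold angles summed over chains, per frame
    for (i in seq_len(nf)) {
      m <- traj$coords[[i]]
      ang <- vertex_angle_deg(m[tp$a, , drop = FALSE],
                              m[tp$v, , drop = FALSE],
                              m[tp$b, , drop = FALSE])
      counts[i] <- sum(ang < angle_threshold)
    }
    purrr::map_dfr(sort(unique(blocks)), function(bk) {
      sel <- blocks == bk
      tibble(chain_label = lab, block = bk,
             torsion_frequency = mean(counts[sel]) / tp$n_chains,
             n_chains = tp$n_chains, n_frames = sum(sel))
    })
  })
}

#' Count chain protrusion events past the glycerol
#'
#' A chain is protruded in a frame when its terminal carbon lies outward of
#' its own lipid's central glycerol carbon along the leaflet's outward
#' normal: `z_CH3 > z_gly` for the upper leaflet, `z_CH3 < z_gly` for the
#' lower. An event is the transition from non-protruded to protruded between
#' consecutive frames; counts are summed per block and reported per chain.
#' An optional hysteresis band (entry above `+hysteresis`, exit below
#' `-hysteresis` along the outward normal) suppresses noise-driven
#' double-counting; the default band is 0.
#'
#' @inheritParams terminal_velocity
#' @param refs Optional precomputed [membrane_reference_traj()] table
#'   (supplies the leaflet assignment).
#' @param hysteresis Hysteresis half-band in nm (default 0).
#' @return Tibble: `chain_label`, `block`, `n_events`, `events_per_chain`,
#'   `n_chains`.
#' @export
protrusion_count <- function(traj, topo, refs = NULL, block_ns = NULL,
                             hysteresis = 0) {
  if (is.null(refs)) refs <- membrane_reference_traj(traj, topo)
  leaf <- attr(refs, "leaflets")
  outward <- ifelse(leaf$leaflet[match(topo$lipids$residue_id, leaf$residue_id)]
                    == "upper", 1, -1)
  z_gly <- traj_axis_matrix(traj, topo$lipids$glycerol_id)
  blocks <- block_index(traj$times, block_ns)
  terms <- chain_terminal_ids(topo)
  purrr::map_dfr(c("sn1", "sn2"), function(lab) {
    z_ch3 <- traj_axis_matrix(traj, terms[[lab]])
    signal <- sweep(z_ch3 - z_gly, 2, outward, "*")
    if (hysteresis == 0) {
      prot <- signal > 0
    } else {
      prot <- matrix(FALSE, nrow(signal), ncol(signal))
      for (j in seq_len(ncol(signal))) {
        state <- signal[1L, j] > hysteresis
        prot[1L, j] <- state
        for (i in 2:nrow(signal)) {
          if (!state && signal[i, j] > hysteresis) state <- TRUE
          else if (state && signal[i, j] < -hysteresis) state <- FALSE
          prot[i, j] <- state
        }
      }
    }
    # rising edges; the event is stamped with the frame where the chain
    # becomes protruded
    edges <- !prot[-nrow(prot), , drop = FALSE] & prot[-1L, , drop = FALSE]
    edge_blocks <- blocks[-1L]
    purrr::map_dfr(sort(unique(blocks)), function(bk) {
      n_ev <- sum(edges[edge_blocks == bk, , drop = FALSE])
      tibble(chain_label = lab, block = bk, n_events = n_ev,
             events_per_chain = n_ev / ncol(z_ch3), n_chains = ncol(z_ch3))
    })
  })
}

#' Mean and SD of block-wise chain metrics
#'
#' Collapses a per-block metric table (as returned by [terminal_velocity()],
#' [torsion_frequency()] or [protrusion_count()]) to a mean and standard
#' deviation over blocks for every numeric metric column.
#'
#' @param x A per-block tibble with a `chain_label` and `block` column.
#' @return A tibble with one row per chain label and `<metric>_mean` /
#'   `<metric>_sd` columns.
#' @export
summarise_blocks <- function(x) {
  metric_cols <- setdiff(names(x)[vapply(x, is.numeric, logical(1))],
                         c("block", "n_chains", "n_frames", "n_intervals",
                           "n_events"))
  dplyr::summarise(
    dplyr::group_by(x, .data$chain_label),
    dplyr::across(dplyr::all_of(metric_cols),
                  list(mean = mean, sd = sd_or_zero)),
    n_blocks = dplyr::n(), .groups = "drop")
}
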