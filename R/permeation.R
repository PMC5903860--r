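# Water permeation: visits of water oxygens to the hydrophobic slab,
# classified as full crossings versus same-side rebounds, and normalised to
# the total water count per time block.

#' Unwrap z coordinates across the periodic boundary
#'
#' Removes periodic jumps from per-atom z paths by minimum-image correction
#' of successive displacements, yielding continuous paths suitable for side
#' bookkeeping. An atom whose corrected per-frame step still reaches a
#' quarter of the box height is physically untrackable at this frame spacing
#' (the true displacement cannot be distinguished from its periodic images)
#' and is flagged with a warning.
#'
#' @param traj An [md_trajectory()].
#' @param atom_ids Integer atom ids (row positions) to track.
#' @return A list with `z` (n_frames x n_atoms matrix of unwrapped z, nm) and
#'   `untrackable` (logical per atom).
#' @export
unwrap_z <- function(traj, atom_ids) {
  z <- traj_axis_matrix(traj, atom_ids)
  nf <- nrow(z)
  untrackable <- rep(FALSE, length(atom_ids))
  if (nf > 1L) {
    dz <- diff(z)
    box_z <- traj$box[-1L, 3]
    dz_corr <- dz - box_z * round(sweep(dz, 1, box_z, "/"))
    untrackable <- apply(abs(dz_corr) >= box_z / 4, 2, any)
    if (any(untrackable)) {
      warn(sprintf("%d atom(s) flagged untrackable (per-frame z step >= box_z/4).",
                   sum(untrackable)))
    }
    cz <- apply(dz_corr, 2, cumsum)
    if (is.null(dim(cz))) cz <- matrix(cz, nrow = 1L)
    # row i (i > 1): z at frame 1 plus the cumulative corrected steps
    z <- rbind(z[1L, , drop = FALSE], sweep(cz, 2, z[1L, ], "+"))
  }
  list(z = z, untrackable = untrackable)
}

#' Detect water visits to the hydrophobic slab
#'
#' A visit is a maximal contiguous run of frames in which a water oxygen lies
#' strictly inside the per-frame hydrophobic slab (`slab_lo < z < slab_hi`);
#' one frame inside suffices, with no minimum dwell time. `entry_side` is the
#' side occupied on the frame before entry, `exit_side` the side on the frame
#' after exit. Events are classified as:
#' * `crossing` — exit side differs from entry side,
#' * `rebound` — exit on the entry side,
#' * `unresolved` — the trajectory ends while the water is inside the slab.
#'
#' A water already inside the slab at the first frame cannot have a known
#' entry side: if it later exits, the event is scored as a rebound on its
#' exit side (the rebound-consistent inference); if it never exits it is
#' unresolved.
#'
#' @param traj An [md_trajectory()].
#' @param topo An [apply_lipid_templates()] result.
#' @param refs Optional precomputed [membrane_reference_traj()] table.
#' @param slab_fraction Slab width fraction used when `refs` is NULL.
#' @return A tibble of class `permeation_records`: `water_id`, `t_entry`,
#'   `t_exit` (ps), `entry_side`, `exit_side` (`"upper"`/`"lower"`/`"none"`),
#'   `event_class`.
#' @export
detect_permeation_events <- function(traj, topo, refs = NULL,
                                     slab_fraction = 0.65) {
  if (is.null(refs)) refs <- membrane_reference_traj(traj, topo, slab_fraction)
  waters <- topo$water_oxygens
  nf <- length(traj$times)
  # status: 0 inside slab, +1 upper side, -1 lower side (frame-wise z is
  # compared against the same frame's slab bounds, so a rigid z translation
  # applied jointly to coordinates and refs leaves the bookkeeping unchanged)
  z <- traj_axis_matrix(traj, waters)
  inside <- sweep(z, 1, refs$slab_lo, ">") & sweep(z, 1, refs$slab_hi, "<")
  upper <- sweep(z, 1, refs$slab_hi, ">=")

  recs <- vector("list", length(waters))
  for (j in seq_along(waters)) {
    ins <- inside[, j]
    if (!any(ins)) next
    r <- rle(ins)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    out <- vector("list", length(runs))
    for (k in seq_along(runs)) {
      i0 <- starts[runs[k]]
      i1 <- ends[runs[k]]
      entry_side <- if (i0 > 1L) ifelse(upper[i0 - 1L, j], "upper", "lower") else NA_character_
      exit_side <- if (i1 < nf) ifelse(upper[i1 + 1L, j], "upper", "lower") else "none"
      if (is.na(entry_side)) {
        # started inside the slab: rebound-consistent inference from the exit
        if (exit_side == "none") {
          event_class <- "unresolved"
          entry_side <- "upper" # placeholder; side unknown
          exit_side <- "none"
        } else {
          entry_side <- exit_side
          event_class <- "rebound"
        }
      } else if (exit_side == "none") {
        event_class <- "unresolved"
      } else if (exit_side == entry_side) {
        event_class <- "rebound"
      } else {
        event_class <- "crossing"
      }
      out[[k]] <- tibble(
        water_id = waters[j],
        t_entry = traj$times[i0],
        t_exit = traj$times[i1],
        entry_side = entry_side,
        exit_side = exit_side,
        event_class = event_class
      )
    }
    recs[[j]] <- dplyr::bind_rows(out)
  }
  out <- dplyr::bind_rows(recs)
  if (nrow(out) == 0L) {
    out <- tibble(water_id = integer(), t_entry = numeric(), t_exit = numeric(),
                  entry_side = character(), exit_side = character(),
                  event_class = character())
  }
  class(out) <- c("permeation_records", class(out))
  out
}

#' Summarise permeation events per time block
#'
#' Events are assigned to consecutive blocks of `block_ns` by their entry
#' time. Per block the crossing/rebound/unresolved event tallies are
#' reported together with `percent_visiting`, the percentage of all water
#' molecules with at least one slab visit in the block (distinct-molecule
#' counting: a water visiting twice in one block counts once).
#'
#' @param records A [detect_permeation_events()] table.
#' @param n_waters Total number of water molecules (normalisation base).
#' @param duration_ns Analysed trajectory duration in ns.
#' @param block_ns Block length in ns (default 100).
#' @param discard_ns Initial equilibration span to drop (ns, default 0).
#' @return A tibble of class `permeation_summary` with one row per block:
#'   `block`, `t_start_ns`, `t_end_ns`, `n_crossings`, `n_rebounds`,
#'   `n_unresolved`, `n_visiting`, `percent_visiting`. Use [glance()] for
#'   mean and SD over blocks.
#' @export
permeation_summary <- function(records, n_waters, duration_ns,
                               block_ns = 100, discard_ns = 0) {
  if (n_waters <= 0) abort("`n_waters` must be positive.")
  if (duration_ns - discard_ns < block_ns) {
    abort("zero blocks: duration (after discard) is shorter than one block.")
  }
  n_blocks <- floor((duration_ns - discard_ns) / block_ns)
  rec <- dplyr::filter(records, .data$t_entry / 1000 >= discard_ns,
                       .data$t_entry / 1000 < discard_ns + n_blocks * block_ns)
  block_of <- floor((rec$t_entry / 1000 - discard_ns) / block_ns) + 1L
  out <- purrr::map_dfr(seq_len(n_blocks), function(b) {
    rb <- rec[block_of == b, ]
    tibble(
      block = b,
      t_start_ns = discard_ns + (b - 1) * block_ns,
      t_end_ns = discard_ns + b * block_ns,
      n_crossings = sum(rb$event_class == "crossing"),
      n_rebounds = sum(rb$event_class == "rebound"),
      n_unresolved = sum(rb$event_class == "unresolved"),
      n_visiting = dplyr::n_distinct(rb$water_id),
      percent_visiting = 100 * dplyr::n_distinct(rb$water_id) / n_waters
    )
  })
  class(out) <- c("permeation_summary", class(out))
  attr(out, "n_waters") <- n_waters
  attr(out, "block_ns") <- block_ns
  out
}

#' One-call permeation analysis of a trajectory
#'
#' Convenience wrapper: computes per-frame slab geometry, detects slab
#' visits and summarises them per block. Defaults mirror the standard
#' analysis protocol for long production runs (100 ns blocks after a 100 ns
#' equilibration discard); short synthetic trajectories should pass explicit
#' `block_ns`/`discard_ns`.
#'
#' @inheritParams detect_permeation_events
#' @inheritParams permeation_summary
#' @return A list with `records`, `summary` and `refs`.
#' @export
permeation_analysis <- function(traj, topo, slab_fraction = 0.65,
                                block_ns = 100, discard_ns = 100) {
  refs <- membrane_reference_traj(traj, topo, slab_fraction)
  records <- detect_permeation_events(traj, topo, refs = refs)
  summary <- permeation_summary(records,
                                n_waters = length(topo$water_oxygens),
                                duration_ns = traj_duration(traj, "ns"),
                                block_ns = block_ns, discard_ns = discard_ns)
  list(records = records, summary = summary, refs = refs)
}

#' @method glance permeation_summary
#' @export
glance.permeation_summary <- function(x, ...) {
  tibble(
    n_blocks = nrow(x),
    mean_percent_visiting = mean(x$percent_visiting),
    sd_percent_visiting = sd_or_zero(x$percent_visiting),
    mean_crossings = mean(x$n_crossings),
    sd_crossings = sd_or_zero(x$n_crossings),
    mean_rebounds = mean(x$n_rebounds),
    sd_rebounds = sd_or_zero(x$n_rebounds)
  )
}

sd_or_zero <- function(x) if (length(x) < 2L) 0 else stats::sd(x)
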