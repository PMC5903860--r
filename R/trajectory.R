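#' Construct a single structure frame
#'
#' A frame holds one set of coordinates together with its orthorhombic box and
#' (optionally) a time stamp. Coordinates are in nm, time in ps.
#'
#' @param coords Numeric matrix, one row per atom, columns x/y/z (nm).
#' @param box Numeric length-3 vector of box edge lengths (nm), all > 0.
#' @param time Time stamp in ps, or `NA` when unknown.
#' @return An object of class `md_frame`.
#' @export
md_frame <- function(coords, box, time = NA_real_) {
  coords <- as.matrix(coords)
  dimnames(coords) <- NULL
  if (ncol(coords) != 3L) abort("`coords` must have three columns (x, y, z).")
  box <- as.numeric(box)
  if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0)) {
    abort("`box` must be three positive finite edge lengths (nm).")
  }
  structure(list(time = as.numeric(time), box = box, coords = coords),
            class = "md_frame")
}

#' @export
print.md_frame <- function(x, ...) {
  cat(sprintf("<md_frame> %d atoms, box %.3f x %.3f x %.3f nm, t = %s ps\n",
              nrow(x$coords), x$box[1], x$box[2], x$box[3],
              ifelse(is.na(x$time), "?", format(x$time))))
  invisible(x)
}

#' Construct a trajectory from frames
#'
#' Frames must share an atom count and carry strictly increasing, uniformly
#' spaced times (relative tolerance 1e-6). When frames carry no times, supply
#' `dt` and times are assigned as `0, dt, 2*dt, ...`. A single frame is a
#' valid degenerate trajectory with undefined `dt`.
#'
#' @param frames List of [md_frame()] objects.
#' @param dt Frame spacing in ps, used when frames carry no time stamps.
#' @return An object of class `md_trajectory` with fields `times` (ps),
#'   `box` (n_frames x 3 matrix, nm), `coords` (list of coordinate matrices),
#'   `n_atoms` and `dt`.
#' @export
md_trajectory <- function(frames, dt = NULL) {
  if (length(frames) == 0L) abort("`frames` is empty.")
  n_atoms <- vapply(frames, function(f) nrow(f$coords), integer(1))
  if (length(unique(n_atoms)) != 1L) {
    abort(sprintf("atom-count mismatch between frames: %s",
                  paste(unique(n_atoms), collapse = ", ")))
  }
  times <- vapply(frames, function(f) f$time, numeric(1))
  if (anyNA(times)) {
    if (is.null(dt)) {
      if (length(frames) > 1L) {
        abort("frames carry no times; supply `dt` (ps).")
      }
      times <- 0
    } else {
      times <- (seq_along(frames) - 1) * dt
    }
  }
  if (is.unsorted(times, strictly = TRUE)) {
    abort("frame times must be strictly increasing.")
  }
  dt_out <- NA_real_
  if (length(times) > 1L) {
    steps <- diff(times)
    dt_out <- steps[1]
    if (any(abs(steps - dt_out) > 1e-6 * max(abs(dt_out), 1))) {
      abort("frame times are not uniformly spaced.")
    }
  }
  structure(list(
    times = times,
    box = do.call(rbind, lapply(frames, function(f) f$box)),
    coords = lapply(frames, function(f) f$coords),
    n_atoms = n_atoms[1],
    dt = dt_out
  ), class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("<md_trajectory> %d frames x %d atoms, dt = %s ps, %.1f-%.1f ps\n",
              length(x$times), x$n_atoms,
              ifelse(is.na(x$dt), "?", format(x$dt)),
              min(x$times), max(x$times)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj An `md_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) length(traj$times)

#' Extract one frame from a trajectory
#' @param traj An `md_trajectory`.
#' @param i Frame index (1-based).
#' @return An `md_frame`.
#' @export
traj_frame <- function(traj, i) {
  md_frame(traj$coords[[i]], traj$box[i, ], traj$times[i])
}

#' Trajectory duration
#' @param traj An `md_trajectory`.
#' @param unit `"ps"` or `"ns"`.
#' @return Elapsed time between the first and last frame.
#' @export
traj_duration <- function(traj, unit = c("ps", "ns")) {
  unit <- match.arg(unit)
  d <- max(traj$times) - min(traj$times)
  if (unit == "ns") d / 1000 else d
}
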