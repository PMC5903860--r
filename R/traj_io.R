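# Structure and trajectory readers/writers.
#
# Internal units are nm and ps everywhere; the readers own all conversions
# (PDB angstroms are divided by 10 on the way in).

guess_element <- function(atom_name) {
  stripped <- gsub("[0-9'\"]", "", atom_name)
  first <- toupper(substr(stripped, 1, 1))
  ifelse(first %in% c("C", "N", "O", "P", "S", "H"), first, stripped)
}

new_atoms_tibble <- function(atom_name, residue_name, residue_id) {
  tibble(
    atom_id = seq_along(atom_name),
    atom_name = trimws(atom_name),
    residue_name = trimws(residue_name),
    residue_id = as.integer(residue_id),
    element = guess_element(trimws(atom_name))
  )
}

parse_gro_block <- function(lines, offset_line = 0L) {
  if (length(lines) < 3L) abort("GRO block too short (need title, count, box).")
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n)) abort(sprintf("GRO parse error at line %d: bad atom count.",
                              offset_line + 2L))
  if (length(lines) < n + 3L) {
    abort(sprintf("GRO block truncated: expected %d atom lines.", n))
  }
  atom_lines <- lines[3:(n + 2L)]
  bad_len <- which(nchar(atom_lines) < 44L)
  if (length(bad_len) > 0L) {
    abort(sprintf("GRO parse error at line %d: truncated coordinate field.",
                  offset_line + 2L + bad_len[1]))
  }
  resid <- suppressWarnings(as.integer(substr(atom_lines, 1, 5)))
  resname <- substr(atom_lines, 6, 10)
  atname <- substr(atom_lines, 11, 15)
  x <- suppressWarnings(as.numeric(substr(atom_lines, 21, 28)))
  y <- suppressWarnings(as.numeric(substr(atom_lines, 29, 36)))
  z <- suppressWarnings(as.numeric(substr(atom_lines, 37, 44)))
  bad <- which(is.na(resid) | is.na(x) | is.na(y) | is.na(z))
  if (length(bad) > 0L) {
    abort(sprintf("GRO parse error at line %d: malformed fixed-width record.",
                  offset_line + 2L + bad[1]))
  }
  box_line <- trimws(lines[n + 3L])
  if (box_line == "") abort("GRO file is missing its box line.")
  box_vals <- suppressWarnings(as.numeric(strsplit(box_line, "\\s+")[[1]]))
  if (length(box_vals) < 3L || anyNA(box_vals[1:3])) {
    abort(sprintf("GRO parse error at line %d: missing or malformed box.",
                  offset_line + n + 3L))
  }
  time <- NA_real_
  tm <- regmatches(lines[1], regexpr("t\\s*=\\s*[-0-9.eE+]+", lines[1]))
  if (length(tm) == 1L) time <- as.numeric(sub("t\\s*=\\s*", "", tm))
  list(
    atoms = new_atoms_tibble(atname, resname, resid),
    frame = md_frame(cbind(x, y, z), box_vals[1:3], time),
    n_lines = n + 3L
  )
}

parse_pdb_model <- function(lines, box) {
  rec <- substr(lines, 1, 6)
  keep <- lines[rec %in% c("ATOM  ", "HETATM")]
  if (length(keep) == 0L) abort("PDB model contains no ATOM/HETATM records.")
  atname <- substr(keep, 13, 16)
  resname <- substr(keep, 18, 21)
  resid <- suppressWarnings(as.integer(substr(keep, 23, 26)))
  x <- suppressWarnings(as.numeric(substr(keep, 31, 38)))
  y <- suppressWarnings(as.numeric(substr(keep, 39, 46)))
  z <- suppressWarnings(as.numeric(substr(keep, 47, 54)))
  bad <- which(is.na(resid) | is.na(x) | is.na(y) | is.na(z))
  if (length(bad) > 0L) {
    abort(sprintf("PDB parse error in record %d: malformed ATOM line.", bad[1]))
  }
  list(
    atoms = new_atoms_tibble(atname, resname, resid),
    frame = md_frame(cbind(x, y, z) / 10, box) # angstrom -> nm
  )
}

pdb_box <- function(lines) {
  cr <- lines[startsWith(lines, "CRYST1")]
  if (length(cr) == 0L) {
    abort("PDB file has no CRYST1 record: missing box.")
  }
  vals <- suppressWarnings(as.numeric(c(substr(cr[1], 7, 15),
                                        substr(cr[1], 16, 24),
                                        substr(cr[1], 25, 33))))
  if (anyNA(vals)) abort("PDB CRYST1 record is malformed.")
  vals / 10 # angstrom -> nm
}

#' Read a molecular structure file
#'
#' Parses a GRO or PDB file into an atom table plus one coordinate frame.
#' Coordinates are returned in nm (PDB values are divided by 10); atom order
#' is preserved and `atom_id` is the row position. The box is taken from the
#' GRO box line or the PDB CRYST1 record; a missing box is an error.
#'
#' @param path Path to the file.
#' @param format `"gro"` or `"pdb"`; defaults to the file extension.
#' @return A list with `atoms` (tibble: atom_id, atom_name, residue_name,
#'   residue_id, element) and `frame` (an [md_frame()]).
#' @export
read_structure <- function(path, format = c("gro", "pdb")) {
  if (missing(format)) {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("gro", "pdb")) abort("cannot infer format; pass `format`.")
  }
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  if (format == "gro") {
    blk <- parse_gro_block(lines)
    list(atoms = blk$atoms, frame = blk$frame)
  } else {
    m <- parse_pdb_model(lines, pdb_box(lines))
    list(atoms = m$atoms, frame = m$frame)
  }
}

#' Read a trajectory
#'
#' Reads a sequence of frames from one or more files. Supported formats:
#' `"multi-gro"` (concatenated GRO blocks, times taken from `t=` in the title
#' line when present), `"multi-model-pdb"` (MODEL/ENDMDL records sharing one
#' CRYST1 box) and `"frame-text"` (the plain-text frame-sequence format
#' written by [write_frame_text()], which carries times and boxes).
#' When frames carry no times, `dt` must be supplied.
#'
#' @param paths Character vector of file paths, read in order.
#' @param format One of `"multi-gro"`, `"multi-model-pdb"`, `"frame-text"`.
#' @param dt Frame spacing in ps for formats without time stamps.
#' @param atoms Optional atom table for `"frame-text"` input (the format
#'   stores only ids and coordinates).
#' @return A list with `atoms` (tibble, `NULL` for frame-text input without
#'   `atoms`) and `traj` (an [md_trajectory()]).
#' @export
read_trajectory <- function(paths,
                            format = c("multi-gro", "multi-model-pdb", "frame-text"),
                            dt = NULL, atoms = NULL) {
  format <- match.arg(format)
  frames <- list()
  atoms_out <- atoms
  for (path in paths) {
    lines <- readLines(path, warn = FALSE)
    if (format == "multi-gro") {
      pos <- 1L
      while (pos + 2L <= length(lines) && any(nzchar(trimws(lines[pos:length(lines)])))) {
        blk <- parse_gro_block(lines[pos:length(lines)], offset_line = pos - 1L)
        if (is.null(atoms_out)) atoms_out <- blk$atoms
        frames[[length(frames) + 1L]] <- blk$frame
        pos <- pos + blk$n_lines
        while (pos <= length(lines) && !nzchar(trimws(lines[pos]))) pos <- pos + 1L
      }
    } else if (format == "multi-model-pdb") {
      box <- pdb_box(lines)
      model_starts <- which(startsWith(lines, "MODEL"))
      model_ends <- which(startsWith(lines, "ENDMDL"))
      if (length(model_starts) == 0L) {
        m <- parse_pdb_model(lines, box)
        if (is.null(atoms_out)) atoms_out <- m$atoms
        frames[[length(frames) + 1L]] <- m$frame
      } else {
        if (length(model_ends) != length(model_starts)) {
          abort("unbalanced MODEL/ENDMDL records.")
        }
        for (k in seq_along(model_starts)) {
          m <- parse_pdb_model(lines[model_starts[k]:model_ends[k]], box)
          if (is.null(atoms_out)) atoms_out <- m$atoms
          frames[[length(frames) + 1L]] <- m$frame
        }
      }
    } else {
      frames <- c(frames, parse_frame_text(lines))
    }
  }
  n_at <- vapply(frames, function(f) nrow(f$coords), integer(1))
  if (length(unique(n_at)) != 1L) {
    abort(sprintf("atom-count mismatch between frames: %s",
                  paste(unique(n_at), collapse = ", ")))
  }
  traj <- md_trajectory(frames, dt = dt)
  if (length(frames) == 1L && is.na(traj$dt)) {
    warn("single-frame trajectory: dt is undefined.")
  }
  list(atoms = atoms_out, traj = traj)
}

parse_frame_text <- function(lines) {
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  t_idx <- which(startsWith(trimws(lines), "t "))
  if (length(t_idx) == 0L) abort("frame-text input has no `t <time>` headers.")
  frames <- vector("list", length(t_idx))
  bounds <- c(t_idx, length(lines) + 1L)
  for (k in seq_along(t_idx)) {
    chunk <- lines[t_idx[k]:(bounds[k + 1L] - 1L)]
    time <- as.numeric(strsplit(trimws(chunk[1]), "\\s+")[[1]][2])
    box_parts <- strsplit(trimws(chunk[2]), "\\s+")[[1]]
    if (box_parts[1] != "box" || length(box_parts) < 4L) {
      abort("frame-text frame is missing its `box x y z` line.")
    }
    box <- as.numeric(box_parts[2:4])
    body <- do.call(rbind, lapply(strsplit(trimws(chunk[-(1:2)]), "\\s+"),
                                  as.numeric))
    if (is.null(body) || ncol(body) != 4L || anyNA(body)) {
      abort("frame-text atom lines must be `id x y z`.")
    }
    coords <- body[order(body[, 1]), 2:4, drop = FALSE]
    frames[[k]] <- md_frame(coords, box, time)
  }
  frames
}

#' Write a trajectory in the frame-text format
#'
#' The frame-text format is a diffable plain-text frame sequence: per frame a
#' `t <time_ps>` line, a `box <x> <y> <z>` line (nm) and one `id x y z` line
#' per atom (nm), ids being atom row positions.
#'
#' @param traj An [md_trajectory()] (or a single [md_frame()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_frame_text <- function(traj, path) {
  if (inherits(traj, "md_frame")) traj <- md_trajectory(list(traj))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# memflex frame-text v1", con)
  for (i in seq_along(traj$times)) {
    writeLines(sprintf("t %.6f", traj$times[i]), con)
    writeLines(sprintf("box %.6f %.6f %.6f",
                       traj$box[i, 1], traj$box[i, 2], traj$box[i, 3]), con)
    m <- traj$coords[[i]]
    writeLines(sprintf("%d %.6f %.6f %.6f", seq_len(nrow(m)),
                       m[, 1], m[, 2], m[, 3]), con)
  }
  invisible(path)
}

#' Write a structure as a GRO file
#'
#' @param atoms Atom tibble as returned by [read_structure()].
#' @param frame An [md_frame()] with matching atom count.
#' @param path Output file path.
#' @param title Title line content.
#' @return `path`, invisibly.
#' @export
write_gro <- function(atoms, frame, path, title = "memflex structure") {
  if (nrow(atoms) != nrow(frame$coords)) {
    abort("`atoms` and `frame` disagree on atom count.")
  }
  if (!is.na(frame$time)) title <- sprintf("%s t= %.3f", title, frame$time)
  lines <- c(
    title,
    sprintf("%5d", nrow(atoms)),
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
            atoms$residue_id %% 100000L,
            substr(atoms$residue_name, 1, 5),
            substr(atoms$atom_name, 1, 5),
            atoms$atom_id %% 100000L,
            frame$coords[, 1], frame$coords[, 2], frame$coords[, 3]),
    sprintf("%10.5f%10.5f%10.5f", frame$box[1], frame$box[2], frame$box[3])
  )
  writeLines(lines, path)
  invisible(path)
}
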