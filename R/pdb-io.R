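#' Read a structure from PDB-format content
#'
#' Parses ATOM/HETATM records of the first MODEL (or the whole file when no
#' MODEL records are present). Alternate locations are resolved by keeping
#' the highest-occupancy conformer, ties broken by altloc letter order.
#'
#' @param source A file path, a single string containing PDB text, or a
#'   character vector of lines.
#' @param keep_altloc If `TRUE`, skip altloc resolution and keep all records.
#' @param water_names Residue names recognised as water.
#' @return An [md_structure()].
#' @export
read_pdb <- function(source, keep_altloc = FALSE,
                     water_names = water_residue_names()) {
  lines <- pdb_lines(source)
  title <- sub("^TITLE\\s+\\d*\\s*", "", grep("^TITLE", lines, value = TRUE)[1])
  if (is.na(title)) title <- ""
  # restrict to first model when MODEL records are present
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) > 0) {
    endmdl <- grep("^ENDMDL", lines)
    stop_at <- if (length(endmdl) > 0) endmdl[1] else length(lines)
    lines_idx <- seq(model_starts[1], stop_at)
  } else {
    lines_idx <- seq_along(lines)
  }
  at <- parse_atom_records(lines, lines_idx)
  if (nrow(at) == 0) abort("no ATOM/HETATM records found (empty structure)")
  if (!keep_altloc) at <- resolve_altloc(at)
  md_structure(at, title = title, water_names = water_names)
}

pdb_lines <- function(source) {
  if (length(source) == 1 && !grepl("\n", source) && file.exists(source)) {
    readLines(source, warn = FALSE)
  } else if (length(source) == 1 && grepl("\n", source)) {
    strsplit(source, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(source)
  }
}

# Fixed-column ATOM/HETATM parsing with line-number error reporting.
parse_atom_records <- function(lines, idx = seq_along(lines)) {
  sel <- idx[grepl("^(ATOM  |HETATM)", lines[idx])]
  if (length(sel) == 0) {
    return(tibble(serial = integer(), name = character(), altloc = character(),
                  resid = character(), chain = character(), resno = integer(),
                  x = double(), y = double(), z = double(),
                  occupancy = double(), element = character()))
  }
  ln <- lines[sel]
  num_field <- function(txt, what) {
    v <- suppressWarnings(as.numeric(txt))
    bad <- is.na(v) & nzchar(trimws(txt))
    bad <- bad | !nzchar(trimws(txt))
    if (any(bad)) {
      abort(sprintf("malformed %s field at line %d: '%s'",
                    what, sel[which(bad)[1]], trimws(txt[which(bad)[1]])))
    }
    v
  }
  x <- num_field(substr(ln, 31, 38), "x coordinate")
  y <- num_field(substr(ln, 39, 46), "y coordinate")
  z <- num_field(substr(ln, 47, 54), "z coordinate")
  occ <- suppressWarnings(as.numeric(substr(ln, 55, 60)))
  occ[is.na(occ)] <- 1
  serial <- suppressWarnings(as.integer(substr(ln, 7, 11)))
  serial[is.na(serial)] <- seq_along(serial)[is.na(serial)]
  element <- trimws(substr(ln, 77, 78))
  name <- trimws(substr(ln, 13, 16))
  element[!nzchar(element)] <- guess_element(name[!nzchar(element)])
  tibble(
    serial = serial,
    name = name,
    altloc = trimws(substr(ln, 17, 17)),
    resid = trimws(substr(ln, 18, 21)),
    chain = trimws(substr(ln, 22, 22)),
    resno = suppressWarnings(as.integer(substr(ln, 23, 26))),
    x = x, y = y, z = z,
    occupancy = occ,
    element = element
  )
}

# Keep the highest-occupancy altloc per (chain, resno, resid, name);
# ties broken by altloc letter order. Deterministic and order-preserving.
resolve_altloc <- function(at) {
  if (all(!nzchar(at$altloc))) return(at)
  key <- paste(at$chain, at$resno, at$resid, at$name, sep = "\r")
  ord <- order(key, -at$occupancy, at$altloc)
  keep_first <- !duplicated(key[ord])
  keep_rows <- sort(ord[keep_first])
  at <- at[keep_rows, ]
  at$altloc <- ""
  at
}

#' Write a structure as PDB text
#'
#' @param structure An [md_structure()].
#' @param path Output file path, or `NULL` to return the lines invisibly.
#' @return Invisibly, the character vector of PDB lines.
#' @export
write_pdb <- function(structure, path = NULL) {
  lines <- c(pdb_atom_lines(structure), "END")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

pdb_atom_lines <- function(s) {
  name4 <- ifelse(nchar(s$name) >= 4, substr(s$name, 1, 4),
                  paste0(" ", formatC(s$name, width = -3)))
  rec <- ifelse(s$is_water, "HETATM", "ATOM  ")
  sprintf(
    "%s%5d %4s%1s%-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    rec, s$serial %% 100000, name4,
    ifelse(nzchar(s$altloc), s$altloc, " "),
    substr(s$resid, 1, 4), substr(s$chain, 1, 1), s$resno %% 10000,
    s$x, s$y, s$z, s$occupancy, 0, toupper(substr(s$element, 1, 2))
  )
}

#' Read a trajectory
#'
#' Accepts either a multi-model PDB (every MODEL is one frame) or the
#' package's binary frame stream (see [write_frame_stream()]). Every frame
#' must carry exactly the topology's atom count; a mismatch aborts naming
#' the offending frame.
#'
#' @param source File path (PDB or frame stream) or PDB text.
#' @param topology Optional [md_structure()]; when `NULL` and `source` is a
#'   multi-model PDB, the first model is used as topology.
#' @param dt Frame spacing in ps (for PDB sources; the frame stream stores
#'   its own).
#' @return An [md_trajectory()].
#' @export
read_trajectory <- function(source, topology = NULL, dt = 1) {
  if (length(source) == 1 && file.exists(source) && is_frame_stream(source)) {
    return(read_frame_stream(source, topology))
  }
  lines <- pdb_lines(source)
  starts <- grep("^MODEL", lines)
  ends <- grep("^ENDMDL", lines)
  if (length(starts) == 0) {
    starts <- 1
    ends <- length(lines)
  }
  if (length(ends) < length(starts)) ends <- c(ends, length(lines))
  frames <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    at <- parse_atom_records(lines, seq(starts[k], ends[k]))
    if (k == 1 && is.null(topology)) {
      if (nrow(at) == 0) abort("no ATOM/HETATM records in first model")
      topology <- md_structure(resolve_altloc(at))
    }
    if (nrow(at) != nrow(topology)) {
      abort(sprintf(
        "frame %d has %d atoms but topology has %d", k, nrow(at), nrow(topology)
      ))
    }
    frames[[k]] <- cbind(at$x, at$y, at$z)
  }
  md_trajectory(topology, frames, dt = dt)
}

#' Write a trajectory as a multi-model PDB
#'
#' @param traj An [md_trajectory()].
#' @param path Output file path, or `NULL` to return lines invisibly.
#' @return Invisibly, the character vector of lines.
#' @export
write_trajectory_pdb <- function(traj, path = NULL) {
  out <- character(0)
  s <- traj$topology
  for (k in seq_len(n_frames(traj))) {
    sk <- set_coords(s, frame_coords(traj, k))
    out <- c(out, sprintf("MODEL     %4d", k), pdb_atom_lines(sk), "ENDMDL")
  }
  out <- c(out, "END")
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}

FRAME_STREAM_MAGIC <- "MDTS"

is_frame_stream <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 4)
  length(magic) == 4 && rawToChar(magic) == FRAME_STREAM_MAGIC
}

#' Write a trajectory as a binary frame stream
#'
#' Format (little-endian): 4-byte magic `"MDTS"`, int32 `n_atoms`, float64
#' `dt` (ps), then frames as 32-bit floats in Angstrom, atom-major
#' x, y, z per atom. Round trips bit-exactly.
#'
#' @param traj An [md_trajectory()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_frame_stream <- function(traj, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(FRAME_STREAM_MAGIC), con)
  writeBin(as.integer(n_atoms(traj)), con, size = 4, endian = "little")
  writeBin(as.double(traj$dt), con, size = 8, endian = "little")
  for (k in seq_len(n_frames(traj))) {
    writeBin(as.double(traj$xyz[k, ]), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a binary frame stream
#'
#' @param path Frame-stream file path.
#' @param topology An [md_structure()] whose atom count must match the
#'   stream header; when `NULL`, a minimal pseudo-atom topology is built.
#' @return An [md_trajectory()].
#' @export
read_frame_stream <- function(path, topology = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", n = 4))
  if (magic != FRAME_STREAM_MAGIC) abort("not a frame stream (bad magic)")
  na <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  dt <- readBin(con, "double", n = 1, size = 8, endian = "little")
  if (is.null(topology)) {
    topology <- pseudo_atom_structure(na)
  } else if (nrow(topology) != na) {
    abort(sprintf("stream has %d atoms but topology has %d", na, nrow(topology)))
  }
  frames <- list()
  k <- 0
  repeat {
    vals <- readBin(con, "double", n = 3 * na, size = 4, endian = "little")
    if (length(vals) == 0) break
    k <- k + 1
    if (length(vals) != 3 * na) {
      abort(sprintf("frame %d is truncated (%d of %d values)", k, length(vals), 3 * na))
    }
    frames[[k]] <- matrix(vals, ncol = 3, byrow = TRUE)
  }
  if (k == 0) abort("frame stream contains no frames")
  md_trajectory(topology, frames, dt = dt)
}

# Minimal CA-pseudo-atom topology for topology-free streams and toys.
pseudo_atom_structure <- function(n, chain = "A", name = "CA", resid = "GLY") {
  md_structure(tibble(
    serial = seq_len(n), name = name, altloc = "", resid = resid,
    chain = chain, resno = seq_len(n),
    x = 0, y = 0, z = 0, occupancy = 1, element = guess_element(name)
  ))
}
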