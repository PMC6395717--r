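#' Construct a trajectory
#'
#' A trajectory couples a topology (an [md_structure()]) with an ordered set
#' of frames stored as an `n_frames x 3N` coordinate matrix (columns
#' atom-major: x1, y1, z1, x2, ...) and a frame spacing `dt` in picoseconds.
#'
#' @param topology An [md_structure()].
#' @param xyz Either an `n_frames x 3N` matrix or a list of `N x 3` matrices.
#' @param dt Frame spacing in ps (> 0).
#' @return An `md_trajectory` object.
#' @export
md_trajectory <- function(topology, xyz, dt = 1) {
  if (!inherits(topology, "md_structure")) abort("`topology` must be an md_structure")
  if (is.list(xyz) && !is.matrix(xyz)) {
    xyz <- do.call(rbind, lapply(xyz, function(m) as.vector(t(m))))
  }
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  if (ncol(xyz) != 3 * nrow(topology)) {
    abort(sprintf(
      "frame width (%d) does not match 3 x n_atoms (%d)",
      ncol(xyz), 3 * nrow(topology)
    ))
  }
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0) abort("`dt` must be a single positive number")
  structure(
    list(topology = topology, xyz = unname(xyz), dt = dt),
    class = "md_trajectory"
  )
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf(
    "<md_trajectory> %d frames x %d atoms, dt = %g ps\n",
    n_frames(x), n_atoms(x), x$dt
  ))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj An `md_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) nrow(traj$xyz)

#' Number of atoms in a trajectory or structure
#' @param x An `md_trajectory` or `md_structure`.
#' @return Integer atom count.
#' @export
n_atoms <- function(x) {
  if (inherits(x, "md_trajectory")) nrow(x$topology) else nrow(x)
}

#' Coordinates of one frame
#'
#' @param traj An `md_trajectory`.
#' @param i Frame index (1-based).
#' @return `N x 3` coordinate matrix.
#' @export
frame_coords <- function(traj, i) {
  if (i < 1 || i > n_frames(traj)) abort(sprintf("frame %d out of range", i))
  matrix(traj$xyz[i, ], ncol = 3, byrow = TRUE,
         dimnames = list(NULL, c("x", "y", "z")))
}

#' Frame times in picoseconds
#' @param traj An `md_trajectory`.
#' @return Numeric vector `0, dt, 2 dt, ...`.
#' @export
frame_times <- function(traj) (seq_len(n_frames(traj)) - 1) * traj$dt

#' Restrict a trajectory to a subset of atoms
#'
#' @param traj An `md_trajectory`.
#' @param idx Atom indices to keep.
#' @return A new `md_trajectory` over the selected atoms.
#' @export
subset_trajectory <- function(traj, idx) {
  cols <- as.vector(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx))
  md_trajectory(md_structure(traj$topology[idx, ],
                             title = attr(traj$topology, "title") %||% ""),
                traj$xyz[, cols, drop = FALSE], dt = traj$dt)
}

#' Restrict a trajectory to a frame range
#'
#' Used for equilibrium-window analysis (e.g. the back half of a run); the
#' window is always an explicit choice, never auto-detected.
#'
#' @param traj An `md_trajectory`.
#' @param frames Integer vector of frame indices to keep (order preserved).
#' @return A new `md_trajectory`.
#' @export
subset_frames <- function(traj, frames) {
  if (any(frames < 1 | frames > n_frames(traj))) abort("frame index out of range")
  md_trajectory(traj$topology, traj$xyz[frames, , drop = FALSE], dt = traj$dt)
}
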