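#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the (optionally
#' weighted) RMSD between two coordinate sets. The returned convention is
#' `aligned = (mobile - centroid_mobile) %*% rotation + centroid_reference`.
#'
#' @param mobile `N x 3` matrix to move.
#' @param reference `N x 3` matrix to match.
#' @param weights Optional per-atom non-negative weights.
#' @return A `kabsch_fit` list with `rotation` (3x3, det +1), `translation`
#'   (the mobile centroid maps onto `translation` after rotation) and `rmsd`
#'   (Angstrom).
#' @export
kabsch_fit <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference))) abort("coordinate sets differ in size")
  n <- nrow(mobile)
  if (n < 3) abort("need at least 3 atoms for a rigid fit")
  w <- weights %||% rep(1, n)
  if (length(w) != n || any(w < 0) || sum(w) == 0) abort("invalid weights")
  w <- w / sum(w)
  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  a <- sweep(mobile, 2, cm)
  b <- sweep(reference, 2, cr)
  h <- t(a * w) %*% b
  sv <- svd(h)
  # degenerate inputs: fewer than two independent directions
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1e-12)) {
    abort("degenerate (collinear or coincident) coordinates; fit undefined")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  corr <- diag(c(1, 1, d))
  rot <- sv$u %*% corr %*% t(sv$v)
  fitted <- a %*% rot
  msd <- sum(w * rowSums((fitted - b)^2))
  structure(
    list(rotation = rot, translation = cr, center_mobile = cm,
         rmsd = sqrt(max(msd, 0))),
    class = "kabsch_fit"
  )
}

#' @export
print.kabsch_fit <- function(x, ...) {
  cat(sprintf("<kabsch_fit> rmsd = %.4f A\n", x$rmsd))
  invisible(x)
}

#' Apply a fitted rigid transform to coordinates
#'
#' @param xyz `N x 3` matrix.
#' @param fit A [kabsch_fit()] result.
#' @return Transformed `N x 3` matrix.
#' @export
apply_fit <- function(xyz, fit) {
  sweep(sweep(as.matrix(xyz), 2, fit$center_mobile) %*% fit$rotation,
        2, fit$translation, `+`)
}

# Iterative mean-structure fitting: fit all frames to a running mean until
# the mean moves < tol (RMS, Angstrom) or max_iter is reached. Returns the
# fitted frames (n_frames x 3N over the selected atoms) and the converged
# mean (N x 3). Shared by RMSF and PCA so that cross-module identities hold
# exactly.
fit_to_mean <- function(traj, idx = NULL, tol = 1e-6, max_iter = 20) {
  idx <- idx %||% seq_len(n_atoms(traj))
  if (length(idx) == 0) abort("empty selection")
  cols <- as.vector(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx))
  xyz <- traj$xyz[, cols, drop = FALSE]
  nf <- nrow(xyz)
  if (nf < 2) abort("need at least 2 frames")
  as_frames <- function(row) matrix(row, ncol = 3, byrow = TRUE)
  ref <- as_frames(xyz[1, ])
  fitted <- xyz
  for (iter in seq_len(max_iter)) {
    for (k in seq_len(nf)) {
      fk <- kabsch_fit(as_frames(xyz[k, ]), ref)
      fitted[k, ] <- as.vector(t(apply_fit(as_frames(xyz[k, ]), fk)))
    }
    new_mean <- as_frames(colMeans(fitted))
    shift <- sqrt(mean(rowSums((new_mean - ref)^2)))
    ref <- new_mean
    if (shift < tol) break
  }
  list(fitted = fitted, mean = ref, idx = idx, iterations = iter)
}

#' Superpose every frame onto a reference using a sub-selection
#'
#' Computes each frame's rigid fit on the selected atoms (e.g. a rigid
#' domain) and applies it to the whole frame. Standard when analysing
#' domain motion: superpose on the static domain, then inspect the rest.
#'
#' @param traj An [md_trajectory()].
#' @param selection An [atom_selection()] defining the fitting atoms.
#' @param reference Reference coordinates over the full topology
#'   (default: the topology's own).
#' @return A new [md_trajectory()] with every frame superposed.
#' @export
superpose_trajectory <- function(traj, selection = backbone_selection(),
                                 reference = NULL) {
  idx <- select_atoms(traj$topology, selection)
  if (length(idx) == 0) abort("selection matched no atoms")
  ref_xyz <- if (is.null(reference)) coords(traj$topology) else as.matrix(reference)
  ref <- ref_xyz[idx, , drop = FALSE]
  out <- traj$xyz
  for (k in seq_len(n_frames(traj))) {
    fr <- frame_coords(traj, k)
    fk <- kabsch_fit(fr[idx, , drop = FALSE], ref)
    out[k, ] <- as.vector(t(apply_fit(fr, fk)))
  }
  md_trajectory(traj$topology, out, dt = traj$dt)
}

#' RMSD time series against a reference structure
#'
#' Each frame is independently superposed (fresh Kabsch fit on the selected
#' atoms) onto the reference before the deviation is measured.
#'
#' @param traj An [md_trajectory()].
#' @param reference An [md_structure()] or `N x 3` matrix over the full
#'   topology; defaults to the topology coordinates.
#' @param selection An [atom_selection()] (default: backbone atoms).
#' @return A tibble with `frame`, `time_ps`, `rmsd` (Angstrom).
#' @export
rmsd_series <- function(traj, reference = NULL, selection = backbone_selection()) {
  idx <- select_atoms(traj$topology, selection)
  if (length(idx) == 0) abort("selection matched no atoms in trajectory")
  ref_xyz <- if (is.null(reference)) {
    coords(traj$topology)
  } else if (inherits(reference, "md_structure")) {
    if (nrow(reference) != n_atoms(traj)) abort("reference/topology atom mismatch")
    coords(reference)
  } else {
    as.matrix(reference)
  }
  ref <- ref_xyz[idx, , drop = FALSE]
  vals <- vapply(seq_len(n_frames(traj)), function(k) {
    kabsch_fit(frame_coords(traj, k)[idx, , drop = FALSE], ref)$rmsd
  }, numeric(1))
  tibble(frame = seq_len(n_frames(traj)), time_ps = frame_times(traj), rmsd = vals)
}

#' Probability distribution of an RMSD series
#'
#' @param series Numeric vector of RMSD values (or the tibble from
#'   [rmsd_series()]).
#' @param bin_width Bin width in Angstrom (> 0).
#' @return A tibble with `bin_mid`, `count`, `probability`; probabilities
#'   sum to one.
#' @export
rmsd_histogram <- function(series, bin_width = 0.1) {
  if (is.data.frame(series)) series <- series$rmsd
  if (length(series) < 1) abort("need at least one value")
  if (!is.numeric(bin_width) || bin_width <= 0) abort("`bin_width` must be positive")
  lo <- floor(min(series) / bin_width) * bin_width
  breaks <- seq(lo, max(series) + bin_width, by = bin_width)
  bin <- findInterval(series, breaks, rightmost.closed = TRUE)
  counts <- tabulate(bin, nbins = length(breaks) - 1)
  tibble(
    bin_mid = breaks[-length(breaks)] + bin_width / 2,
    count = counts,
    probability = counts / sum(counts)
  )
}

#' Per-atom root-mean-square fluctuation
#'
#' Frames are superposed onto their iteratively refined mean structure
#' (fit, average, refit; convergence 1e-6 Angstrom) and
#' `rmsf_i = sqrt(<|x_i - <x_i>|^2>)` is reported per selected atom.
#'
#' @param traj An [md_trajectory()].
#' @param selection An [atom_selection()]; default backbone atoms.
#' @return A tibble with `atom` (topology row index), `label`, `rmsf`
#'   (Angstrom); the converged mean coordinates are attached as attribute
#'   `"mean"`.
#' @export
rmsf <- function(traj, selection = backbone_selection()) {
  idx <- select_atoms(traj$topology, selection)
  if (length(idx) == 0) abort("selection matched no atoms")
  ft <- fit_to_mean(traj, idx)
  dev2 <- sweep(ft$fitted, 2, as.vector(t(ft$mean)))^2
  per_coord <- colMeans(dev2)
  per_atom <- matrix(per_coord, ncol = 3, byrow = TRUE)
  out <- tibble(
    atom = idx,
    label = atom_labels(traj$topology[idx, ]),
    rmsf = sqrt(rowSums(per_atom))
  )
  attr(out, "mean") <- ft$mean
  out
}
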