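#' Cartesian covariance matrix of a trajectory
#'
#' Elements are `C_ij = <(x_i - <x_i>)(x_j - <x_j>)>` over frames (ensemble
#' average, no mass weighting), computed on the selected atoms after an
#' optional superposition of every frame onto the iteratively refined mean
#' structure (the default, standard in essential dynamics: it removes
#' rigid-body motion).
#'
#' @param traj An [md_trajectory()].
#' @param selection An [atom_selection()]; default backbone atoms.
#' @param fit Superpose frames onto the iterative mean first (default TRUE).
#' @return A list with `C` (3N x 3N), `mean` (3N vector), `idx` (atom
#'   indices), `n_frames`.
#' @export
covariance_matrix <- function(traj, selection = backbone_selection(), fit = TRUE) {
  idx <- select_atoms(traj$topology, selection)
  if (length(idx) == 0) abort("selection matched no atoms")
  if (n_frames(traj) < 2) abort("need at least 2 frames")
  if (fit) {
    ft <- fit_to_mean(traj, idx)
    x <- ft$fitted
    mu <- as.vector(t(ft$mean))
  } else {
    cols <- as.vector(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx))
    x <- traj$xyz[, cols, drop = FALSE]
    mu <- colMeans(x)
  }
  d <- sweep(x, 2, mu)
  C <- crossprod(d) / nrow(d)
  C <- (C + t(C)) / 2
  list(C = C, mean = mu, idx = idx, n_frames = nrow(d))
}

#' Eigendecomposition of a positional covariance matrix
#'
#' @param covariance Output of [covariance_matrix()], or a bare symmetric
#'   matrix.
#' @return An `md_pca` object: `mean` (3N), `values` (descending, A^2),
#'   `vectors` (orthonormal 3N columns), `idx`, `n_frames`.
#' @export
eigendecompose <- function(covariance) {
  if (is.matrix(covariance)) covariance <- list(C = covariance, mean = rep(0, ncol(covariance)), idx = NULL, n_frames = NA_integer_)
  C <- covariance$C
  if (!isSymmetric(unname(C), tol = 1e-8)) abort("covariance matrix is not symmetric")
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  structure(
    list(mean = covariance$mean, values = e$values, vectors = e$vectors,
         idx = covariance$idx, n_frames = covariance$n_frames),
    class = "md_pca"
  )
}

#' Essential-dynamics PCA of a trajectory
#'
#' Convenience wrapper: covariance (with iterative-mean fitting) followed by
#' eigendecomposition.
#'
#' @inheritParams covariance_matrix
#' @param dt Frame spacing carried through for projections; defaults to the
#'   trajectory's.
#' @return An `md_pca` object.
#' @export
pca_trajectory <- function(traj, selection = backbone_selection(), fit = TRUE,
                           dt = NULL) {
  res <- eigendecompose(covariance_matrix(traj, selection, fit = fit))
  res$dt <- dt %||% traj$dt
  res
}

#' @export
print.md_pca <- function(x, ...) {
  tot <- sum(pmax(x$values, 0))
  cat(sprintf(
    "<md_pca> %d modes over %s frames; top-2 variance fraction %.1f%%\n",
    length(x$values), x$n_frames,
    if (tot > 0) 100 * sum(pmax(x$values[1:min(2, length(x$values))], 0)) / tot else NA_real_
  ))
  invisible(x)
}

#' Tidy a PCA result into an eigenvalue table
#'
#' One row per mode with `eigenvalue`, `variance_fraction` and
#' `cumulative_fraction`.
#'
#' @param x An `md_pca` object.
#' @param ... Unused.
#' @return A tibble with one row per mode.
#' @export
tidy.md_pca <- function(x, ...) {
  v <- pmax(x$values, 0)
  tot <- sum(v)
  tibble(
    mode = seq_along(v),
    eigenvalue = x$values,
    variance_fraction = if (tot > 0) v / tot else rep(NA_real_, length(v)),
    cumulative_fraction = if (tot > 0) cumsum(v) / tot else rep(NA_real_, length(v))
  )
}

#' One-row PCA summary
#'
#' Mode count, frame count, total variance and top-2 variance fraction.
#'
#' @param x An `md_pca` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.md_pca <- function(x, ...) {
  v <- pmax(x$values, 0)
  tibble(
    n_modes = length(v),
    n_frames = x$n_frames,
    total_variance = sum(v),
    variance_fraction_2 = if (sum(v) > 0) sum(v[1:min(2, length(v))]) / sum(v) else NA_real_
  )
}

#' Project a trajectory onto principal components
#'
#' `p_i(t) = v_i . (x(t) - mean)` per frame, with frames superposed onto the
#' PCA mean structure first (matching the fitting protocol that produced the
#' covariance).
#'
#' @param traj An [md_trajectory()].
#' @param result An `md_pca` object from the same selection.
#' @param modes Mode indices (1-based, eigenvalue-descending order).
#' @param fit Superpose each frame onto the PCA mean first (default TRUE;
#'   use FALSE for unfitted analyses such as diffusion diagnostics).
#' @return A tibble with `frame`, `time_ps`, `mode`, `value` (Angstrom).
#' @export
project <- function(traj, result, modes = 1:2, fit = TRUE) {
  if (any(modes < 1 | modes > length(result$values))) {
    abort(sprintf("mode index out of range 1..%d", length(result$values)))
  }
  idx <- result$idx %||% seq_len(n_atoms(traj))
  cols <- as.vector(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx))
  x <- traj$xyz[, cols, drop = FALSE]
  mu_mat <- matrix(result$mean, ncol = 3, byrow = TRUE)
  if (fit) {
    for (k in seq_len(nrow(x))) {
      fk <- kabsch_fit(matrix(x[k, ], ncol = 3, byrow = TRUE), mu_mat)
      x[k, ] <- as.vector(t(apply_fit(matrix(x[k, ], ncol = 3, byrow = TRUE), fk)))
    }
  }
  d <- sweep(x, 2, result$mean)
  proj <- d %*% result$vectors[, modes, drop = FALSE]
  dt <- result$dt %||% traj$dt
  tidyr::pivot_longer(
    tibble::as_tibble(stats::setNames(as.data.frame(proj), paste0("m", modes))) |>
      mutate(frame = row_number(), time_ps = (row_number() - 1) * dt),
    cols = tidyr::starts_with("m"), names_to = "mode", values_to = "value"
  ) |>
    mutate(mode = as.integer(sub("^m", "", .data$mode))) |>
    arrange(.data$mode, .data$frame) |>
    select("frame", "time_ps", "mode", "value")
}

#' Cumulative variance fraction of the leading modes
#'
#' @param result An `md_pca` object.
#' @param k Number of leading modes.
#' @return Fraction in `[0, 1]`.
#' @export
variance_fraction <- function(result, k) {
  if (k < 1) abort("`k` must be >= 1")
  v <- pmax(result$values, 0)
  k <- min(k, length(v))
  if (sum(v) == 0) return(0)
  sum(v[seq_len(k)]) / sum(v)
}

#' Cosine content of a principal-component projection
#'
#' `cc_i = (2/T) (int_0^T cos(i pi t / T) p_i(t) dt)^2 / int_0^T p_i(t)^2 dt`
#' evaluated by the trapezoid rule on uniformly spaced frames with time
#' mapped to `[0, T]`. Values near 1 indicate random-diffusion-like
#' (insufficient) sampling; the statistic is invariant under amplitude
#' scaling of the series.
#'
#' @param series Numeric projection values, or the tibble from [project()]
#'   (a single mode).
#' @param i Cosine index; defaults to the tibble's mode, else 1.
#' @return Value in `[0, 1]`.
#' @export
cosine_content <- function(series, i = NULL) {
  if (is.data.frame(series)) {
    if (length(unique(series$mode)) != 1) abort("pass a single mode's projection")
    i <- i %||% unique(series$mode)
    series <- series$value
  }
  i <- i %||% 1
  n <- length(series)
  if (n < 2) abort("need at least 2 points")
  if (all(series == 0)) abort("cosine content undefined for an identically zero series")
  u <- seq(0, 1, length.out = n)  # t / T
  num <- pracma::trapz(u, cos(i * pi * u) * series)^2 * 2
  den <- pracma::trapz(u, series^2)
  cc <- num / den
  min(max(cc, 0), 1)
}

#' Per-atom displacement arrows for a principal mode
#'
#' Arrow `k` starts at the mean position of atom `k` and points along the
#' mode eigenvector, scaled by `scale * sqrt(eigenvalue)`.
#'
#' @param result An `md_pca` object.
#' @param i Mode index.
#' @param scale Multiplier applied on top of `sqrt(eigenvalue)`.
#' @return A tibble with start coordinates (`x`, `y`, `z`), displacement
#'   (`dx`, `dy`, `dz`) and `magnitude`.
#' @export
mode_vectors <- function(result, i = 1, scale = 1) {
  if (i < 1 || i > length(result$values)) abort("mode index out of range")
  amp <- scale * sqrt(max(result$values[i], 0))
  v <- matrix(result$vectors[, i], ncol = 3, byrow = TRUE)
  mu <- matrix(result$mean, ncol = 3, byrow = TRUE)
  tibble(
    atom = result$idx %||% seq_len(nrow(mu)),
    x = mu[, 1], y = mu[, 2], z = mu[, 3],
    dx = amp * v[, 1], dy = amp * v[, 2], dz = amp * v[, 3],
    magnitude = amp * sqrt(rowSums(v^2))
  )
}

#' Export mode arrows as a two-model PDB (mean, mean + displacement)
#'
#' @param result An `md_pca` object.
#' @param topology The trajectory topology the PCA was computed from.
#' @param i Mode index.
#' @param scale Displacement scale.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_mode_pdb <- function(result, topology, i = 1, scale = 1, path) {
  mv <- mode_vectors(result, i, scale)
  idx <- result$idx %||% seq_len(nrow(mv))
  s <- md_structure(topology[idx, ])
  s1 <- set_coords(s, cbind(mv$x, mv$y, mv$z))
  s2 <- set_coords(s, cbind(mv$x + mv$dx, mv$y + mv$dy, mv$z + mv$dz))
  tr <- md_trajectory(s1, list(coords(s1), coords(s2)), dt = 1)
  write_trajectory_pdb(tr, path)
  invisible(path)
}
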