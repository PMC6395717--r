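# Seeded fixture generators. Every generator routes all randomness through
# withr::with_seed so identical inputs give bit-identical output without
# touching the caller's RNG state.

#' Toy globular structure of pseudo-atoms
#'
#' Deterministic blob of CA pseudo-atoms on a perturbed grid; handy base
#' structure for planted-mode trajectories.
#'
#' @param n_atoms Number of atoms.
#' @param chain Chain id.
#' @param spread Approximate radius, Angstrom.
#' @param seed RNG seed.
#' @return An [md_structure()].
#' @export
gen_toy_structure <- function(n_atoms = 20, chain = "A", spread = 10, seed = 1) {
  withr::with_seed(seed, {
    xyz <- matrix(stats::runif(3 * n_atoms, -spread, spread), ncol = 3)
  })
  s <- pseudo_atom_structure(n_atoms, chain = chain)
  set_coords(s, xyz)
}

#' Random internal collective modes
#'
#' Draws `k` random orthonormal 3N displacement vectors orthogonal to the
#' six rigid-body modes (three translations, three rotations about the
#' centroid) of the base structure. Planting such modes guarantees the
#' fitted-PCA machinery can recover them: superposition removes only
#' rigid-body motion.
#'
#' @param base An [md_structure()].
#' @param k Number of modes.
#' @param seed RNG seed.
#' @return A `3N x k` orthonormal matrix.
#' @export
orthonormal_modes <- function(base, k = 2, seed = 1) {
  xyz <- coords(base)
  n <- nrow(xyz)
  cen <- sweep(xyz, 2, colMeans(xyz))
  rigid <- matrix(0, 3 * n, 6)
  for (d in 1:3) rigid[seq(d, 3 * n, 3), d] <- 1  # translations
  # infinitesimal rotations about x, y, z
  rots <- list(c(2, 3), c(3, 1), c(1, 2))
  for (a in 1:3) {
    v <- matrix(0, n, 3)
    v[, rots[[a]][1]] <- -cen[, rots[[a]][2]]
    v[, rots[[a]][2]] <- cen[, rots[[a]][1]]
    rigid[, 3 + a] <- as.vector(t(v))
  }
  withr::with_seed(seed, {
    rnd <- matrix(stats::rnorm(3 * n * k), ncol = k)
  })
  basis <- qr.Q(qr(cbind(rigid, rnd)))
  out <- basis[, 7:(6 + k), drop = FALSE]
  # qr.Q sign is implementation-defined; fix a deterministic convention
  for (j in seq_len(k)) if (out[1, j] < 0) out[, j] <- -out[, j]
  out
}

#' Trajectory with planted orthogonal collective modes
#'
#' Frame `t` is `base + sum_k sigma_k z_kt mode_k + noise`, with `z`
#' standard normal. This emulates the covariance structure essential-
#' dynamics PCA assumes: a few dominant orthogonal directions over white
#' positional noise, with known ground-truth eigenvalues `sigma_k^2`.
#'
#' @param base An [md_structure()] (the mean structure).
#' @param modes `3N x k` matrix of mutually orthonormal displacement
#'   vectors (checked to 1e-8).
#' @param amplitudes Mode standard deviations `sigma_k`, Angstrom,
#'   descending.
#' @param noise_sd White-noise standard deviation per coordinate, Angstrom.
#' @param n_frames Number of frames.
#' @param seed RNG seed.
#' @param dt Frame spacing, ps.
#' @return An [md_trajectory()]; the drawn mode amplitudes are attached as
#'   attribute `"z"` (`n_frames x k`).
#' @export
gen_mode_trajectory <- function(base, modes, amplitudes, noise_sd = 0,
                                n_frames = 1000, seed = 1, dt = 1) {
  modes <- as.matrix(modes)
  if (nrow(modes) != 3 * nrow(base)) abort("modes must be 3N x k")
  g <- crossprod(modes)
  if (max(abs(g - diag(ncol(modes)))) > 1e-8) {
    abort("modes must be mutually orthonormal (within 1e-8)")
  }
  if (length(amplitudes) != ncol(modes)) abort("one amplitude per mode required")
  if (is.unsorted(rev(amplitudes))) abort("amplitudes must be descending")
  base_vec <- as.vector(t(coords(base)))
  withr::with_seed(seed, {
    z <- matrix(stats::rnorm(n_frames * ncol(modes)), n_frames)
    noise <- if (noise_sd > 0) {
      matrix(stats::rnorm(n_frames * length(base_vec), sd = noise_sd), n_frames)
    } else {
      0
    }
  })
  xyz <- matrix(base_vec, n_frames, length(base_vec), byrow = TRUE) +
    z %*% (t(modes) * amplitudes) + noise
  out <- md_trajectory(base, xyz, dt = dt)
  attr(out, "z") <- z
  out
}

#' Random-diffusion trajectory
#'
#' Cumulative-sum Gaussian random walk per coordinate: the canonical
#' null model whose leading principal components resemble cosines
#' (the signature the cosine-content diagnostic detects).
#'
#' @param n_atoms Number of pseudo-atoms.
#' @param step_sd Per-step displacement SD, Angstrom.
#' @param n_frames Number of frames.
#' @param seed RNG seed.
#' @param dt Frame spacing, ps.
#' @return An [md_trajectory()].
#' @export
gen_diffusion_trajectory <- function(n_atoms = 10, step_sd = 0.1,
                                     n_frames = 1000, seed = 1, dt = 1) {
  if (n_atoms <= 0 || n_frames <= 0 || step_sd < 0) abort("arguments must be positive")
  s <- gen_toy_structure(n_atoms, seed = seed)
  base_vec <- as.vector(t(coords(s)))
  withr::with_seed(seed, {
    steps <- matrix(stats::rnorm(n_frames * 3 * n_atoms, sd = step_sd), n_frames)
  })
  xyz <- apply(steps, 2, cumsum)
  if (n_frames == 1) xyz <- matrix(xyz, nrow = 1)
  xyz <- sweep(xyz, 2, base_vec, `+`)
  md_trajectory(s, xyz, dt = dt)
}

#' Scheduled hydrogen-bond scene
#'
#' A minimal donor/acceptor (optionally water-bridged) system whose bond is
#' geometrically satisfied exactly on the "on" frames (2.9 Angstrom,
#' collinear donor-H-acceptor) and broken on the "off" frames (5.0
#' Angstrom), giving exact ground-truth occupancy.
#'
#' @param schedule Logical vector, one element per frame.
#' @param bridge If `TRUE`, build donor - water - acceptor so the bond is a
#'   water bridge; direct contact is never formed.
#' @param dt Frame spacing, ps.
#' @return An [md_trajectory()] whose topology has a serine-like donor
#'   (chain `P`), a nucleotide-like acceptor (chain `D`) and, for bridges,
#'   one water.
#' @export
gen_hbond_scene <- function(schedule, bridge = FALSE, dt = 1) {
  if (length(schedule) == 0) abort("schedule must be non-empty")
  schedule <- as.logical(schedule)
  on_d <- 2.9
  off_d <- 5.0
  atoms <- list(
    tibble(name = "OG", resid = "SER", resno = 1, chain = "P", x = 0, y = 0, z = 0),
    tibble(name = "HG", resid = "SER", resno = 1, chain = "P", x = 0.96, y = 0, z = 0)
  )
  if (bridge) {
    atoms <- c(atoms, list(
      tibble(name = "O", resid = "HOH", resno = 100, chain = "W", x = on_d, y = 0, z = 0),
      tibble(name = "H1", resid = "HOH", resno = 100, chain = "W", x = on_d + 0.96, y = 0, z = 0),
      tibble(name = "H2", resid = "HOH", resno = 100, chain = "W", x = on_d - 0.3, y = 0.9, z = 0),
      tibble(name = "O1P", resid = "DT", resno = 5, chain = "D", x = 2 * on_d, y = 0, z = 0)
    ))
  } else {
    atoms <- c(atoms, list(
      tibble(name = "O1P", resid = "DT", resno = 5, chain = "D", x = on_d, y = 0, z = 0)
    ))
  }
  s <- md_structure(bind_rows(atoms))
  base <- coords(s)
  frames <- lapply(schedule, function(on) {
    xyz <- base
    if (!on) {
      # displace everything beyond the donor along +x to break the geometry
      shift <- off_d - on_d
      move <- s$chain != "P"
      xyz[move, 1] <- xyz[move, 1] + shift * if (bridge) 2 else 1
      if (bridge) {
        # move the acceptor further so neither leg of the bridge survives
        acc <- s$chain == "D"
        xyz[acc, 1] <- xyz[acc, 1] + shift
      }
    }
    xyz
  })
  md_trajectory(s, frames, dt = dt)
}

#' Smoothly bent duplex trajectory
#'
#' Maps an ideal B-form duplex onto a circular arc with the stated total
#' turning angle, optionally adding Gaussian atomic jitter per frame.
#' `arc = 0, thermal_sd = 0` reproduces [build_bdna()] exactly.
#'
#' @param sequence DNA string.
#' @param total_arc Total axis turning in degrees (0 <= arc < 180).
#' @param thermal_sd Per-coordinate Gaussian jitter SD, Angstrom.
#' @param n_frames Number of frames.
#' @param seed RNG seed (used only when `thermal_sd > 0`).
#' @param dt Frame spacing, ps.
#' @return An [md_trajectory()] with the duplex topology.
#' @export
gen_bent_duplex <- function(sequence, total_arc = 0, thermal_sd = 0,
                            n_frames = 1, seed = 1, dt = 1) {
  if (total_arc < 0) abort("`total_arc` must be >= 0")
  if (total_arc >= 180) abort("`total_arc` must be < 180 degrees")
  s <- build_bdna(sequence)
  xyz <- coords(s)
  if (total_arc > 0) {
    nlev <- length(unique(s$resno[s$chain == "A"]))
    len <- (nlev - 1) * BDNA_RISE
    R <- len / (total_arc * pi / 180)
    # bend in the x-z plane about a line parallel to y through (R, 0, *)
    phi <- xyz[, 3] / R
    xnew <- R - (R - xyz[, 1]) * cos(phi)
    znew <- (R - xyz[, 1]) * sin(phi)
    xyz <- cbind(xnew, xyz[, 2], znew)
  }
  bent <- set_coords(s, xyz)
  if (thermal_sd > 0) {
    withr::with_seed(seed, {
      frames <- lapply(seq_len(n_frames), function(k) {
        xyz + matrix(stats::rnorm(length(xyz), sd = thermal_sd), ncol = 3)
      })
    })
  } else {
    frames <- rep(list(xyz), n_frames)
  }
  md_trajectory(bent, frames, dt = dt)
}

#' Two-body hinge toy trajectory
#'
#' Two rigid pseudo-atom bodies joined at a hinge atom at the origin; body
#' B is rotated about the z axis so that the angle between the reference
#' atoms of the two bodies at the hinge follows `schedule` exactly
#' (degrees). Useful ground truth for angle-series and PCA machinery: only
#' body B moves.
#'
#' @param schedule Hinge angle per frame, degrees.
#' @param n_body Atoms per body; a length-2 vector gives the fixed and
#'   mobile body sizes separately (an asymmetric split keeps the
#'   superposition anchored to the fixed body, so planted motion stays on
#'   the mobile one).
#' @param seed RNG seed for body shapes.
#' @param dt Frame spacing, ps.
#' @return An [md_trajectory()]; chains `A` (fixed body), `H` (hinge
#'   atom), `B` (mobile body). The angle defined by `A:1:CA`, `H:1:CA`,
#'   `B:1:CA` follows the schedule.
#' @export
gen_hinge_trajectory <- function(schedule, n_body = 10, seed = 1, dt = 1) {
  if (length(schedule) == 0) abort("schedule must be non-empty")
  n_body <- rep_len(n_body, 2)
  withr::with_seed(seed, {
    blob <- function(n) matrix(stats::runif(3 * (n - 1), -2, 2), ncol = 3)
    body_a_extra <- blob(n_body[1])
    body_b_extra <- blob(n_body[2])
  })
  # reference atoms at +/- 5 A from the hinge along x (before rotation)
  body_a <- rbind(c(-5, 0, 0), sweep(body_a_extra, 2, c(-8, 0, 0), `+`))
  body_b0 <- rbind(c(5, 0, 0), sweep(body_b_extra, 2, c(8, 0, 0), `+`))
  hinge <- matrix(0, 1, 3)
  n_a <- nrow(body_a)
  n_b <- nrow(body_b0)
  at <- tibble(
    name = "CA", resid = "GLY",
    chain = c(rep("A", n_a), "H", rep("B", n_b)),
    resno = c(seq_len(n_a), 1L, seq_len(n_b)),
    x = 0, y = 0, z = 0
  )
  s <- set_coords(md_structure(at), rbind(body_a, hinge, body_b0))
  frames <- lapply(schedule, function(ang) {
    # rotate body B about z so angle(ref_A, hinge, ref_B) = ang
    a <- (180 - ang) * pi / 180
    rot <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
    rbind(body_a, hinge, body_b0 %*% t(rot))
  })
  md_trajectory(s, frames, dt = dt)
}

#' Write a generator output with its ground-truth sidecar
#'
#' Writes a trajectory (frame stream plus topology PDB) together with a
#' JSON sidecar describing the planted ground truth, so external tools can
#' validate against the same fixtures.
#'
#' @param traj An [md_trajectory()].
#' @param prefix Output path prefix.
#' @param truth A list of ground-truth values to record.
#' @return Invisibly, the files written.
#' @export
write_synthetic_bundle <- function(traj, prefix, truth = list()) {
  topo <- paste0(prefix, "_topology.pdb")
  stream <- paste0(prefix, ".mdts")
  sidecar <- paste0(prefix, "_truth.json")
  write_pdb(traj$topology, topo)
  write_frame_stream(traj, stream)
  jsonlite::write_json(truth, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(c(topo, stream, sidecar))
}
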