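#' Read a per-atom force-field parameter file
#'
#' Whitespace-delimited columns: `atom_label` (`chain:resno:name`),
#' `charge` (e), `sigma` (Angstrom), `epsilon` (kcal/mol), `born_radius`
#' (Angstrom). The package never derives force-field parameters; they are
#' always supplied (templates for the toy systems ship with the package).
#'
#' @param path Parameter file path.
#' @return A tibble with the five columns.
#' @export
read_ff_params <- function(path) {
  df <- utils::read.table(path, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("atom_label", "charge", "sigma", "epsilon", "born_radius")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    abort(paste0("parameter file lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (any(df$sigma < 0) || any(df$epsilon < 0)) abort("sigma and epsilon must be >= 0")
  if (any(df$born_radius <= 0)) abort("born radii must be positive")
  as_tibble(df[, need])
}

#' Uniform parameters for a toy structure
#'
#' @param structure An [md_structure()].
#' @param charge,sigma,epsilon,born_radius Values recycled across atoms.
#' @return A parameter tibble aligned to the structure's atoms.
#' @export
uniform_ff_params <- function(structure, charge = 0, sigma = 3.4,
                              epsilon = 0.1, born_radius = 1.7) {
  tibble(
    atom_label = sprintf("%s:%d:%s", structure$chain, structure$resno, structure$name),
    charge = rep_len(charge, nrow(structure)),
    sigma = rep_len(sigma, nrow(structure)),
    epsilon = rep_len(epsilon, nrow(structure)),
    born_radius = rep_len(born_radius, nrow(structure))
  )
}

# Align a parameter table to structure rows; error names the first
# unparameterized atom.
match_params <- function(structure, params, idx = seq_len(nrow(structure))) {
  labels <- sprintf("%s:%d:%s", structure$chain, structure$resno, structure$name)
  m <- match(labels[idx], params$atom_label)
  if (anyNA(m)) {
    abort(sprintf("atom %s has no force-field parameters", labels[idx][which(is.na(m))[1]]))
  }
  params[m, ]
}

pair_distances <- function(a, b) {
  d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * a %*% t(b)
  sqrt(pmax(d2, 0))
}

#' Coulomb interaction energy between two groups
#'
#' `sum k_e q_a q_b / (eps_r r_ab)` with `k_e = 332.0636` kcal A / (mol e^2).
#'
#' @param xyz_A,xyz_B Coordinate matrices.
#' @param q_A,q_B Partial charges (e).
#' @param dielectric Relative dielectric `eps_r`.
#' @return Energy in kcal/mol (0 when either group is empty).
#' @export
coulomb_energy <- function(xyz_A, q_A, xyz_B, q_B, dielectric = 1) {
  if (length(q_A) == 0 || length(q_B) == 0) return(0)
  r <- pair_distances(as.matrix(xyz_A), as.matrix(xyz_B))
  if (any(r < 0.5)) abort(sprintf("atomic clash: pair distance %.3f A < 0.5 A", min(r)))
  sum(KE_KCAL * outer(q_A, q_B) / (dielectric * r))
}

#' Lennard-Jones interaction energy between two groups
#'
#' `sum 4 eps_ij ((sigma_ij/r)^12 - (sigma_ij/r)^6)` with Lorentz-Berthelot
#' combination (`sigma_ij = (sigma_i + sigma_j)/2`,
#' `eps_ij = sqrt(eps_i eps_j)`).
#'
#' @param xyz_A,xyz_B Coordinate matrices.
#' @param params_A,params_B Parameter tibbles (need `sigma`, `epsilon`).
#' @return Energy in kcal/mol.
#' @export
lj_energy <- function(xyz_A, params_A, xyz_B, params_B) {
  if (nrow(params_A) == 0 || nrow(params_B) == 0) return(0)
  r <- pair_distances(as.matrix(xyz_A), as.matrix(xyz_B))
  if (any(r < 0.5)) abort(sprintf("atomic clash: pair distance %.3f A < 0.5 A", min(r)))
  sig <- outer(params_A$sigma, params_B$sigma, function(a, b) (a + b) / 2)
  eps <- sqrt(outer(params_A$epsilon, params_B$epsilon))
  sr6 <- (sig / r)^6
  sum(4 * eps * (sr6^2 - sr6))
}

#' Effective Born radii (pairwise descreening)
#'
#' Hawkins-Cramer-Truhlar-style analytic pairwise descreening of the seed
#' (intrinsic) radii. An isolated atom keeps its intrinsic radius.
#'
#' @param xyz Coordinate matrix.
#' @param rho Intrinsic radii, Angstrom.
#' @param scale Descreening scale factor(s) for neighbour radii
#'   (default 0.8).
#' @return Effective radii, Angstrom.
#' @export
effective_born_radii <- function(xyz, rho, scale = 0.8) {
  n <- length(rho)
  if (n == 1) return(rho)
  scale <- rep_len(scale, n)
  r <- pair_distances(as.matrix(xyz), as.matrix(xyz))
  inv_eff <- 1 / rho
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(n)[-i]) {
      sr <- scale[j] * rho[j]
      rij <- r[i, j]
      if (rij + sr <= rho[i]) next  # neighbour buried inside atom i
      L <- max(rho[i], abs(rij - sr))
      U <- rij + sr
      acc <- acc + (1 / L - 1 / U) +
        (rij / 4) * (1 / U^2 - 1 / L^2) +
        (1 / (2 * rij)) * log(L / U) +
        (sr^2 / (4 * rij)) * (1 / L^2 - 1 / U^2)
    }
    inv_eff[i] <- 1 / rho[i] - acc / 2
  }
  ifelse(inv_eff > 0, 1 / inv_eff, 1e6)
}

# Still generalized-Born pair function.
gb_f <- function(r, Ri, Rj) sqrt(r^2 + Ri * Rj * exp(-r^2 / (4 * Ri * Rj)))

# Per-atom polar solvation contributions of one state (kcal/mol):
# g_i = -1/2 k_e (1/eps_in - 1/eps_out) sum_j q_i q_j / f_ij (j over all
# atoms including i, with f_ii = R_i). sum(g) is the state's G_polar.
gb_per_atom <- function(xyz, q, radii, eps_in, eps_out) {
  tau <- 1 / eps_in - 1 / eps_out
  n <- length(q)
  r <- pair_distances(as.matrix(xyz), as.matrix(xyz))
  f <- gb_f(r, outer(radii, rep(1, n)), outer(rep(1, n), radii))
  diag(f) <- radii
  qq <- outer(q, q) / f
  -0.5 * KE_KCAL * tau * rowSums(qq)
}

#' Generalized-Born polar solvation energy of binding
#'
#' Pairwise Still functional over effective (descreened) radii;
#' `DG_polar = G(complex) - G(A) - G(B)` at fixed coordinates (the
#' single-trajectory approximation). For a single ion the expression
#' reduces to the Born formula
#' `-(k_e/2) (1/eps_in - 1/eps_out) q^2 / a`.
#'
#' @param xyz Complex coordinates (`N x 3`).
#' @param charges Partial charges (e).
#' @param rho Intrinsic Born radii, Angstrom.
#' @param idx_A,idx_B Index split defining the two binding partners.
#' @param eps_in,eps_out Interior/solvent dielectric (defaults 2 / 80).
#' @param scale Descreening scale (see [effective_born_radii()]).
#' @param descreen If `FALSE`, use the intrinsic radii directly (exact
#'   closed-form checks).
#' @return A list with `dG` (kcal/mol), `per_atom` (length-N binding
#'   contributions summing to `dG`) and the per-state totals.
#' @export
gb_polar_energy <- function(xyz, charges, rho, idx_A, idx_B,
                            eps_in = 2, eps_out = 80, scale = 0.8,
                            descreen = TRUE) {
  if (any(rho <= 0)) abort("Born radii must be positive")
  xyz <- as.matrix(xyz)
  radii_of <- function(idx) {
    if (descreen) effective_born_radii(xyz[idx, , drop = FALSE], rho[idx], scale)
    else rho[idx]
  }
  all_idx <- sort(c(idx_A, idx_B))
  g_complex <- rep(0, nrow(xyz))
  g_complex[all_idx] <- gb_per_atom(xyz[all_idx, , drop = FALSE],
                                    charges[all_idx], radii_of(all_idx),
                                    eps_in, eps_out)
  g_free <- rep(0, nrow(xyz))
  for (idx in list(idx_A, idx_B)) {
    g_free[idx] <- gb_per_atom(xyz[idx, , drop = FALSE], charges[idx],
                               radii_of(idx), eps_in, eps_out)
  }
  per_atom <- g_complex - g_free
  list(
    dG = sum(per_atom[all_idx]),
    per_atom = per_atom,
    G_complex = sum(g_complex[all_idx]),
    G_A = sum(g_free[idx_A]),
    G_B = sum(g_free[idx_B])
  )
}

# Deterministic Fibonacci sphere directions.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (numerical rolling probe)
#'
#' Shrake-Rupley style: each atom's accessible sphere (radius + probe) is
#' sampled with a deterministic point set and points buried inside any
#' neighbour's accessible sphere are discarded.
#'
#' @param xyz Coordinate matrix.
#' @param radii Atomic radii, Angstrom.
#' @param probe Probe radius, Angstrom (default 1.4, water).
#' @param n_points Sphere points per atom (>= 960 recommended).
#' @return Per-atom SASA vector, Angstrom^2.
#' @export
sasa <- function(xyz, radii, probe = 1.4, n_points = 960) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  pts <- fibonacci_sphere(n_points)
  rr <- radii + probe
  out <- numeric(n)
  if (n > 1) d <- pair_distances(xyz, xyz)
  for (i in seq_len(n)) {
    sphere <- sweep(pts * rr[i], 2, xyz[i, ], `+`)
    exposed <- rep(TRUE, n_points)
    if (n > 1) {
      nb <- which(d[i, ] < rr[i] + rr & seq_len(n) != i)
      for (j in nb) {
        dj2 <- colSums((t(sphere) - xyz[j, ])^2)
        exposed <- exposed & dj2 > rr[j]^2
        if (!any(exposed)) break
      }
    }
    out[i] <- 4 * pi * rr[i]^2 * sum(exposed) / n_points
  }
  out
}

#' Nonpolar solvation energy of binding from buried surface area
#'
#' `DG_nonpolar = gamma * DSASA + beta` with
#' `DSASA = SASA(complex) - SASA(A) - SASA(B)`.
#'
#' @param xyz Complex coordinates.
#' @param radii Atomic radii, Angstrom.
#' @param idx_A,idx_B Binding-partner index split.
#' @param gamma Surface coefficient, kcal/(mol A^2) (default 0.0072).
#' @param beta Offset, kcal/mol (default 0).
#' @param probe,n_points Passed to [sasa()].
#' @return A list with `dG`, `per_atom` (gamma-weighted per-atom DSASA;
#'   beta is added to `dG` only) and `dSASA`.
#' @export
sasa_nonpolar <- function(xyz, radii, idx_A, idx_B, gamma = 0.0072, beta = 0,
                          probe = 1.4, n_points = 960) {
  xyz <- as.matrix(xyz)
  all_idx <- sort(c(idx_A, idx_B))
  s_complex <- rep(0, nrow(xyz))
  s_complex[all_idx] <- sasa(xyz[all_idx, , drop = FALSE], radii[all_idx],
                             probe, n_points)
  s_free <- rep(0, nrow(xyz))
  for (idx in list(idx_A, idx_B)) {
    s_free[idx] <- sasa(xyz[idx, , drop = FALSE], radii[idx], probe, n_points)
  }
  d_per_atom <- s_complex - s_free
  list(
    dG = gamma * sum(d_per_atom[all_idx]) + beta,
    per_atom = gamma * d_per_atom,
    dSASA = sum(d_per_atom[all_idx])
  )
}

#' Per-residue interface energy decomposition
#'
#' MM/GBSA-spirit decomposition over sampled frames with the
#' single-trajectory approximation (complex geometry reused for the
#' unbound states). Cross-interface Coulomb and Lennard-Jones pair terms
#' are split half-and-half between the two partners' residues; GB and
#' surface terms are apportioned per atom and summed per residue, so the
#' per-residue totals sum exactly to the complex totals every frame.
#'
#' @param traj An [md_trajectory()].
#' @param idx_A,idx_B Atom index split (e.g. protein side / DNA side).
#' @param params Parameter tibble covering all analysed atoms (see
#'   [read_ff_params()]).
#' @param stride Frame stride.
#' @param dielectric MM electrostatic dielectric (default 1).
#' @param eps_in,eps_out GB dielectrics (defaults 2 / 80).
#' @param gamma,beta Nonpolar surface model (defaults 0.0072, 0).
#' @param n_points SASA sphere points.
#' @param gb_descreen Use descreened effective radii (default TRUE).
#' @return A list with `by_residue` (tibble: residue label, means and SDs
#'   of `E_elec`, `E_vdw`, `E_polar`, `E_nonpolar`, `E_total`) and
#'   `totals` (tibble of per-frame totals).
#' @export
decompose_energy <- function(traj, idx_A, idx_B, params, stride = 1,
                             dielectric = 1, eps_in = 2, eps_out = 80,
                             gamma = 0.0072, beta = 0, n_points = 960,
                             gb_descreen = TRUE) {
  s <- traj$topology
  all_idx <- sort(c(idx_A, idx_B))
  pm <- match_params(s, params, all_idx)
  full <- tibble(charge = rep(0, nrow(s)), sigma = 0, epsilon = 0, born_radius = 1)
  full[all_idx, ] <- pm[, c("charge", "sigma", "epsilon", "born_radius")]
  res_key <- sprintf("%s:%s %d", s$chain, s$resid, s$resno)
  frames <- seq(1, n_frames(traj), by = stride)
  acc <- list()
  totals <- list()
  for (f in frames) {
    xyz <- frame_coords(traj, f)
    xa <- xyz[idx_A, , drop = FALSE]
    xb <- xyz[idx_B, , drop = FALSE]
    r <- pair_distances(xa, xb)
    if (any(r < 0.5)) abort(sprintf("atomic clash in frame %d", f))
    qa <- full$charge[idx_A]; qb <- full$charge[idx_B]
    elec_pair <- KE_KCAL * outer(qa, qb) / (dielectric * r)
    sig <- outer(full$sigma[idx_A], full$sigma[idx_B], function(a, b) (a + b) / 2)
    eps <- sqrt(outer(full$epsilon[idx_A], full$epsilon[idx_B]))
    sr6 <- (sig / r)^6
    vdw_pair <- 4 * eps * (sr6^2 - sr6)
    per_atom <- function(pair) {
      v <- rep(0, nrow(s))
      v[idx_A] <- v[idx_A] + rowSums(pair) / 2
      v[idx_B] <- v[idx_B] + colSums(pair) / 2
      v
    }
    elec_atom <- per_atom(elec_pair)
    vdw_atom <- per_atom(vdw_pair)
    gb <- gb_polar_energy(xyz, full$charge, full$born_radius, idx_A, idx_B,
                          eps_in, eps_out, descreen = gb_descreen)
    np <- sasa_nonpolar(xyz, full$born_radius, idx_A, idx_B, gamma, beta,
                        n_points = n_points)
    frame_tbl <- tibble(
      residue = res_key,
      E_elec = elec_atom, E_vdw = vdw_atom,
      E_polar = gb$per_atom, E_nonpolar = np$per_atom
    ) |>
      filter(seq_len(nrow(s)) %in% all_idx) |>
      group_by(.data$residue) |>
      summarise(across(dplyr::starts_with("E_"), sum), .groups = "drop") |>
      mutate(E_total = .data$E_elec + .data$E_vdw + .data$E_polar + .data$E_nonpolar)
    acc[[length(acc) + 1]] <- mutate(frame_tbl, frame = f)
    totals[[length(totals) + 1]] <- tibble(
      frame = f,
      E_elec = sum(elec_pair), E_vdw = sum(vdw_pair),
      E_polar = gb$dG, E_nonpolar = np$dG,
      E_total = sum(elec_pair) + sum(vdw_pair) + gb$dG + np$dG
    )
  }
  per_frame <- bind_rows(acc)
  by_residue <- per_frame |>
    group_by(.data$residue) |>
    summarise(
      across(dplyr::starts_with("E_"), list(mean = mean, sd = stats::sd)),
      .groups = "drop"
    )
  list(
    by_residue = by_residue,
    per_frame = per_frame,
    totals = bind_rows(totals)
  )
}
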