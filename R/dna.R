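# Idealized B-form fiber geometry. Base-pair frames are stacked with a
# 36 degree twist and 3.38 A rise; the second strand is the image of the
# first under the dyad (x, y, z) -> (x, -y, -z). Phosphate radius/phase and
# the C1'-C1' geometry follow published fiber values (P radius 9.4 A,
# C1'-C1' ~10.5 A); sugar atoms are placed schematically between C1' and P
# (the builder is intended for groove/axis/bend analysis, not for
# stereochemistry).
BDNA_RISE <- 3.38
BDNA_TWIST <- 36

bdna_backbone_template <- function() {
  # name, x, y, z in the bp frame (strand I); P geometry is load-bearing
  cyl <- function(name, r, phi_deg, z) {
    a <- phi_deg * pi / 180
    data.frame(name = name, x = r * cos(a), y = r * sin(a), z = z)
  }
  rbind(
    cyl("P", 9.4, 95.0, 2.08),
    cyl("O1P", 10.35, 99.5, 2.35),
    cyl("O2P", 9.75, 90.0, 3.25),
    cyl("O5'", 9.0, 87.0, 1.70),
    cyl("C5'", 8.6, 79.0, 1.20),
    cyl("C4'", 7.8, 72.0, 0.80),
    cyl("O4'", 6.6, 70.0, 0.90),
    cyl("C3'", 7.9, 65.0, -0.10),
    cyl("C2'", 6.9, 57.0, -0.30),
    cyl("O3'", 8.2, 60.0, -1.00),
    data.frame(name = "C1'", x = 2.68, y = 5.26, z = 0.25)
  )
}

bdna_base_template <- function(base) {
  pur <- rbind(
    c("N9", 2.35, 3.95, 0.15), c("C8", 4.15, 3.80, 0.12),
    c("N7", 3.90, 2.50, 0.10), c("C5", 2.70, 2.15, 0.08),
    c("C6", 2.30, 0.90, 0.05), c("N1", 1.00, 0.75, 0.05),
    c("C2", 0.15, 1.70, 0.05), c("N3", 0.55, 2.90, 0.10),
    c("C4", 1.70, 2.85, 0.10)
  )
  pyr <- rbind(
    c("N1", 2.35, 3.95, 0.15), c("C2", 1.35, 3.05, 0.10),
    c("O2", 0.30, 2.60, 0.10), c("N3", 1.65, 1.75, 0.08),
    c("C4", 2.90, 1.30, 0.05), c("C5", 3.95, 2.20, 0.08),
    c("C6", 3.65, 3.50, 0.12)
  )
  m <- switch(base,
    A = rbind(pur, c("N6", 3.15, 0.95, 0.0)),
    G = rbind(pur, c("O6", 3.00, 0.95, 0.0), c("N2", -0.70, 1.00, 0.05)),
    C = rbind(pyr, c("N4", 3.05, 2.20, 0.0)),
    T = rbind(pyr, c("O4", 3.05, 2.20, 0.0), c("C7", 5.30, 1.80, 0.08))
  )
  data.frame(name = m[, 1], x = as.numeric(m[, 2]),
             y = as.numeric(m[, 3]), z = as.numeric(m[, 4]))
}

complement_base <- function(b) c(A = "T", T = "A", G = "C", C = "G")[b]

#' Build an ideal B-form DNA duplex
#'
#' Generates both strands of a straight fiber-geometry duplex (rise 3.38
#' Angstrom, twist 36 degrees per base pair) for the given sequence; the
#' complementary strand is generated automatically, antiparallel, with
#' standard nucleotide atom names (`DA`/`DT`/`DG`/`DC` residues). The
#' 5'-terminal residue of each strand carries no phosphate group. Chain
#' `A` is the input strand (resno 1..n, 5' to 3'); chain `B` the
#' complement (its own 5' to 3' numbering).
#'
#' @param sequence A DNA string (ACGT, length >= 4).
#' @param rise Rise per bp, Angstrom.
#' @param twist Twist per bp, degrees.
#' @return An [md_structure()].
#' @export
build_bdna <- function(sequence, rise = BDNA_RISE, twist = BDNA_TWIST) {
  bases <- strsplit(toupper(sequence), "")[[1]]
  if (length(bases) < 4) abort("sequence must have length >= 4")
  if (!all(bases %in% c("A", "C", "G", "T"))) {
    abort(sprintf("invalid base '%s'; only ACGT supported",
                  setdiff(bases, c("A", "C", "G", "T"))[1]))
  }
  n <- length(bases)
  backbone <- bdna_backbone_template()
  helix_place <- function(tmpl, level, dyad) {
    xyz <- as.matrix(tmpl[, c("x", "y", "z")])
    if (dyad) xyz <- xyz %*% diag(c(1, -1, -1))
    a <- (level - 1) * twist * pi / 180
    rot <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
    xyz <- xyz %*% t(rot)
    xyz[, 3] <- xyz[, 3] + (level - 1) * rise
    xyz
  }
  rows <- list()
  add_res <- function(chain, resno, base, level, dyad, drop_p) {
    tmpl <- rbind(backbone, bdna_base_template(base))
    if (drop_p) tmpl <- tmpl[!tmpl$name %in% c("P", "O1P", "O2P"), ]
    xyz <- helix_place(tmpl, level, dyad)
    tibble(
      name = tmpl$name, resid = paste0("D", base), resno = resno,
      chain = chain, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
    )
  }
  for (i in seq_len(n)) {
    rows[[length(rows) + 1]] <-
      add_res("A", i, bases[i], level = i, dyad = FALSE, drop_p = i == 1)
  }
  for (j in seq_len(n)) {
    level <- n + 1 - j   # chain B resno j sits at bp level n+1-j
    rows[[length(rows) + 1]] <-
      add_res("B", j, unname(complement_base(bases[level])), level = level,
              dyad = TRUE, drop_p = j == 1)
  }
  at <- bind_rows(rows)
  at$serial <- seq_len(nrow(at))
  md_structure(at, title = sprintf("ideal B-DNA %d-mer", n))
}

#' Annotate a duplex for bp-level analysis
#'
#' Records which chains form the duplex, their paired residue ranges and
#' the bp pairing (a bijection; strands antiparallel). Pairing is
#' configuration, never inferred from geometry. The default pairs residue
#' `i` of the alpha strand with residue `n + 1 - i` of the beta strand.
#'
#' @param structure An [md_structure()] containing the duplex.
#' @param chain_alpha,chain_beta Chain ids of the two strands.
#' @param resno_alpha Ordered residue numbers of the alpha strand within
#'   the duplex (default: all residues of the chain).
#' @param resno_beta Ordered residue numbers of the beta strand pairing
#'   with `resno_alpha` level by level (default: reverse order of the
#'   chain's residues).
#' @return A `duplex_annotation` object with a `pairing` tibble
#'   (`level`, `resno_alpha`, `resno_beta`).
#' @export
duplex_annotation <- function(structure, chain_alpha = "A", chain_beta = "B",
                              resno_alpha = NULL, resno_beta = NULL) {
  ra <- resno_alpha %||% sort(unique(structure$resno[structure$chain == chain_alpha]))
  rb <- resno_beta %||% rev(sort(unique(structure$resno[structure$chain == chain_beta])))
  if (length(ra) != length(rb)) abort("strand ranges differ in length; pairing must be a bijection")
  if (length(ra) < 4) abort("need at least 4 bp levels")
  structure(
    list(
      chain_alpha = chain_alpha, chain_beta = chain_beta,
      pairing = tibble(level = seq_along(ra), resno_alpha = ra, resno_beta = rb)
    ),
    class = "duplex_annotation"
  )
}

# C1' midpoints per bp level; NA rows where a C1' is missing.
bp_midpoints <- function(structure, annotation, xyz) {
  pr <- annotation$pairing
  n <- nrow(pr)
  mids <- matrix(NA_real_, n, 3)
  basis <- matrix(NA_real_, n, 3)  # bp vector C1'(alpha) - C1'(beta)
  for (k in seq_len(n)) {
    ia <- which(structure$chain == annotation$chain_alpha &
                  structure$resno == pr$resno_alpha[k] & structure$name == "C1'")
    ib <- which(structure$chain == annotation$chain_beta &
                  structure$resno == pr$resno_beta[k] & structure$name == "C1'")
    if (length(ia) == 1 && length(ib) == 1) {
      mids[k, ] <- (xyz[ia, ] + xyz[ib, ]) / 2
      basis[k, ] <- xyz[ia, ] - xyz[ib, ]
    }
  }
  list(mids = mids, basis = basis)
}

# Global twist estimate (degrees/level) from bp vectors projected
# perpendicular to the local chord; falls back to the fiber value.
estimate_twist <- function(mids, basis) {
  n <- nrow(mids)
  angs <- c()
  for (k in seq_len(n - 1)) {
    if (anyNA(mids[k, ]) || anyNA(mids[k + 1, ]) ||
        anyNA(basis[k, ]) || anyNA(basis[k + 1, ])) next
    # chord over ~one helical turn so the midpoint wobble cancels
    t0 <- mids[min(k + 5, n), ] - mids[max(k - 5, 1), ]
    if (anyNA(t0) || sum(t0^2) == 0) next
    t0 <- t0 / sqrt(sum(t0^2))
    perp <- function(v) v - sum(v * t0) * t0
    b1 <- perp(basis[k, ]); b2 <- perp(basis[k + 1, ])
    if (sum(b1^2) == 0 || sum(b2^2) == 0) next
    angs <- c(angs, vector_angle(b1, b2))
  }
  if (length(angs) == 0) BDNA_TWIST else stats::median(angs)
}

#' Estimate the helical axis of a duplex
#'
#' A simplified Curves-style axis: per-level C1' midpoints carry a helical
#' wobble about the true axis, which is removed by a local least-squares
#' fit of a straight-line-plus-one-harmonic model (window of 5 levels,
#' twist estimated from the data) evaluated at each level. Tangents are
#' smoothed finite differences (window 3), unit norm. Absolute bend values
#' from any axis definition are convention-dependent; this one reproduces
#' bp-level groove/bend trends at desk scale.
#'
#' @param structure An [md_structure()] (topology).
#' @param annotation A [duplex_annotation()].
#' @param xyz Optional replacement coordinates (`N x 3`).
#' @return A tibble with `level`, axis point (`x`, `y`, `z`), unit tangent
#'   (`tx`, `ty`, `tz`) and `flagged` (levels lacking C1' atoms).
#' @export
fit_axis <- function(structure, annotation, xyz = NULL) {
  xyz <- xyz %||% coords(structure)
  bp <- bp_midpoints(structure, annotation, xyz)
  mids <- bp$mids
  n <- nrow(mids)
  if (n < 4) abort("need at least 4 bp levels")
  flagged <- apply(mids, 1, anyNA)
  if (all(flagged)) abort("no bp level has both C1' atoms")
  theta <- estimate_twist(mids, bp$basis) * pi / 180
  ok <- which(!flagged)
  axis_pts <- matrix(NA_real_, n, 3)
  W <- 7
  for (k in seq_len(n)) {
    # window of W usable levels nearest to k; the local model is
    # quadratic-in-level plus one helical harmonic, so clamped edge
    # windows still follow a smoothly curved axis when extrapolating
    win <- ok[order(abs(ok - k))]
    win <- sort(utils::head(win, max(W, 4)))
    if (length(win) < 4) next
    c0 <- mean(win)
    u <- win - c0
    X <- cbind(1, u, cos(theta * win), sin(theta * win))
    if (length(win) >= 6) X <- cbind(X, u^2)
    beta <- tryCatch(qr.solve(X, mids[win, , drop = FALSE]),
                     error = function(e) NULL)
    if (is.null(beta)) next
    axis_pts[k, ] <- beta[1, ] + (k - c0) * beta[2, ] +
      if (ncol(X) == 5) (k - c0)^2 * beta[5, ] else 0
  }
  miss <- apply(axis_pts, 1, anyNA)
  tang <- matrix(NA_real_, n, 3)
  raw <- matrix(NA_real_, n, 3)
  for (k in seq_len(n)) {
    lo <- max(1, k - 1); hi <- min(n, k + 1)
    if (miss[lo] || miss[hi] || lo == hi) next
    raw[k, ] <- axis_pts[hi, ] - axis_pts[lo, ]
  }
  have_raw <- which(!apply(raw, 1, anyNA))
  for (k in seq_len(n)) {
    if (k == 1 || k == n) {
      # one-sided chord at the termini; symmetric smoothing would bias
      # the end tangents inward on a curved axis
      a <- if (k == 1) 1 else n - 1
      b <- a + 1
      if (miss[a] || miss[b]) next
      v <- axis_pts[b, ] - axis_pts[a, ]
    } else {
      nb <- intersect((k - 1):(k + 1), have_raw)
      if (length(nb) == 0) next
      v <- colMeans(raw[nb, , drop = FALSE])
    }
    if (sum(v^2) == 0) next
    tang[k, ] <- v / sqrt(sum(v^2))
  }
  tibble(
    level = seq_len(n),
    x = axis_pts[, 1], y = axis_pts[, 2], z = axis_pts[, 3],
    tx = tang[, 1], ty = tang[, 2], tz = tang[, 3],
    flagged = flagged | miss | apply(tang, 1, anyNA)
  )
}

# Groove register windows (bp-level offset of the beta-strand phosphate
# relative to the alpha-strand phosphate at the same level). With the
# builder's strand convention the minor-groove cross-strand contact sits
# around offset +4 and the major-groove contact around offset -3; the
# windows below scan the standard register span on either side and take
# the minimum distance.
GROOVE_MINOR_OFFSETS <- 2:6
GROOVE_MAJOR_OFFSETS <- -7:-1
GROOVE_BACKBONE_CORRECTION <- 5.8

#' Major and minor groove widths per bp level
#'
#' Widths are minimal cross-strand phosphate-phosphate distances within the
#' groove-appropriate register window, minus the conventional 5.8 Angstrom
#' backbone correction. The terminal two levels at each end are flagged
#' undefined (missing phosphates / incomplete register).
#'
#' @param structure An [md_structure()].
#' @param annotation A [duplex_annotation()].
#' @param xyz Optional replacement coordinates.
#' @return A tibble with `level`, `label` (`"i/j"` in the two strands'
#'   numbering), `major`, `minor` (Angstrom; `NA` where undefined).
#' @export
groove_widths <- function(structure, annotation, xyz = NULL) {
  xyz <- xyz %||% coords(structure)
  pr <- annotation$pairing
  n <- nrow(pr)
  p_of <- function(chain, resno) {
    i <- which(structure$chain == chain & structure$resno == resno &
                 structure$name == "P")
    if (length(i) == 1) xyz[i, ] else c(NA_real_, NA_real_, NA_real_)
  }
  p_alpha <- t(vapply(pr$resno_alpha, function(r) p_of(annotation$chain_alpha, r),
                      numeric(3)))
  p_beta <- t(vapply(pr$resno_beta, function(r) p_of(annotation$chain_beta, r),
                     numeric(3)))
  width_at <- function(k, offsets) {
    if (anyNA(p_alpha[k, ])) return(NA_real_)
    js <- k + offsets
    js <- js[js >= 1 & js <= n]
    if (length(js) == 0) return(NA_real_)
    d <- sqrt(rowSums((p_beta[js, , drop = FALSE] -
                         matrix(p_alpha[k, ], length(js), 3, byrow = TRUE))^2))
    d <- d[!is.na(d)]
    # an incomplete register window (ends of the duplex) cannot bracket
    # the true cross-strand contact; flag rather than overestimate
    if (length(d) < 3) return(NA_real_)
    max(min(d) - GROOVE_BACKBONE_CORRECTION, 0)
  }
  major <- vapply(seq_len(n), width_at, numeric(1), offsets = GROOVE_MAJOR_OFFSETS)
  minor <- vapply(seq_len(n), width_at, numeric(1), offsets = GROOVE_MINOR_OFFSETS)
  edge <- c(1, 2, n - 1, n)
  major[edge] <- NA_real_
  minor[edge] <- NA_real_
  tibble(
    level = pr$level,
    label = sprintf("%d/%d", pr$resno_alpha, pr$resno_beta),
    major = major, minor = minor
  )
}

#' Axis bend per bp level
#'
#' Bend at level `k` is the angle between the axis tangents at levels
#' `k - window` and `k + window`, in degrees. Levels without both flanking
#' tangents are `NA`.
#'
#' @param axis Output of [fit_axis()].
#' @param window Half-window in levels (>= 1).
#' @return A tibble with `level`, `bend` (degrees), `window`.
#' @export
axis_bend <- function(axis, window = 1) {
  if (window < 1) abort("`window` must be >= 1")
  n <- nrow(axis)
  tang <- cbind(axis$tx, axis$ty, axis$tz)
  bend <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    lo <- k - window; hi <- k + window
    if (lo < 1 || hi > n) next
    if (anyNA(tang[lo, ]) || anyNA(tang[hi, ])) next
    bend[k] <- vector_angle(tang[lo, ], tang[hi, ])
  }
  tibble(level = axis$level, bend = bend, window = window)
}

#' Groove and bend profiles over a trajectory
#'
#' Computes per-level groove widths and axis bends on sampled frames and
#' reports their means and standard deviations.
#'
#' @param traj An [md_trajectory()].
#' @param annotation A [duplex_annotation()].
#' @param every Frame stride (>= 1), e.g. every 5th frame for snapshots
#'   spaced 10 ps when `dt = 2` ps.
#' @param window Bend half-window in levels.
#' @return A list with tibbles `grooves` (`level`, `label`, `major_mean`,
#'   `major_sd`, `minor_mean`, `minor_sd`) and `bend` (`level`,
#'   `bend_mean`, `bend_sd`), plus `n_frames_used`.
#' @export
profile_over_trajectory <- function(traj, annotation, every = 1, window = 1) {
  if (every < 1) abort("`every` must be >= 1")
  frames <- seq(1, n_frames(traj), by = every)
  s <- traj$topology
  gw_list <- vector("list", length(frames))
  bd_list <- vector("list", length(frames))
  for (f in seq_along(frames)) {
    xyz <- frame_coords(traj, frames[f])
    gw_list[[f]] <- groove_widths(s, annotation, xyz)
    bd_list[[f]] <- axis_bend(fit_axis(s, annotation, xyz), window)
  }
  col_stats <- function(lst, col) {
    m <- vapply(lst, function(d) d[[col]], numeric(nrow(lst[[1]])))
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
    list(mean = rowMeans(m, na.rm = TRUE),
         sd = apply(m, 1, stats::sd, na.rm = TRUE))
  }
  g1 <- gw_list[[1]]
  maj <- col_stats(gw_list, "major")
  mino <- col_stats(gw_list, "minor")
  bd <- col_stats(bd_list, "bend")
  list(
    grooves = tibble(
      level = g1$level, label = g1$label,
      major_mean = maj$mean, major_sd = maj$sd,
      minor_mean = mino$mean, minor_sd = mino$sd
    ),
    bend = tibble(level = g1$level, bend_mean = bd$mean, bend_sd = bd$sd,
                  window = window),
    n_frames_used = length(frames)
  )
}
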