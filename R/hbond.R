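#' Hydrogen-bond detection criteria
#'
#' Defaults follow common practice for protein-DNA interface analysis: a
#' donor-heavy-atom to acceptor-heavy-atom distance cutoff of 3.5 Angstrom
#' and an angle cutoff of 45 degrees. Two angle conventions are supported:
#' `"DHA-deviation"` (deviation of the donor-hydrogen-acceptor angle from
#' 180 degrees must not exceed the cutoff; the default) and `"HDA"` (the
#' hydrogen-donor-acceptor angle itself must not exceed the cutoff).
#'
#' @param distance_cut Heavy-atom distance cutoff, Angstrom (> 0).
#' @param angle_cut Angle cutoff, degrees (0 < cut <= 90).
#' @param angle_convention `"DHA-deviation"` or `"HDA"`.
#' @return An `hbond_criteria` object.
#' @export
hbond_criteria <- function(distance_cut = 3.5, angle_cut = 45,
                           angle_convention = c("DHA-deviation", "HDA")) {
  if (distance_cut <= 0) abort("`distance_cut` must be positive")
  if (angle_cut <= 0 || angle_cut > 90) abort("`angle_cut` must be in (0, 90]")
  structure(
    list(distance_cut = distance_cut, angle_cut = angle_cut,
         angle_convention = match.arg(angle_convention)),
    class = "hbond_criteria"
  )
}

#' Donor/acceptor chemistry table
#'
#' Which N/O (and S) atoms donate or accept per residue and nucleotide,
#' shipped as editable data (`inst/extdata/donor_acceptor.tsv`) so the
#' package needs no bond topology. `resid = "*"` rows apply to every
#' residue (backbone atoms).
#'
#' @param path Optional path to an alternative table.
#' @return A tibble with `resid`, `name`, `donor`, `acceptor`.
#' @export
hbond_chemistry <- function(path = NULL) {
  path <- path %||% system.file("extdata", "donor_acceptor.tsv", package = "mdtidy")
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE) |>
    as_tibble() |>
    mutate(donor = as.logical(.data$donor), acceptor = as.logical(.data$acceptor))
}

# Classify structure atoms as donors/acceptors using the chemistry table.
# Returns the structure row indices; unknown residues fall back to the
# polar-element heuristic (N donates and accepts, O accepts; O with an
# attached hydrogen also donates).
polar_roles <- function(structure, chemistry = hbond_chemistry()) {
  resid <- toupper(structure$resid)
  key <- paste(resid, toupper(structure$name))
  tab_specific <- chemistry[chemistry$resid != "*", ]
  tab_generic <- chemistry[chemistry$resid == "*", ]
  spec_key <- paste(toupper(tab_specific$resid), toupper(tab_specific$name))
  gen_names <- toupper(tab_generic$name)
  m_spec <- match(key, spec_key)
  m_gen <- match(toupper(structure$name), gen_names)
  known_res <- resid %in% toupper(tab_specific$resid) | structure$is_water
  donor <- rep(FALSE, nrow(structure))
  acceptor <- rep(FALSE, nrow(structure))
  hit <- !is.na(m_spec)
  donor[hit] <- tab_specific$donor[m_spec[hit]]
  acceptor[hit] <- tab_specific$acceptor[m_spec[hit]]
  ghit <- is.na(m_spec) & !is.na(m_gen)
  donor[ghit] <- tab_generic$donor[m_gen[ghit]]
  acceptor[ghit] <- tab_generic$acceptor[m_gen[ghit]]
  # water oxygen both donates and accepts
  wat_o <- structure$is_water & toupper(structure$element) == "O"
  donor[wat_o] <- TRUE
  acceptor[wat_o] <- TRUE
  # heuristic for residues absent from the table
  unk <- !known_res & !structure$is_water & is.na(m_spec) & is.na(m_gen)
  donor[unk & toupper(structure$element) == "N"] <- TRUE
  acceptor[unk & toupper(structure$element) %in% c("N", "O")] <- TRUE
  list(donor = which(donor & !structure$is_hydrogen),
       acceptor = which(acceptor & !structure$is_hydrogen))
}

# Attach hydrogens to donor heavy atoms: a hydrogen in the same residue
# within 1.25 Angstrom of the donor heavy atom is considered bound to it.
donor_hydrogens <- function(structure, xyz, donor_idx) {
  h_idx <- which(structure$is_hydrogen)
  if (length(h_idx) == 0 || length(donor_idx) == 0) {
    return(tibble(donor = integer(), hydrogen = integer()))
  }
  out_d <- integer(0)
  out_h <- integer(0)
  res_key <- paste(structure$chain, structure$resno, structure$resid)
  for (d in donor_idx) {
    cand <- h_idx[res_key[h_idx] == res_key[d]]
    if (length(cand) == 0) next
    dd <- sqrt(colSums((t(xyz[cand, , drop = FALSE]) - xyz[d, ])^2))
    near <- cand[dd > 0 & dd <= 1.25]
    out_d <- c(out_d, rep(d, length(near)))
    out_h <- c(out_h, near)
  }
  tibble(donor = out_d, hydrogen = out_h)
}

# Core geometric test for one frame. donors: integer indices of donor heavy
# atoms; acceptors: integer indices. Returns one row per satisfied
# (donor, acceptor) pair (the best hydrogen is reported).
detect_hbonds_frame <- function(structure, xyz, donors, acceptors,
                                criteria = hbond_criteria(),
                                heavy_only = NULL, dh = NULL) {
  empty <- tibble(donor = integer(), hydrogen = integer(), acceptor = integer(),
                  distance = double(), angle = double(), heavy_only = logical())
  donors <- donors[!structure$is_hydrogen[donors]]
  acceptors <- acceptors[!structure$is_hydrogen[acceptors]]
  if (length(donors) == 0 || length(acceptors) == 0) return(empty)
  if (is.null(dh)) dh <- donor_hydrogens(structure, xyz, donors)
  if (is.null(heavy_only)) heavy_only <- nrow(dh) == 0
  dmat <- xyz[donors, , drop = FALSE]
  amat <- xyz[acceptors, , drop = FALSE]
  d2 <- outer(rowSums(dmat^2), rep(1, nrow(amat))) +
    outer(rep(1, nrow(dmat)), rowSums(amat^2)) - 2 * dmat %*% t(amat)
  d2[d2 < 0] <- 0
  hits <- which(d2 <= criteria$distance_cut^2, arr.ind = TRUE)
  if (nrow(hits) == 0) return(empty)
  rows <- list()
  for (r in seq_len(nrow(hits))) {
    d <- donors[hits[r, 1]]
    a <- acceptors[hits[r, 2]]
    if (d == a) next
    dist <- sqrt(d2[hits[r, 1], hits[r, 2]])
    if (heavy_only) {
      rows[[length(rows) + 1]] <- tibble(
        donor = d, hydrogen = NA_integer_, acceptor = a,
        distance = dist, angle = NA_real_, heavy_only = TRUE
      )
      next
    }
    hs <- dh$hydrogen[dh$donor == d]
    if (length(hs) == 0) next
    best <- NULL
    for (h in hs) {
      ang <- switch(criteria$angle_convention,
        "DHA-deviation" = 180 - vector_angle(xyz[d, ] - xyz[h, ], xyz[a, ] - xyz[h, ]),
        "HDA" = vector_angle(xyz[h, ] - xyz[d, ], xyz[a, ] - xyz[d, ])
      )
      if (ang <= criteria$angle_cut && (is.null(best) || ang < best$angle)) {
        best <- list(hydrogen = h, angle = ang)
      }
    }
    if (!is.null(best)) {
      rows[[length(rows) + 1]] <- tibble(
        donor = d, hydrogen = best$hydrogen, acceptor = a,
        distance = dist, angle = best$angle, heavy_only = FALSE
      )
    }
  }
  if (length(rows) == 0) empty else bind_rows(rows)
}

vector_angle <- function(u, v) {
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(min(max(cosang, -1), 1)) * 180 / pi
}

#' Find hydrogen bonds in a single structure or frame
#'
#' A pair is reported iff the donor-acceptor heavy-atom distance is within
#' `distance_cut` and the configured angle criterion is within `angle_cut`
#' for some hydrogen bound to the donor. Structures without hydrogens (e.g.
#' crystal structures) are analysed in heavy-atom-only mode (distance
#' criterion only), flagged in the output column `heavy_only`.
#'
#' @param structure An [md_structure()].
#' @param donors,acceptors Integer atom indices of candidate donor and
#'   acceptor heavy atoms (see [interface_pairs()]); defaults to all polar
#'   atoms classified by [hbond_chemistry()].
#' @param criteria An [hbond_criteria()].
#' @param xyz Optional replacement coordinates (`N x 3`).
#' @return A tibble with `donor`, `hydrogen`, `acceptor` (atom indices),
#'   `donor_label`, `acceptor_label`, `distance`, `angle`, `heavy_only`.
#' @export
find_hbonds <- function(structure, donors = NULL, acceptors = NULL,
                        criteria = hbond_criteria(), xyz = NULL) {
  xyz <- xyz %||% coords(structure)
  if (is.null(donors) || is.null(acceptors)) {
    roles <- polar_roles(structure)
    donors <- donors %||% roles$donor
    acceptors <- acceptors %||% roles$acceptor
  }
  dh <- donor_hydrogens(structure, xyz, donors)
  heavy_only <- nrow(dh) == 0
  if (heavy_only && any(structure$is_hydrogen)) {
    warn("donors carry no resolvable hydrogens; falling back to heavy-atom-only mode")
  }
  out <- detect_hbonds_frame(structure, xyz, donors, acceptors, criteria,
                             heavy_only = heavy_only, dh = dh)
  out$donor_label <- atom_labels(structure[out$donor, ])
  out$acceptor_label <- atom_labels(structure[out$acceptor, ])
  select(out, "donor", "hydrogen", "acceptor", "donor_label", "acceptor_label",
         "distance", "angle", "heavy_only")
}

#' Find water-mediated bridges in a single frame
#'
#' A bridge `(a in A, b in B, w)` is reported iff one water `w` forms a
#' hydrogen bond (in either polarity) with `a` and with `b` within the same
#' frame.
#'
#' @param structure An [md_structure()] containing waters.
#' @param set_A,set_B Integer atom indices of the two interface sides
#'   (polar heavy atoms).
#' @param criteria An [hbond_criteria()].
#' @param xyz Optional replacement coordinates.
#' @return A tibble with `atom_a`, `atom_b`, `water` (O atom index), labels,
#'   and `bridge = TRUE`.
#' @export
find_water_bridges <- function(structure, set_A, set_B,
                               criteria = hbond_criteria(), xyz = NULL) {
  xyz <- xyz %||% coords(structure)
  wat_o <- which(structure$is_water & toupper(structure$element) == "O")
  empty <- tibble(atom_a = integer(), atom_b = integer(), water = integer(),
                  label_a = character(), label_b = character(),
                  water_label = character(), bridge = logical())
  if (length(wat_o) == 0) return(empty)
  bonded <- function(set) {
    # water-to-set bonds in either polarity
    b1 <- detect_hbonds_frame(structure, xyz, donors = set, acceptors = wat_o, criteria)
    b2 <- detect_hbonds_frame(structure, xyz, donors = wat_o, acceptors = set, criteria)
    unique(rbind(
      cbind(atom = b1$donor, water = b1$acceptor),
      cbind(atom = b2$acceptor, water = b2$donor)
    ))
  }
  ba <- bonded(set_A)
  bb <- bonded(set_B)
  if (is.null(dim(ba)) || is.null(dim(bb)) || nrow(ba) == 0 || nrow(bb) == 0) return(empty)
  rows <- list()
  for (w in intersect(ba[, "water"], bb[, "water"])) {
    for (a in ba[ba[, "water"] == w, "atom"]) {
      for (b in bb[bb[, "water"] == w, "atom"]) {
        if (a == b) next
        rows[[length(rows) + 1]] <- tibble(atom_a = a, atom_b = b, water = w)
      }
    }
  }
  if (length(rows) == 0) return(empty)
  out <- bind_rows(rows)
  out$label_a <- atom_labels(structure[out$atom_a, ])
  out$label_b <- atom_labels(structure[out$atom_b, ])
  out$water_label <- atom_labels(structure[out$water, ])
  out$bridge <- TRUE
  out
}

#' Candidate donor/acceptor sets across an interface
#'
#' Partitions polar heavy atoms (N, O per the chemistry table) by interface
#' side so only cross-side pairs are ever tested.
#'
#' @param structure An [md_structure()].
#' @param map A [subunit_map()].
#' @param group_A,group_B Character vectors of logical subunit names.
#' @param chemistry A chemistry table from [hbond_chemistry()].
#' @return A list with `donors_A`, `acceptors_A`, `donors_B`, `acceptors_B`
#'   (atom index vectors) and `idx_A`, `idx_B` (all polar atoms per side).
#' @export
interface_pairs <- function(structure, map, group_A, group_B,
                            chemistry = hbond_chemistry()) {
  chains_A <- subunit_chains(map, group_A)
  chains_B <- subunit_chains(map, group_B)
  roles <- polar_roles(structure, chemistry)
  side <- function(chains, which_set) {
    keep <- which(structure$chain %in% chains)
    out <- intersect(roles[[which_set]], keep)
    out
  }
  res <- list(
    donors_A = side(chains_A, "donor"),
    acceptors_A = side(chains_A, "acceptor"),
    donors_B = side(chains_B, "donor"),
    acceptors_B = side(chains_B, "acceptor")
  )
  res$idx_A <- sort(union(res$donors_A, res$acceptors_A))
  res$idx_B <- sort(union(res$donors_B, res$acceptors_B))
  if (length(res$idx_A) == 0) warn("group A contains no polar atoms")
  if (length(res$idx_B) == 0) warn("group B contains no polar atoms")
  res
}

#' Hydrogen-bond occupancy over a trajectory
#'
#' For every (donor, acceptor, bridge) pair the fraction of analysed frames
#' in which the bond is present. Direct bonds are evaluated in both
#' polarities across the interface; water bridges (optional) require
#' simultaneous bonds to the same water within a frame.
#'
#' @param traj An [md_trajectory()].
#' @param set_A,set_B Atom index vectors for the two interface sides, or a
#'   list from [interface_pairs()].
#' @param criteria An [hbond_criteria()].
#' @param min_occupancy Rows below this fraction are dropped (default 0.20).
#' @param bridges Also detect water-mediated bridges (default TRUE when the
#'   topology contains water).
#' @param stride Analyse every `stride`-th frame.
#' @return A tibble with `donor_label`, `acceptor_label`, `bridge`,
#'   `n_present`, `n_frames`, `occupancy`, sorted by decreasing occupancy.
#' @export
hbond_occupancy <- function(traj, set_A, set_B, criteria = hbond_criteria(),
                            min_occupancy = 0.20, bridges = NULL, stride = 1) {
  s <- traj$topology
  if (is.list(set_A) && !is.null(set_A$idx_A)) {
    pairs <- set_A
  } else {
    roles <- polar_roles(s)
    pairs <- list(
      donors_A = intersect(roles$donor, set_A),
      acceptors_A = intersect(roles$acceptor, set_A),
      donors_B = intersect(roles$donor, set_B),
      acceptors_B = intersect(roles$acceptor, set_B),
      idx_A = set_A, idx_B = set_B
    )
  }
  bridges <- bridges %||% any(s$is_water)
  frames <- seq(1, n_frames(traj), by = stride)
  tally <- new.env(parent = emptyenv())
  bump <- function(key) {
    assign(key, (get0(key, envir = tally) %||% 0L) + 1L, envir = tally)
  }
  for (k in frames) {
    xyz <- frame_coords(traj, k)
    direct <- bind_rows(
      detect_hbonds_frame(s, xyz, pairs$donors_A, pairs$acceptors_B, criteria),
      detect_hbonds_frame(s, xyz, pairs$donors_B, pairs$acceptors_A, criteria)
    )
    if (nrow(direct) > 0) {
      keys <- paste0(direct$donor, "|", direct$acceptor, "|direct")
      for (key in unique(keys)) bump(key)
    }
    if (bridges) {
      br <- find_water_bridges(s, pairs$idx_A, pairs$idx_B, criteria, xyz = xyz)
      if (nrow(br) > 0) {
        keys <- paste0(br$atom_a, "|", br$atom_b, "|bridge")
        for (key in unique(keys)) bump(key)
      }
    }
  }
  keys <- ls(tally)
  nf <- length(frames)
  if (length(keys) == 0) {
    return(tibble(donor_label = character(), acceptor_label = character(),
                  bridge = logical(), n_present = integer(),
                  n_frames = integer(), occupancy = double()))
  }
  parts <- strsplit(keys, "|", fixed = TRUE)
  out <- tibble(
    a = as.integer(map_chr(parts, 1)),
    b = as.integer(map_chr(parts, 2)),
    bridge = map_chr(parts, 3) == "bridge",
    n_present = map_int(keys, function(k) get(k, envir = tally)),
    n_frames = nf
  ) |>
    mutate(
      occupancy = .data$n_present / .data$n_frames,
      donor_label = atom_labels(s[.data$a, ]),
      acceptor_label = atom_labels(s[.data$b, ])
    ) |>
    filter(.data$occupancy >= min_occupancy) |>
    arrange(dplyr::desc(.data$occupancy)) |>
    select("donor_label", "acceptor_label", "bridge", "n_present",
           "n_frames", "occupancy")
  out
}

#' Write an occupancy table as TSV
#'
#' Mirrors the usual interface-table layout: donor subunit, donor label,
#' acceptor label, strand tag, bridge flag and occupancy percentage.
#'
#' @param table Output of [hbond_occupancy()].
#' @param structure The topology (for chain-to-subunit resolution).
#' @param map Optional [subunit_map()] for subunit and strand tags.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_occupancy_tsv <- function(table, structure = NULL, map = NULL, path) {
  tag_for <- function(label) {
    if (is.null(map)) return(NA_character_)
    chain <- sub(":.*$", "", label)
    for (nm in names(map)) if (chain %in% map[[nm]]) return(nm)
    NA_character_
  }
  out <- table |>
    mutate(
      donor_subunit = map_chr(.data$donor_label, tag_for),
      acceptor_subunit = map_chr(.data$acceptor_label, tag_for),
      occupancy_pct = sprintf("%.2f%%", 100 * .data$occupancy)
    ) |>
    select("donor_subunit", "donor_label", "acceptor_label",
           "acceptor_subunit", "bridge", "occupancy_pct")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
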