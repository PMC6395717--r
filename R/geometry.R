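#' Angle defined by three points
#'
#' @param p1,p2,p3 Numeric 3-vectors; the vertex is `p2`.
#' @return Angle at `p2` in degrees, in `[0, 180]`.
#' @export
three_point_angle <- function(p1, p2, p3) {
  u <- p1 - p2
  v <- p3 - p2
  if (sum(u^2) == 0 || sum(v^2) == 0) abort("coincident points; angle undefined")
  vector_angle(u, v)
}

#' Specify a point for an angle definition
#'
#' A point is either a single atom or the unweighted geometric centre of a
#' selection, optionally restricted to logical subunits (resolved through a
#' [subunit_map()] at evaluation time).
#'
#' @param kind `"atom"` (selection must resolve to exactly one atom) or
#'   `"center"` (geometric centre of all selected atoms).
#' @param selection An [atom_selection()].
#' @param subunit Optional character vector of logical subunit names whose
#'   chains further restrict the selection.
#' @return A `point_spec` object.
#' @export
point_spec <- function(kind = c("atom", "center"), selection = atom_selection(),
                       subunit = NULL) {
  structure(
    list(kind = match.arg(kind), selection = selection, subunit = subunit),
    class = "point_spec"
  )
}

# Resolve a point spec to atom indices on a structure.
resolve_point <- function(structure, spec, map = NULL, label = "point") {
  sel <- spec$selection
  if (!is.null(spec$subunit)) {
    if (is.null(map)) abort(sprintf("%s references subunits but no subunit_map given", label))
    chains <- subunit_chains(map, spec$subunit)
    sel$chain <- if (is.null(sel$chain)) chains else intersect(sel$chain, chains)
  }
  idx <- select_atoms(structure, sel, warn_empty = FALSE)
  if (length(idx) == 0) abort(sprintf("%s resolves to no atoms", label))
  if (spec$kind == "atom" && length(idx) != 1) {
    abort(sprintf("%s is ambiguous: %d atoms match a single-atom point", label, length(idx)))
  }
  idx
}

point_position <- function(xyz, idx) {
  if (length(idx) == 1) xyz[idx, ] else colMeans(xyz[idx, , drop = FALSE])
}

#' Define a named three-point angle
#'
#' @param name Angle name (`"alpha"`, `"beta"`, `"gamma"` or user-defined).
#' @param p1,p2,p3 [point_spec()] objects; the vertex is `p2`.
#' @return An `angle_definition` object.
#' @export
angle_definition <- function(name, p1, p2, p3) {
  structure(list(name = name, points = list(p1, p2, p3)),
            class = "angle_definition")
}

#' Shipped angle definitions for the Cas1-Cas2 heterohexamer
#'
#' `alpha` monitors the open-close motion of one Cas1a-Cas2'-Cas1b' (or
#' primed) surface: Cα of Glu121 in Cas1a, the geometric centre of Cas2',
#' Cα of Arg245 in Cas1b' (and symmetrically for the primed surface).
#' `beta` monitors the Cas1-dimer rotation: Cα of Glu155 in Cas1a', centre
#' of the whole Cas2 dimer, Cα of Glu155 in Cas1a. Geometric centres use
#' all atoms of the subunit by default; set `center_atoms = "CA"` for
#' Cα-only centres (the two conventions differ by under ~2 degrees on
#' compact domains).
#'
#' @param surface For `alpha`: `"unprimed"` uses Cas1a/Cas2'/Cas1b',
#'   `"primed"` uses Cas1a'/Cas2/Cas1b.
#' @param center_atoms `"all"` or `"CA"`.
#' @return An `angle_definition`.
#' @export
alpha_definition <- function(surface = c("unprimed", "primed"),
                             center_atoms = c("all", "CA")) {
  surface <- match.arg(surface)
  center_atoms <- match.arg(center_atoms)
  csel <- if (center_atoms == "CA") atom_selection(name = "CA") else
    atom_selection(water = FALSE, hydrogen = FALSE)
  if (surface == "unprimed") {
    angle_definition(
      "alpha",
      point_spec("atom", atom_selection(name = "CA", resno = 121), subunit = "Cas1a"),
      point_spec("center", csel, subunit = "Cas2p"),
      point_spec("atom", atom_selection(name = "CA", resno = 245), subunit = "Cas1bp")
    )
  } else {
    angle_definition(
      "alpha",
      point_spec("atom", atom_selection(name = "CA", resno = 121), subunit = "Cas1ap"),
      point_spec("center", csel, subunit = "Cas2"),
      point_spec("atom", atom_selection(name = "CA", resno = 245), subunit = "Cas1b")
    )
  }
}

#' @rdname alpha_definition
#' @export
beta_definition <- function(center_atoms = c("all", "CA")) {
  center_atoms <- match.arg(center_atoms)
  csel <- if (center_atoms == "CA") atom_selection(name = "CA") else
    atom_selection(water = FALSE, hydrogen = FALSE)
  angle_definition(
    "beta",
    point_spec("atom", atom_selection(name = "CA", resno = 155), subunit = "Cas1ap"),
    point_spec("center", csel, subunit = c("Cas2", "Cas2p")),
    point_spec("atom", atom_selection(name = "CA", resno = 155), subunit = "Cas1a")
  )
}

#' Gamma: duplex-bend angle from nucleotide centres
#'
#' Three geometric centres: the first, middle and last base-pair levels of
#' the duplex, each centre taken over both paired nucleotides.
#'
#' @param annotation A [duplex_annotation()].
#' @return An `angle_definition`.
#' @export
gamma_definition <- function(annotation) {
  n <- nrow(annotation$pairing)
  mid <- ceiling((n + 1) / 2)
  p_level <- function(level) {
    structure(list(
      kind = "center",
      selection = NULL,
      level = level,
      annotation = annotation
    ), class = c("bp_point_spec", "point_spec"))
  }
  angle_definition("gamma", p_level(1), p_level(mid), p_level(n))
}

# bp-level point: union of the two paired nucleotides' heavy atoms
resolve_bp_point <- function(structure, spec) {
  ann <- spec$annotation
  row <- ann$pairing[spec$level, ]
  idx_a <- which(structure$chain == ann$chain_alpha &
                   structure$resno == row$resno_alpha & !structure$is_hydrogen)
  idx_b <- which(structure$chain == ann$chain_beta &
                   structure$resno == row$resno_beta & !structure$is_hydrogen)
  idx <- c(idx_a, idx_b)
  if (length(idx) == 0) abort(sprintf("bp level %d resolves to no atoms", spec$level))
  idx
}

#' Measure a defined angle on one structure
#'
#' @param structure An [md_structure()].
#' @param definition An `angle_definition`.
#' @param map Optional [subunit_map()] for subunit-scoped points.
#' @param xyz Optional replacement coordinates.
#' @return Angle in degrees.
#' @export
measure_angle <- function(structure, definition, map = NULL, xyz = NULL) {
  xyz <- xyz %||% coords(structure)
  idx <- resolve_angle_points(structure, definition, map)
  pts <- lapply(idx, function(i) point_position(xyz, i))
  three_point_angle(pts[[1]], pts[[2]], pts[[3]])
}

resolve_angle_points <- function(structure, definition, map = NULL) {
  lapply(seq_along(definition$points), function(k) {
    spec <- definition$points[[k]]
    label <- sprintf("%s point %d", definition$name, k)
    if (inherits(spec, "bp_point_spec")) {
      resolve_bp_point(structure, spec)
    } else {
      resolve_point(structure, spec, map, label)
    }
  })
}

#' Angle time series over a trajectory
#'
#' Geometric centres are recomputed every frame; atom resolution happens
#' once on the topology.
#'
#' @param traj An [md_trajectory()].
#' @param definition An `angle_definition`.
#' @param map Optional [subunit_map()].
#' @return A tibble with `frame`, `time_ps`, `name`, `angle` (degrees).
#' @export
angle_series <- function(traj, definition, map = NULL) {
  idx <- resolve_angle_points(traj$topology, definition, map)
  vals <- vapply(seq_len(n_frames(traj)), function(k) {
    xyz <- frame_coords(traj, k)
    three_point_angle(
      point_position(xyz, idx[[1]]),
      point_position(xyz, idx[[2]]),
      point_position(xyz, idx[[3]])
    )
  }, numeric(1))
  tibble(frame = seq_len(n_frames(traj)), time_ps = frame_times(traj),
         name = definition$name, angle = vals)
}

#' Distance time series between two atoms
#'
#' Atom labels take the form `"chain:resno:name"` (e.g. `"E:77:NH2"`), or
#' pass [atom_selection()]s resolving to single atoms.
#'
#' @param traj An [md_trajectory()].
#' @param atom_a,atom_b Labels or selections.
#' @return A tibble with `frame`, `time_ps`, `distance` (Angstrom);
#'   attributes `mean` and `sd` carry the summary.
#' @export
pair_distance_series <- function(traj, atom_a, atom_b) {
  resolve_one <- function(spec, what) {
    if (is.character(spec)) {
      parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
      if (length(parts) != 3) abort(sprintf("%s: label must be 'chain:resno:name'", what))
      spec <- atom_selection(chain = parts[1], resno = as.integer(parts[2]),
                             name = parts[3])
    }
    idx <- select_atoms(traj$topology, spec, warn_empty = FALSE)
    if (length(idx) == 0) abort(sprintf("%s resolves to no atom", what))
    if (length(idx) > 1) abort(sprintf("%s is ambiguous (%d atoms)", what, length(idx)))
    idx
  }
  ia <- resolve_one(atom_a, "atom_a")
  ib <- resolve_one(atom_b, "atom_b")
  ca <- traj$xyz[, c(3 * ia - 2, 3 * ia - 1, 3 * ia), drop = FALSE]
  cb <- traj$xyz[, c(3 * ib - 2, 3 * ib - 1, 3 * ib), drop = FALSE]
  d <- sqrt(rowSums((ca - cb)^2))
  out <- tibble(frame = seq_len(n_frames(traj)), time_ps = frame_times(traj),
                distance = d)
  attr(out, "mean") <- mean(d)
  attr(out, "sd") <- stats::sd(d)
  out
}

#' Product-moment correlation between two series
#'
#' @param series_a,series_b Numeric vectors of equal length (>= 3), or
#'   tibbles with an obvious value column (`angle`, `value`, `distance`).
#' @return Pearson correlation coefficient in `[-1, 1]`.
#' @export
correlate <- function(series_a, series_b) {
  pull_values <- function(x) {
    if (is.data.frame(x)) {
      for (col in c("angle", "value", "distance", "rmsd")) {
        if (col %in% names(x)) return(x[[col]])
      }
      abort("cannot find a value column in data frame input")
    }
    as.numeric(x)
  }
  a <- pull_values(series_a)
  b <- pull_values(series_b)
  if (length(a) != length(b)) abort("series differ in length")
  if (length(a) < 3) abort("need at least 3 points")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) abort("zero-variance series; correlation undefined")
  stats::cor(a, b)
}
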