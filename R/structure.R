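#' Build a molecular structure from an atom table
#'
#' An `md_structure` is a tibble with one row per atom and a fixed set of
#' columns (`serial`, `name`, `altloc`, `resid`, `chain`, `resno`, `x`, `y`,
#' `z`, `occupancy`, `element`, `is_water`, `is_hydrogen`). All coordinates
#' are in Angstrom; residue numbers follow the 1-based PDB convention while
#' atom indices returned by [select_atoms()] are plain R (1-based) row
#' indices into this table.
#'
#' @param atoms A data frame with at least `name`, `resid`, `resno`, `chain`,
#'   `x`, `y`, `z`. Missing bookkeeping columns are filled with defaults.
#' @param title Optional title string carried as an attribute.
#' @param water_names Residue names recognised as water.
#' @return An `md_structure` tibble.
#' @export
md_structure <- function(atoms, title = "", water_names = water_residue_names()) {
  atoms <- as_tibble(atoms)
  required <- c("name", "resid", "resno", "chain", "x", "y", "z")
  missing <- setdiff(required, names(atoms))
  if (length(missing) > 0) {
    abort(paste0("atom table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (nrow(atoms) == 0) abort("structure has zero atoms")
  if (is.null(atoms[["serial"]])) atoms$serial <- seq_len(nrow(atoms))
  if (is.null(atoms[["altloc"]])) atoms$altloc <- ""
  if (is.null(atoms[["occupancy"]])) atoms$occupancy <- 1
  if (is.null(atoms[["element"]])) atoms$element <- guess_element(atoms$name)
  atoms$is_water <- toupper(atoms$resid) %in% water_names
  atoms$is_hydrogen <- toupper(atoms$element) == "H"
  bad <- !is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)
  if (any(bad)) abort(paste0("non-finite coordinates at atom row ", which(bad)[1]))
  atoms <- atoms[, c(
    "serial", "name", "altloc", "resid", "chain", "resno",
    "x", "y", "z", "occupancy", "element", "is_water", "is_hydrogen"
  )]
  structure(atoms,
    title = title,
    class = c("md_structure", class(tibble()))
  )
}

#' @export
print.md_structure <- function(x, ...) {
  cat(sprintf(
    "<md_structure> %d atoms, %d chains%s\n",
    nrow(x), length(unique(x$chain)),
    if (nzchar(attr(x, "title") %||% "")) paste0(" - ", attr(x, "title")) else ""
  ))
  NextMethod()
}

# Infer an element symbol from a PDB atom name (fallback when columns 77-78
# are blank). Leading digits are stripped; names starting with H/D after
# digits are hydrogen.
guess_element <- function(name) {
  nm <- gsub("^[0-9']+", "", trimws(name))
  first <- toupper(substr(nm, 1, 1))
  two <- toupper(substr(nm, 1, 2))
  el <- first
  el[two %in% c("CL", "BR", "NA", "MG", "ZN", "FE", "MN") & nchar(trimws(name)) > 3] <-
    two[two %in% c("CL", "BR", "NA", "MG", "ZN", "FE", "MN") & nchar(trimws(name)) > 3]
  el[first %in% c("H", "D")] <- "H"
  el
}

#' Extract the coordinate matrix of a structure
#'
#' @param x An `md_structure` or a data frame with `x`, `y`, `z` columns.
#' @return A numeric n_atoms x 3 matrix (Angstrom).
#' @export
coords <- function(x) {
  m <- cbind(x$x, x$y, x$z)
  colnames(m) <- c("x", "y", "z")
  m
}

#' Replace the coordinates of a structure
#'
#' @param x An `md_structure`.
#' @param xyz An n_atoms x 3 matrix.
#' @return The structure with updated coordinates.
#' @export
set_coords <- function(x, xyz) {
  stopifnot(nrow(xyz) == nrow(x), ncol(xyz) == 3)
  x$x <- xyz[, 1]
  x$y <- xyz[, 2]
  x$z <- xyz[, 3]
  x
}

#' Human-readable atom labels
#'
#' Labels have the form `chain:resid resno:name`, e.g. `"A:ARG 77:NH2"`.
#'
#' @param x An `md_structure` (or compatible tibble).
#' @return Character vector, one label per atom.
#' @export
atom_labels <- function(x) {
  sprintf("%s:%s %d:%s", x$chain, x$resid, x$resno, x$name)
}
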