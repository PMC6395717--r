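#' Declarative atom selections
#'
#' An `atom_selection` is a serialisable conjunction of per-field constraints
#' evaluated against an [md_structure()]. Every argument left `NULL` imposes
#' no constraint; supplied arguments are combined with logical AND. The same
#' structure and selection always yield the same, strictly increasing, index
#' list.
#'
#' @param name Atom names to keep (e.g. `c("CA", "P")`).
#' @param element Element symbols to keep.
#' @param chain Chain identifiers to keep.
#' @param resno Residue numbers to keep (any integer vector, e.g. `5:30`).
#' @param resid Residue names to keep (e.g. `"ARG"`, `"DT"`).
#' @param water `TRUE` to keep only water, `FALSE` to drop water.
#' @param hydrogen `TRUE` to keep only hydrogens, `FALSE` to drop them.
#' @return An object of class `atom_selection`.
#' @export
atom_selection <- function(name = NULL, element = NULL, chain = NULL,
                           resno = NULL, resid = NULL, water = NULL,
                           hydrogen = NULL) {
  sel <- list(
    name = name, element = element, chain = chain,
    resno = resno, resid = resid, water = water, hydrogen = hydrogen
  )
  structure(sel, class = "atom_selection")
}

#' @export
print.atom_selection <- function(x, ...) {
  set <- Filter(Negate(is.null), unclass(x))
  if (length(set) == 0) {
    cat("<atom_selection> all atoms\n")
  } else {
    cat("<atom_selection>\n")
    for (f in names(set)) {
      cat(" ", f, ":", paste(utils::head(set[[f]], 12), collapse = " "),
        if (length(set[[f]]) > 12) "..." else "", "\n")
    }
  }
  invisible(x)
}

#' Resolve a selection to atom indices
#'
#' @param structure An [md_structure()].
#' @param selection An [atom_selection()] (or `NULL` for all atoms).
#' @param warn_empty Emit a warning when the selection matches nothing.
#' @return Strictly increasing integer vector of 1-based atom row indices.
#' @export
select_atoms <- function(structure, selection = NULL, warn_empty = TRUE) {
  if (is.null(selection)) return(seq_len(nrow(structure)))
  if (!inherits(selection, "atom_selection")) {
    abort("`selection` must be an atom_selection object")
  }
  keep <- rep(TRUE, nrow(structure))
  if (!is.null(selection$name)) keep <- keep & structure$name %in% selection$name
  if (!is.null(selection$element)) {
    keep <- keep & toupper(structure$element) %in% toupper(selection$element)
  }
  if (!is.null(selection$chain)) keep <- keep & structure$chain %in% selection$chain
  if (!is.null(selection$resno)) keep <- keep & structure$resno %in% selection$resno
  if (!is.null(selection$resid)) {
    keep <- keep & toupper(structure$resid) %in% toupper(selection$resid)
  }
  if (!is.null(selection$water)) keep <- keep & structure$is_water == selection$water
  if (!is.null(selection$hydrogen)) {
    keep <- keep & structure$is_hydrogen == selection$hydrogen
  }
  idx <- which(keep)
  if (length(idx) == 0 && warn_empty) warn("selection matched no atoms")
  idx
}

#' Backbone atom selection
#'
#' "Backbone atoms" are protein N, CA, C, O plus nucleic-acid P, O5', C5',
#' C4', C3', O3' (the default interpretation used throughout the package;
#' override by passing your own name set to [atom_selection()]).
#'
#' @return An [atom_selection()] covering protein and nucleic backbones.
#' @export
backbone_selection <- function() {
  atom_selection(
    name = c("N", "CA", "C", "O", "P", "O5'", "C5'", "C4'", "C3'", "O3'"),
    water = FALSE, hydrogen = FALSE
  )
}

#' Map logical subunit names onto file chains
#'
#' The crystal chains carrying the positional subunit labels (Cas1a, Cas1b,
#' Cas1a', Cas1b', Cas2, Cas2', DNA_alpha, DNA_beta) differ between
#' deposited entries, so the mapping is always user-supplied configuration,
#' never inferred.
#'
#' @param structure An [md_structure()] (used to validate chain existence).
#' @param ... Named arguments, each a character vector of chain ids, e.g.
#'   `Cas2 = "E"`, `DNA_alpha = "G"`.
#' @param assignments Alternatively, a named list of chain vectors.
#' @return A named list of chain sets with class `subunit_map`.
#' @export
subunit_map <- function(structure, ..., assignments = NULL) {
  map <- assignments %||% list(...)
  if (length(map) == 0) abort("no subunit assignments supplied")
  if (is.null(names(map)) || any(!nzchar(names(map)))) {
    abort("all subunit assignments must be named")
  }
  available <- unique(structure$chain)
  for (nm in names(map)) {
    unknown <- setdiff(map[[nm]], available)
    if (length(unknown) > 0) {
      abort(sprintf(
        "subunit '%s' references unknown chain(s) %s; available chains: %s",
        nm, paste(unknown, collapse = ", "), paste(available, collapse = ", ")
      ))
    }
  }
  all_chains <- unlist(map, use.names = FALSE)
  if (anyDuplicated(all_chains)) {
    abort(sprintf(
      "subunit chain sets must be disjoint; duplicated: %s",
      paste(unique(all_chains[duplicated(all_chains)]), collapse = ", ")
    ))
  }
  structure(map, class = "subunit_map")
}

#' @export
print.subunit_map <- function(x, ...) {
  cat("<subunit_map>\n")
  for (nm in names(x)) cat(" ", nm, "->", paste(x[[nm]], collapse = " "), "\n")
  invisible(x)
}

#' Chains belonging to a set of logical subunit names
#'
#' @param map A [subunit_map()].
#' @param names Logical subunit names to resolve.
#' @return Character vector of chain ids.
#' @export
subunit_chains <- function(map, names) {
  unknown <- setdiff(names, base::names(map))
  if (length(unknown) > 0) {
    abort(sprintf(
      "unknown subunit name(s) %s; map defines: %s",
      paste(unknown, collapse = ", "), paste(base::names(map), collapse = ", ")
    ))
  }
  unique(unlist(map[names], use.names = FALSE))
}
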