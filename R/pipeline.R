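# Pipeline driver: runs the full analysis sequence (RMSD/RMSF -> PCA and
# cosine content -> FEL -> angles -> H-bonds -> DNA descriptors ->
# optional energetics) from one configuration object, writing TSV reports
# with provenance headers.

# Tiny polynomial rolling hash for provenance headers (no external digest
# dependency; collision resistance is not a goal, change detection is).
config_fingerprint <- function(txt) {
  bytes <- utf8ToInt(txt)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483629
  sprintf("%08x", h)
}

#' Assemble an analysis configuration
#'
#' @param trajectory Path to a trajectory (multi-model PDB or frame
#'   stream), or an [md_trajectory()] object.
#' @param topology Optional topology PDB path or [md_structure()].
#' @param subunits Named list of chain vectors for [subunit_map()].
#' @param selection An [atom_selection()] for superposition/PCA (default
#'   backbone).
#' @param equilibrium Length-2 numeric, fractional frame window analysed
#'   (default `c(0, 1)`; the usual choice for equilibrium analysis is
#'   `c(0.5, 1)`, the back half of the run).
#' @param hbond An [hbond_criteria()].
#' @param fel_bins,fel_T Free-energy landscape bins and temperature (K).
#' @param angles List of `angle_definition` objects (defaults to the
#'   shipped alpha/beta when subunits are mapped).
#' @param duplex Optional [duplex_annotation()] arguments as a list
#'   (`chain_alpha`, `chain_beta`, ...).
#' @param hbond_groups Optional list with `group_A`, `group_B` logical
#'   subunit names for interface occupancy.
#' @param energy Optional list with `params` (path or tibble), `idx_A`,
#'   `idx_B` (or `group_A`/`group_B` subunit names) and `stride`.
#' @param out_dir Output directory for reports.
#' @param dt Frame spacing when reading PDB trajectories, ps.
#' @param seed Seed recorded in provenance (analyses are deterministic).
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(trajectory, topology = NULL, subunits = NULL,
                            selection = backbone_selection(),
                            equilibrium = c(0, 1),
                            hbond = hbond_criteria(),
                            fel_bins = 80, fel_T = 310,
                            angles = NULL, duplex = NULL,
                            hbond_groups = NULL, energy = NULL,
                            out_dir = tempfile("mdtidy_run_"), dt = 1,
                            seed = 1) {
  if (length(equilibrium) != 2 || equilibrium[1] < 0 || equilibrium[2] > 1 ||
      equilibrium[1] >= equilibrium[2]) {
    abort("`equilibrium` must be a fraction window c(lo, hi) within [0, 1]")
  }
  structure(
    list(trajectory = trajectory, topology = topology, subunits = subunits,
         selection = selection, equilibrium = equilibrium, hbond = hbond,
         fel_bins = fel_bins, fel_T = fel_T, angles = angles, duplex = duplex,
         hbond_groups = hbond_groups, energy = energy, out_dir = out_dir,
         dt = dt, seed = seed),
    class = "analysis_config"
  )
}

config_hash <- function(config) {
  desc <- utils::capture.output(utils::str(config, max.level = 3))
  config_fingerprint(paste(desc, collapse = "\n"))
}

write_report <- function(df, path, config, stage) {
  header <- c(
    sprintf("# mdtidy %s", as.character(utils::packageVersion("mdtidy"))),
    sprintf("# stage: %s", stage),
    sprintf("# config_hash: %s", config_hash(config)),
    sprintf("# seed: %s", config$seed)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes every configured stage in sequence on the equilibrium window
#' of the trajectory, writes one TSV report per stage into
#' `config$out_dir` (with a provenance header: package version, config
#' hash, seed) and returns the result tables. Any stage failure aborts
#' with the stage name; reports already written are retained.
#'
#' @param config An [analysis_config()].
#' @return A named list of result tables (invisible components: paths).
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  results <- list()
  traj <- stage("input", {
    topo <- config$topology
    if (is.character(topo)) topo <- read_pdb(topo)
    tr <- config$trajectory
    if (is.character(tr)) tr <- read_trajectory(tr, topology = topo, dt = config$dt)
    if (!inherits(tr, "md_trajectory")) abort("not a trajectory")
    tr
  })
  nf <- n_frames(traj)
  lo <- max(1, floor(config$equilibrium[1] * nf) + 1)
  hi <- max(lo, ceiling(config$equilibrium[2] * nf))
  eq <- subset_frames(traj, lo:hi)
  results$frames_used <- tibble(first = lo, last = hi, n = hi - lo + 1)
  map <- if (!is.null(config$subunits)) {
    subunit_map(traj$topology, assignments = config$subunits)
  } else NULL

  results$rmsd <- stage("rmsd", rmsd_series(eq, traj$topology, config$selection))
  write_report(results$rmsd, file.path(config$out_dir, "rmsd.tsv"), config, "rmsd")
  results$rmsd_hist <- stage("rmsd", rmsd_histogram(results$rmsd))
  results$rmsf <- stage("rmsf", rmsf(eq, config$selection))
  write_report(results$rmsf, file.path(config$out_dir, "rmsf.tsv"), config, "rmsf")

  pca_res <- stage("pca", pca_trajectory(eq, config$selection))
  results$pca <- tidy(pca_res)
  write_report(results$pca, file.path(config$out_dir, "pca_eigenvalues.tsv"),
               config, "pca")
  proj <- stage("pca", project(eq, pca_res, modes = 1:2))
  results$projections <- proj
  results$cosine_content <- stage("pca", tibble(
    mode = 1:2,
    cc = c(cosine_content(filter(proj, .data$mode == 1)),
           cosine_content(filter(proj, .data$mode == 2)))
  ))
  write_report(results$cosine_content,
               file.path(config$out_dir, "cosine_content.tsv"), config, "pca")

  fel <- stage("fel", fel_2d(filter(proj, .data$mode == 1),
                             filter(proj, .data$mode == 2),
                             n_bins = config$fel_bins, T_K = config$fel_T))
  results$fel <- fel
  results$basins <- stage("fel", find_basins(fel))
  write_fel_tsv(fel, file.path(config$out_dir, "fel"))

  if (!is.null(config$angles)) {
    results$angles <- stage("angles", {
      bind_rows(lapply(config$angles, function(def) {
        angle_series(eq, def, map)
      }))
    })
    write_report(results$angles, file.path(config$out_dir, "angles.tsv"),
                 config, "angles")
  }

  if (!is.null(config$hbond_groups)) {
    results$hbonds <- stage("hbonds", {
      pairs <- interface_pairs(traj$topology, map,
                               config$hbond_groups$group_A,
                               config$hbond_groups$group_B)
      hbond_occupancy(eq, pairs, NULL, criteria = config$hbond)
    })
    write_report(results$hbonds, file.path(config$out_dir, "hbonds.tsv"),
                 config, "hbonds")
  }

  if (!is.null(config$duplex)) {
    results$dna <- stage("dna", {
      ann <- do.call(duplex_annotation, c(list(traj$topology), config$duplex))
      profile_over_trajectory(eq, ann)
    })
    write_report(results$dna$grooves, file.path(config$out_dir, "grooves.tsv"),
                 config, "dna")
    write_report(results$dna$bend, file.path(config$out_dir, "bend.tsv"),
                 config, "dna")
  }

  if (!is.null(config$energy)) {
    results$energy <- stage("energy", {
      en <- config$energy
      params <- if (is.character(en$params)) read_ff_params(en$params) else en$params
      idx_A <- en$idx_A %||% select_atoms(
        traj$topology, atom_selection(chain = subunit_chains(map, en$group_A)))
      idx_B <- en$idx_B %||% select_atoms(
        traj$topology, atom_selection(chain = subunit_chains(map, en$group_B)))
      decompose_energy(eq, idx_A, idx_B, params, stride = en$stride %||% 1)
    })
    write_report(results$energy$by_residue,
                 file.path(config$out_dir, "energy_decomposition.tsv"),
                 config, "energy")
  }
  results
}

#' Measure shipped angle definitions on a single structure
#'
#' Evaluates each angle definition on a static structure (e.g. a deposited
#' crystal structure) and reports one row per angle. For `alpha`, whose
#' definition exists on two symmetric surfaces, pass both definitions and
#' average, or use [measure_alpha()].
#'
#' @param structure An [md_structure()] or PDB path.
#' @param definitions List of `angle_definition` objects.
#' @param map A [subunit_map()] resolving the definitions' subunits.
#' @return A tibble with `name`, `degrees` and `points` provenance.
#' @export
measure_structure <- function(structure, definitions, map = NULL) {
  if (is.character(structure)) structure <- read_pdb(structure)
  rows <- lapply(definitions, function(def) {
    idx <- resolve_angle_points(structure, def, map)
    tibble(
      name = def$name,
      degrees = measure_angle(structure, def, map),
      points = paste(map_int(idx, length), collapse = "+")
    )
  })
  bind_rows(rows)
}

#' Alpha angle of a Cas1-Cas2 hexamer structure
#'
#' The open-close angle exists on two symmetric surfaces
#' (Cas1a-Cas2'-Cas1b' and Cas1a'-Cas2-Cas1b); both are measured and their
#' mean reported, which is what a single quoted per-structure value is
#' compared against.
#'
#' @param structure An [md_structure()] or PDB path.
#' @param map A [subunit_map()] with Cas1a/Cas1ap/Cas1b/Cas1bp/Cas2/Cas2p.
#' @param center_atoms `"all"` or `"CA"` geometric centres.
#' @return A tibble with `surface`, `degrees` plus a `mean` attribute.
#' @export
measure_alpha <- function(structure, map, center_atoms = "all") {
  if (is.character(structure)) structure <- read_pdb(structure)
  vals <- tibble(
    surface = c("unprimed", "primed"),
    degrees = c(
      measure_angle(structure, alpha_definition("unprimed", center_atoms), map),
      measure_angle(structure, alpha_definition("primed", center_atoms), map)
    )
  )
  attr(vals, "mean") <- mean(vals$degrees)
  vals
}
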