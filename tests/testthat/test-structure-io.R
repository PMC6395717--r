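test_that("well-formed ATOM records parse as an identity", {
  txt <- paste(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  C   ALA B   2      12.759   7.095  -4.948  1.00  0.00           C",
    sep = "\n"
  )
  s <- read_pdb(txt)
  expect_equal(nrow(s), 3)
  expect_equal(s$name, c("N", "CA", "C"))
  expect_equal(s$chain, c("A", "A", "B"))
  expect_equal(s$resno, c(1L, 1L, 2L))
  expect_equal(s$x, c(11.104, 11.639, 12.759))
  expect_equal(s$element, c("N", "C", "C"))
})

test_that("altloc resolution keeps the highest-occupancy conformer", {
  txt <- paste(
    "ATOM      1  CA AALA A   1      10.000   0.000   0.000  0.60  0.00           C",
    "ATOM      2  CA BALA A   1      20.000   0.000   0.000  0.40  0.00           C",
    sep = "\n"
  )
  s <- read_pdb(txt)
  expect_equal(nrow(s), 1)
  expect_equal(s$x, 10)
  # ties break by altloc letter order
  txt2 <- gsub("0.60", "0.40", txt, fixed = TRUE)
  s2 <- read_pdb(txt2)
  expect_equal(s2$x, 10)
})

test_that("malformed coordinates and empty structures are rejected informatively", {
  txt <- paste(
    "ATOM      1  CA  ALA A   1      11.104   6.134  -6.504  1.00  0.00           C",
    "ATOM      2  CA  ALA A   2      xx.xxx   6.134  -6.504  1.00  0.00           C",
    sep = "\n"
  )
  expect_error(read_pdb(txt), "line 2")
  expect_error(read_pdb("REMARK nothing here\nEND"), "empty|no ATOM")
})

test_that("write -> read round trip preserves coordinates and identifiers", {
  s <- toy_peptide(4)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s, path)
  s2 <- read_pdb(path)
  expect_equal(s2$name, s$name)
  expect_equal(s2$resno, s$resno)
  expect_equal(s2$chain, s$chain)
  expect_lt(max(abs(coords(s2) - coords(s))), 1e-3)
  # idempotent: second round trip exact
  path2 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s2, path2)
  expect_identical(coords(read_pdb(path2)), coords(s2))
})

test_that("parser agrees with an independent reader on atom inventory", {
  skip_if_not_installed("bio3d")
  s <- toy_peptide(5)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s, path)
  ref <- bio3d::read.pdb(path)
  expect_equal(nrow(s), nrow(ref$atom))
  expect_equal(sum(s$name == "CA"), sum(ref$atom$elety == "CA"))
  expect_equal(sort(unique(s$chain)), sort(unique(ref$atom$chain)))
  expect_equal(unname(coords(s)), unname(cbind(ref$atom$x, ref$atom$y, ref$atom$z)),
               tolerance = 1e-6)
})

test_that("multi-model PDB reads as an ordered trajectory", {
  s <- toy_peptide(3)
  tr <- md_trajectory(s, list(coords(s), coords(s) + 1), dt = 2)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory_pdb(tr, path)
  tr2 <- read_trajectory(path, topology = s, dt = 2)
  expect_equal(n_frames(tr2), 2)
  expect_lt(max(abs(tr2$xyz - tr$xyz)), 1e-3)
  # atom-count mismatch names the offending frame
  lines <- readLines(path)
  drop <- which(grepl("^ATOM", lines))
  bad <- lines[-drop[length(drop)]]  # remove one atom from model 2
  expect_error(read_trajectory(paste(bad, collapse = "\n"), topology = s),
               "frame 2")
})

test_that("binary frame stream round trips bit-exactly and preserves frame order", {
  tr <- gen_diffusion_trajectory(7, 0.2, 100, seed = 5, dt = 0.5)
  path <- withr::local_tempfile(fileext = ".mdts")
  write_frame_stream(tr, path)
  tr2 <- read_frame_stream(path, tr$topology)
  expect_equal(tr2$dt, 0.5)
  expect_equal(n_frames(tr2), 100)
  # float32 storage: re-writing gives identical bytes
  path2 <- withr::local_tempfile(fileext = ".mdts")
  write_frame_stream(tr2, path2)
  expect_identical(readBin(path, "raw", file.size(path)),
                   readBin(path2, "raw", file.size(path2)))
  # frame 37 equals the generator's stored frame within float32 precision
  expect_equal(frame_coords(tr2, 37), frame_coords(tr, 37), tolerance = 1e-6)
})

test_that("selections are deterministic, ordered and honour every field", {
  s <- toy_peptide(3)
  idx <- select_atoms(s, atom_selection(name = "CA"))
  expect_equal(length(idx), 3)
  expect_true(all(diff(idx) > 0))
  expect_identical(idx, select_atoms(s, atom_selection(name = "CA")))
  expect_warning(empty <- select_atoms(s, atom_selection(water = TRUE)),
                 "no atoms")
  expect_equal(length(empty), 0)
  # P selection on a generated 23-bp duplex: 2*23 minus the two 5' termini
  duplex <- build_bdna(duplex_sequence())
  expect_equal(length(select_atoms(duplex, atom_selection(name = "P"))), 44)
})

test_that("subunit maps validate chains and reject overlap", {
  s <- md_structure(dplyr::bind_rows(lapply(c("C", "D", "E", "F", "G", "H"),
    function(ch) {
      tibble::tibble(name = "CA", resid = "GLY", resno = 1, chain = ch,
                     x = match(ch, LETTERS), y = 0, z = 0)
    })))
  map <- subunit_map(s, Cas1a = "C", Cas1b = "D", Cas2 = "E", Cas2p = "F",
                     DNA_alpha = "G", DNA_beta = "H")
  expect_equal(subunit_chains(map, c("Cas2", "Cas2p")), c("E", "F"))
  expect_error(subunit_map(s, A1 = "C", A2 = "C"), "disjoint")
  expect_error(subunit_map(s, A1 = "Z"), "available chains")
  expect_error(subunit_chains(map, "Cas9"), "unknown subunit")
})
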