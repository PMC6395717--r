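test_that("collinear short contacts are detected, long ones are not", {
  make_scene <- function(oo) {
    md_structure(tibble::tibble(
      name = c("OG", "HG", "O"),
      resid = c("SER", "SER", "GLY"),
      resno = c(1, 1, 2), chain = c("A", "A", "B"),
      x = c(0, 0.96, oo), y = 0, z = 0
    ))
  }
  hb <- find_hbonds(make_scene(2.8))
  expect_equal(nrow(hb), 1)
  expect_equal(hb$distance, 2.8)
  expect_equal(hb$angle, 0, tolerance = 1e-8)
  expect_false(hb$heavy_only)
  expect_equal(nrow(find_hbonds(make_scene(4.0))), 0)
})

test_that("detection equals the brute-force oracle on random frames", {
  for (seed in 1:50) {
    s <- random_hbond_frame(n_groups = sample(10:40, 1), seed = seed)
    expect_lte(nrow(s), 200)
    xyz <- coords(s)
    roles <- mdtidy:::polar_roles(s)
    for (conv in c("DHA-deviation", "HDA")) {
      crit <- hbond_criteria(angle_convention = conv)
      got <- find_hbonds(s, roles$donor, roles$acceptor, crit)
      got_m <- matrix(as.integer(as.matrix(
        got[order(got$donor, got$acceptor), c("donor", "acceptor")]
      )), ncol = 2)
      oracle <- brute_force_hbonds(s, xyz, roles$donor, roles$acceptor, crit)
      expect_equal(unname(got_m), unname(matrix(as.integer(oracle), ncol = 2)))
    }
  }
})

test_that("stricter criteria select a subset of records", {
  s <- random_hbond_frame(30, seed = 99)
  roles <- mdtidy:::polar_roles(s)
  loose <- find_hbonds(s, roles$donor, roles$acceptor, hbond_criteria(3.5, 60))
  tight <- find_hbonds(s, roles$donor, roles$acceptor, hbond_criteria(3.0, 30))
  key <- function(d) paste(d$donor, d$acceptor)
  expect_true(all(key(tight) %in% key(loose)))
})

test_that("detection is invariant under global rigid transforms", {
  s <- random_hbond_frame(25, seed = 13)
  roles <- mdtidy:::polar_roles(s)
  ref <- find_hbonds(s, roles$donor, roles$acceptor)
  set.seed(14)
  r <- random_rotation()
  xyz2 <- coords(s) %*% r + matrix(c(10, -4, 2), nrow(s), 3, byrow = TRUE)
  moved <- find_hbonds(s, roles$donor, roles$acceptor, xyz = xyz2)
  expect_equal(moved[, c("donor", "acceptor")], ref[, c("donor", "acceptor")])
  expect_equal(moved$angle, ref$angle, tolerance = 1e-6)
})

test_that("water bridges require simultaneous bonds to both sides", {
  tr <- gen_hbond_scene(TRUE, bridge = TRUE)
  s <- tr$topology
  br <- find_water_bridges(s, which(s$chain == "P"), which(s$chain == "D"),
                           xyz = frame_coords(tr, 1))
  expect_equal(nrow(br), 1)
  expect_true(all(br$bridge))
  # water bonded to one side only: push the acceptor away
  xyz <- frame_coords(tr, 1)
  xyz[s$chain == "D", 1] <- xyz[s$chain == "D", 1] + 10
  expect_equal(nrow(find_water_bridges(s, which(s$chain == "P"),
                                       which(s$chain == "D"), xyz = xyz)), 0)
})

test_that("occupancy equals the planted schedule fraction exactly", {
  sched <- rep(FALSE, 100)
  sched[sample.int(100, 37)] <- TRUE
  tr <- gen_hbond_scene(sched)
  s <- tr$topology
  occ <- hbond_occupancy(tr, which(s$chain == "P"), which(s$chain == "D"),
                         min_occupancy = 0)
  expect_equal(nrow(occ), 1)
  expect_equal(occ$occupancy, 0.37)
  expect_false(occ$bridge)
  # permanent bond
  tr2 <- gen_hbond_scene(rep(TRUE, 10))
  occ2 <- hbond_occupancy(tr2, which(s$chain == "P"), which(s$chain == "D"),
                          min_occupancy = 0)
  expect_equal(occ2$occupancy, 1)
  # a never-formed pair is absent, and the default threshold drops rare bonds
  tr3 <- gen_hbond_scene(c(TRUE, rep(FALSE, 9)))
  expect_equal(nrow(hbond_occupancy(tr3, which(s$chain == "P"),
                                    which(s$chain == "D"))), 0)
  # occupancy invariant under frame permutation
  perm <- sample(100)
  occ_p <- hbond_occupancy(subset_frames(tr, perm), which(s$chain == "P"),
                           which(s$chain == "D"), min_occupancy = 0)
  expect_equal(occ_p$occupancy, 0.37)
})

test_that("bridged schedules aggregate to bridge occupancy", {
  sched <- rep(c(TRUE, TRUE, TRUE, FALSE, FALSE), 4)  # 12 of 20 on
  tr <- gen_hbond_scene(sched, bridge = TRUE)
  s <- tr$topology
  occ <- hbond_occupancy(tr, which(s$chain == "P"), which(s$chain == "D"),
                         min_occupancy = 0)
  expect_equal(nrow(occ), 1)
  expect_true(occ$bridge)
  expect_equal(occ$occupancy, 0.60)
})

test_that("interface pairs partition polar atoms by side", {
  tr <- gen_hbond_scene(TRUE, bridge = TRUE)
  s <- tr$topology
  map <- subunit_map(s, protein = "P", dna = "D", water = "W")
  pairs <- interface_pairs(s, map, "protein", "dna")
  expect_true(all(s$chain[pairs$idx_A] == "P"))
  expect_true(all(s$chain[pairs$idx_B] == "D"))
  # candidate count equals a manual polar census (heavy N/O on each side)
  census_A <- sum(s$chain == "P" & !s$is_hydrogen & s$element %in% c("N", "O"))
  expect_equal(length(pairs$idx_A), census_A)
  s2 <- md_structure(dplyr::bind_rows(
    tibble::tibble(name = "OG", resid = "SER", resno = 1, chain = "P",
                   x = 0, y = 0, z = 0),
    tibble::tibble(name = c("CA", "CB"), resid = "ALA", resno = 2, chain = "X",
                   x = c(5, 6), y = 0, z = 0)
  ))
  expect_warning(
    interface_pairs(s2, subunit_map(s2, a = "P", b = "X"), "a", "b"),
    "no polar"
  )
  expect_error(interface_pairs(s, map, "protein", "rna"), "unknown subunit")
})

test_that("heavy-atom-only mode applies when hydrogens are absent", {
  s <- md_structure(tibble::tibble(
    name = c("OG", "O"), resid = c("SER", "GLY"), resno = 1:2,
    chain = c("A", "B"), x = c(0, 3.0), y = 0, z = 0
  ))
  hb <- find_hbonds(s)
  expect_equal(nrow(hb), 1)
  expect_true(hb$heavy_only)
  expect_true(is.na(hb$angle))
})
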