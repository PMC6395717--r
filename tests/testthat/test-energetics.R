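test_that("coulomb energy matches closed forms and brute force", {
  expect_equal(
    coulomb_energy(matrix(0, 1, 3), 1, matrix(c(3.320636, 0, 0), 1), -1),
    -100, tolerance = 1e-6
  )
  expect_equal(coulomb_energy(matrix(0, 0, 3), numeric(0), matrix(0, 1, 3), 1), 0)
  set.seed(1)
  xa <- matrix(rnorm(15, sd = 3), 5)
  xb <- matrix(rnorm(15, sd = 3) + 8, 5)
  qa <- runif(5, -1, 1)
  qb <- runif(5, -1, 1)
  brute <- 0
  for (i in 1:5) for (j in 1:5) {
    brute <- brute + 332.0636 * qa[i] * qb[j] / sqrt(sum((xa[i, ] - xb[j, ])^2))
  }
  expect_equal(coulomb_energy(xa, qa, xb, qb), brute, tolerance = 1e-10)
  expect_error(coulomb_energy(matrix(0, 1, 3), 1, matrix(c(0.1, 0, 0), 1), 1), "clash")
})

test_that("lennard-jones energy matches closed forms and brute force", {
  p1 <- tibble::tibble(sigma = 3.2, epsilon = 0.25)
  expect_equal(lj_energy(matrix(0, 1, 3), p1, matrix(c(3.2, 0, 0), 1), p1), 0,
               tolerance = 1e-10)
  expect_equal(
    lj_energy(matrix(0, 1, 3), p1, matrix(c(2^(1 / 6) * 3.2, 0, 0), 1), p1),
    -0.25, tolerance = 1e-10
  )
  set.seed(2)
  xa <- matrix(rnorm(12, sd = 2), 4)
  xb <- matrix(rnorm(12, sd = 2) + 7, 4)
  pa <- tibble::tibble(sigma = runif(4, 2.5, 3.8), epsilon = runif(4, 0.05, 0.3))
  pb <- tibble::tibble(sigma = runif(4, 2.5, 3.8), epsilon = runif(4, 0.05, 0.3))
  brute <- 0
  for (i in 1:4) for (j in 1:4) {
    r <- sqrt(sum((xa[i, ] - xb[j, ])^2))
    sg <- (pa$sigma[i] + pb$sigma[j]) / 2
    ep <- sqrt(pa$epsilon[i] * pb$epsilon[j])
    brute <- brute + 4 * ep * ((sg / r)^12 - (sg / r)^6)
  }
  expect_equal(lj_energy(xa, pa, xb, pb), brute, tolerance = 1e-10)
})

test_that("generalized Born reduces to the Born formula and the Still pair form", {
  # isolated ion: effective radius is the intrinsic radius
  expect_equal(effective_born_radii(matrix(0, 1, 3), 2), 2)
  # distant neighbours barely descreen
  rr <- effective_born_radii(rbind(c(0, 0, 0), c(100, 0, 0)), c(2, 2))
  expect_equal(rr, c(2, 2), tolerance = 1e-2)
  # single ion Born limit (eps_in 1 to match the textbook form)
  xyz <- rbind(c(0, 0, 0), c(60, 0, 0))
  g <- gb_polar_energy(xyz, c(1, 0), c(2, 2), 1, 2, eps_in = 1, eps_out = 80)
  expect_equal(g$G_A, -0.5 * 332.0636 * (1 - 1 / 80) / 2, tolerance = 1e-6)
  # neutral group contributes nothing
  g0 <- gb_polar_energy(xyz, c(0, 0), c(2, 2), 1, 2)
  expect_equal(g0$dG, 0)
  # two-atom toy against the hand-evaluated Still functional
  xyz2 <- rbind(c(0, 0, 0), c(4, 0, 0))
  q <- c(0.5, -0.8)
  radii <- c(1.6, 1.9)
  g2 <- gb_polar_energy(xyz2, q, radii, 1, 2, eps_in = 2, eps_out = 80,
                        descreen = FALSE)
  tau <- 1 / 2 - 1 / 80
  fgb <- sqrt(16 + radii[1] * radii[2] * exp(-16 / (4 * radii[1] * radii[2])))
  hand_complex <- -0.5 * 332.0636 * tau *
    (q[1]^2 / radii[1] + q[2]^2 / radii[2] + 2 * q[1] * q[2] / fgb)
  hand_free <- -0.5 * 332.0636 * tau * (q[1]^2 / radii[1] + q[2]^2 / radii[2])
  expect_equal(g2$G_complex, hand_complex, tolerance = 1e-8)
  expect_equal(g2$dG, hand_complex - hand_free, tolerance = 1e-8)
})

test_that("numerical SASA matches analytic sphere results", {
  r <- 1.5; w <- 1.4
  expect_lt(abs(sasa(matrix(0, 1, 3), r, w) / (4 * pi * (r + w)^2) - 1), 0.005)
  # two fused spheres against the analytic two-sphere area
  r1 <- 1.8; r2 <- 1.5; d <- 2.2
  R1 <- r1 + w; R2 <- r2 + w
  xyz <- rbind(c(0, 0, 0), c(d, 0, 0))
  got <- sasa(xyz, c(r1, r2), w, n_points = 4000)
  cap_h1 <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  cap_h2 <- R2 - (d^2 + R2^2 - R1^2) / (2 * d)
  analytic <- c(4 * pi * R1^2 - 2 * pi * R1 * cap_h1,
                4 * pi * R2^2 - 2 * pi * R2 * cap_h2)
  expect_lt(max(abs(got / analytic - 1)), 0.01)
  # infinitely separated groups bury nothing
  far <- rbind(c(0, 0, 0), c(50, 0, 0))
  np <- sasa_nonpolar(far, c(r1, r2), 1, 2)
  expect_equal(np$dSASA, 0)
  expect_equal(np$dG, 0)
})

test_that("per-residue decomposition conserves the totals every frame", {
  set.seed(3)
  at <- tibble::tibble(
    name = rep(c("N", "CA", "O"), 4),
    resid = rep(c("ARG", "GLY", "DT", "DA"), each = 3),
    resno = rep(c(1, 2, 5, 6), each = 3),
    chain = rep(c("P", "P", "D", "D"), each = 3),
    x = rnorm(12, rep(c(0, 4, 9, 13), each = 3), 0.7),
    y = rnorm(12, 0, 0.7), z = rnorm(12, 0, 0.7)
  )
  s <- md_structure(at)
  params <- uniform_ff_params(s, charge = rep(c(0.35, -0.2, -0.15), 4),
                              sigma = 3.2, epsilon = 0.15, born_radius = 1.6)
  frames <- list(coords(s), coords(s) + 0.15)
  tr <- md_trajectory(s, frames, dt = 1)
  de <- decompose_energy(tr, 1:6, 7:12, params, n_points = 320)
  for (f in unique(de$per_frame$frame)) {
    parts <- sum(de$per_frame$E_total[de$per_frame$frame == f])
    whole <- de$totals$E_total[de$totals$frame == f]
    expect_equal(parts, whole, tolerance = 1e-6)
  }
  # rigid invariance of all terms
  set.seed(4)
  r <- random_rotation()
  tr2 <- md_trajectory(s, lapply(frames, function(fr) fr %*% r + 3), dt = 1)
  de2 <- decompose_energy(tr2, 1:6, 7:12, params, n_points = 320)
  expect_equal(de2$totals$E_elec, de$totals$E_elec, tolerance = 1e-8)
  expect_equal(de2$totals$E_vdw, de$totals$E_vdw, tolerance = 1e-8)
  expect_equal(de2$totals$E_polar, de$totals$E_polar, tolerance = 1e-8)
  # the SASA point grid is not rotation invariant; agreement is to the
  # quadrature resolution only
  expect_lt(max(abs(de2$totals$E_nonpolar - de$totals$E_nonpolar)), 0.02)
  # unparameterized atom is named
  expect_error(decompose_energy(tr, 1:6, 7:12, params[-1, ]), "P:1:N")
})

test_that("symmetric dimers receive symmetric contributions", {
  at <- tibble::tibble(
    name = rep("CA", 4),
    resid = "GLY", resno = c(1, 2, 1, 2),
    chain = c("A", "A", "B", "B"),
    x = c(-2, 2, -2, 2), y = c(0, 0, 4, 4), z = 0
  )
  s <- md_structure(at)
  params <- uniform_ff_params(s, charge = c(0.4, -0.4, -0.4, 0.4),
                              sigma = 3.0, epsilon = 0.2, born_radius = 1.7)
  tr <- md_trajectory(s, list(coords(s)), dt = 1)
  # high SASA point count: the quadrature grid is the only symmetry breaker
  de <- decompose_energy(tr, 1:2, 3:4, params, n_points = 4000)
  tot <- de$by_residue
  a <- tot$E_total_mean[tot$residue == "A:GLY 1"]
  b <- tot$E_total_mean[tot$residue == "B:GLY 2"]
  expect_equal(a, b, tolerance = 1e-3)
})

test_that("parameter files round trip", {
  s <- toy_peptide(2)
  params <- uniform_ff_params(s, charge = seq(-0.4, 0.3, length.out = 8))
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(params, path, row.names = FALSE, quote = FALSE)
  back <- read_ff_params(path)
  expect_equal(back$charge, params$charge, tolerance = 1e-12)
  expect_equal(back$atom_label, params$atom_label)
})
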