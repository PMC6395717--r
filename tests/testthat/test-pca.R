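test_that("covariance matrix handles closed-form cases", {
  s <- toy_peptide(4)
  static <- md_trajectory(s, rep(list(coords(s)), 3), dt = 1)
  cv <- covariance_matrix(static, atom_selection())
  expect_equal(max(abs(cv$C)), 0, tolerance = 1e-10)
  # single atom alternating +/- a along x (no fitting possible or wanted)
  one <- pseudo_atom_structure(1)
  tr <- md_trajectory(one, list(cbind(2, 0, 0), cbind(-2, 0, 0),
                                cbind(2, 0, 0), cbind(-2, 0, 0)), dt = 1)
  cv1 <- covariance_matrix(tr, atom_selection(), fit = FALSE)
  expect_equal(cv1$C, diag(c(4, 0, 0)), tolerance = 1e-10)
  expect_error(covariance_matrix(md_trajectory(one, cbind(0, 0, 0), dt = 1),
                                 atom_selection(), fit = FALSE), "2 frames")
})

test_that("eigendecomposition satisfies its invariants", {
  r <- eigendecompose(diag(c(3, 2, 1)))
  expect_equal(r$values, c(3, 2, 1))
  expect_equal(abs(r$vectors), diag(3), tolerance = 1e-10)
  expect_equal(eigendecompose(matrix(0, 3, 3))$values, rep(0, 3))
  expect_error(eigendecompose(matrix(1:9, 3)), "symmetric")
  set.seed(8)
  a <- matrix(rnorm(900), 30)
  C <- crossprod(a) / 30
  r2 <- eigendecompose(C)
  expect_lt(max(abs(r2$vectors %*% diag(r2$values) %*% t(r2$vectors) - C)), 1e-8)
  expect_lt(max(abs(crossprod(r2$vectors) - diag(30))), 1e-6)
  expect_equal(sum(r2$values), sum(diag(C)), tolerance = 1e-6)
  expect_false(is.unsorted(rev(r2$values)))
})

test_that("planted modes are recovered in eigenvalues and eigenvectors", {
  base <- gen_toy_structure(20, seed = 3)
  modes <- orthonormal_modes(base, 2, seed = 5)
  tr <- gen_mode_trajectory(base, modes, c(2, 1), noise_sd = 0.1,
                            n_frames = 5000, seed = 11)
  p <- pca_trajectory(tr, atom_selection())
  expect_lt(abs(p$values[1] - 4) / 4, 0.1)
  expect_lt(abs(p$values[2] - 1) / 1, 0.1)
  expect_gt(abs(sum(p$vectors[, 1] * modes[, 1])), 0.99)
  expect_gt(abs(sum(p$vectors[, 2] * modes[, 2])), 0.99)
})

test_that("projections behave like coordinates along eigenvectors", {
  C <- diag(c(3, 2, 1, rep(0.1, 3)))
  r <- eigendecompose(C)
  r$mean <- rep(0, 6)
  r$idx <- 1:2
  r$dt <- 1
  topo <- pseudo_atom_structure(2)
  xyz <- rbind(2 * r$vectors[, 1], -1 * r$vectors[, 1], 0 * r$vectors[, 1])
  tr <- md_trajectory(topo, xyz, dt = 1)
  pr <- project(tr, r, 1:2, fit = FALSE)
  expect_equal(dplyr::filter(pr, mode == 1)$value, c(2, -1, 0), tolerance = 1e-10)
  expect_equal(dplyr::filter(pr, mode == 2)$value, rep(0, 3), tolerance = 1e-10)
  expect_error(project(tr, r, 99), "out of range")
  # projection variance equals the eigenvalue on the same data
  base <- gen_toy_structure(10, seed = 1)
  m <- orthonormal_modes(base, 1, seed = 2)
  tr2 <- gen_mode_trajectory(base, m, 1.2, noise_sd = 0.05, n_frames = 800, seed = 3)
  p2 <- pca_trajectory(tr2, atom_selection())
  v1 <- dplyr::filter(project(tr2, p2, 1), mode == 1)$value
  expect_equal(mean(v1^2) - mean(v1)^2, p2$values[1], tolerance = 1e-6)
  expect_lt(abs(mean(v1)), 1e-6 + 1e-6 * sd(v1))
})

test_that("variance fractions accumulate correctly", {
  r <- eigendecompose(diag(c(3, 2, 1)))
  expect_equal(variance_fraction(r, 2), 5 / 6)
  expect_equal(variance_fraction(r, 3), 1.0)
  expect_error(variance_fraction(r, 0), ">= 1")
  fr <- vapply(1:3, variance_fraction, numeric(1), result = r)
  expect_false(is.unsorted(fr))
  # planted construction carrying ~54% in the top two modes
  base <- gen_toy_structure(20, seed = 6)
  modes <- orthonormal_modes(base, 2, seed = 7)
  # noise also adds variance along the planted modes; solve
  # (S + 2 v) / (S + 54 v) = 0.54 for the per-coordinate noise variance v
  S <- 5 + 2.56
  v <- S * (1 - 0.54) / (0.54 * 54 - 2)
  noise_sd <- sqrt(v)
  tr <- gen_mode_trajectory(base, modes, c(sqrt(5), sqrt(2.56)),
                            noise_sd = noise_sd, n_frames = 5000, seed = 8)
  p <- pca_trajectory(tr, atom_selection())
  expect_lt(abs(variance_fraction(p, 2) - 0.54), 0.02)
})

test_that("cosine content matches its defining integrals", {
  u <- seq(0, 1, length.out = 1000)
  expect_equal(cosine_content(cos(pi * u), 1), 1, tolerance = 1e-3)
  expect_equal(cosine_content(cos(2 * pi * u), 2), 1, tolerance = 1e-3)
  # cos(2 pi t / T) is orthogonal to cos(pi t / T) on [0, T]
  expect_lt(cosine_content(cos(2 * pi * u), 1), 1e-2)
  # amplitude-scaling invariance
  set.seed(4)
  p <- cumsum(rnorm(500))
  expect_equal(cosine_content(p, 1), cosine_content(17.3 * p, 1), tolerance = 1e-12)
  expect_error(cosine_content(rep(0, 10)), "zero")
  cc <- cosine_content(p, 1)
  expect_gte(cc, 0)
  expect_lte(cc, 1)
})

test_that("pure diffusion yields high cosine content in PC1", {
  ccs <- vapply(1:10, function(sd) {
    tr <- gen_diffusion_trajectory(10, 0.1, 2000, seed = sd)
    p <- pca_trajectory(tr, atom_selection(), fit = FALSE)
    cosine_content(project(tr, p, 1, fit = FALSE))
  }, numeric(1))
  expect_gt(mean(ccs), 0.8)
})

test_that("mode vectors export planted displacement patterns", {
  base <- gen_toy_structure(12, seed = 2)
  modes <- orthonormal_modes(base, 1, seed = 3)
  tr <- gen_mode_trajectory(base, modes, 1.5, noise_sd = 0.03,
                            n_frames = 2000, seed = 4)
  p <- pca_trajectory(tr, atom_selection())
  mv <- mode_vectors(p, 1)
  d <- as.vector(t(cbind(mv$dx, mv$dy, mv$dz)))
  cos_sim <- abs(sum(d * modes[, 1])) / sqrt(sum(d^2))
  expect_gt(cos_sim, 0.99)
  mv2 <- mode_vectors(p, 1, scale = 2)
  expect_equal(mv2$magnitude, 2 * mv$magnitude, tolerance = 1e-12)
  # a zero-eigenvalue mode has zero-length arrows
  r0 <- eigendecompose(diag(c(1, 0, 0)))
  r0$mean <- rep(0, 3)
  expect_equal(mode_vectors(r0, 3)$magnitude, 0)
})

test_that("pca eigenvalue sum equals rmsf squared sum under the shared protocol", {
  base <- gen_toy_structure(10, seed = 5)
  modes <- orthonormal_modes(base, 2, seed = 6)
  tr <- gen_mode_trajectory(base, modes, c(1, 0.5), noise_sd = 0.05,
                            n_frames = 300, seed = 7)
  p <- pca_trajectory(tr, atom_selection())
  prof <- rmsf(tr, atom_selection())
  expect_equal(sum(p$values), sum(prof$rmsf^2), tolerance = 1e-6)
})

test_that("projections of distinct modes are uncorrelated and tidiers are consistent", {
  base <- gen_toy_structure(10, seed = 9)
  modes <- orthonormal_modes(base, 2, seed = 10)
  tr <- gen_mode_trajectory(base, modes, c(1.4, 0.7), noise_sd = 0.05,
                            n_frames = 2000, seed = 11)
  p <- pca_trajectory(tr, atom_selection())
  pr <- project(tr, p, 1:2)
  r <- cor(dplyr::filter(pr, mode == 1)$value, dplyr::filter(pr, mode == 2)$value)
  expect_lt(abs(r), 3 / sqrt(2000))
  td <- tidy(p)
  expect_equal(td$eigenvalue, p$values)
  expect_equal(td$cumulative_fraction[nrow(td)], 1)
  gl <- glance(p)
  expect_equal(gl$n_frames, 2000)
  expect_equal(gl$variance_fraction_2, variance_fraction(p, 2))
})

test_that("planted-mode pca agrees with an independent pca implementation", {
  skip_if_not_installed("bio3d")
  base <- gen_toy_structure(12, seed = 13)
  modes <- orthonormal_modes(base, 2, seed = 14)
  tr <- gen_mode_trajectory(base, modes, c(1.5, 0.75), noise_sd = 0.05,
                            n_frames = 400, seed = 15)
  ours <- pca_trajectory(tr, atom_selection())
  theirs <- suppressWarnings(bio3d::pca.xyz(bio3d::fit.xyz(tr$xyz[1, ], tr$xyz)))
  expect_equal(ours$values[1:4], theirs$L[1:4], tolerance = 0.02)
})
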