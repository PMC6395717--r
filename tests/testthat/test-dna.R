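test_that("the B-DNA builder emits a well-formed duplex", {
  s <- build_bdna("ACGT")
  expect_equal(length(unique(paste(s$chain, s$resno))), 8)
  expect_equal(sort(unique(s$chain)), c("A", "B"))
  expect_error(build_bdna("ACGX"), "invalid base")
  expect_error(build_bdna("ACG"), "length >= 4")
  # complementary, antiparallel: chain B resno 1 pairs chain A resno n
  s23 <- build_bdna(duplex_sequence())
  expect_equal(s23$resid[s23$chain == "B" & s23$resno == 1][1],
               paste0("D", c(A = "T", C = "G", G = "C", T = "A")[[substr(duplex_sequence(), 23, 23)]]))
})

test_that("successive intra-strand phosphates sit at the fiber spacing", {
  s <- build_bdna(duplex_sequence())
  xyz <- coords(s)
  for (ch in c("A", "B")) {
    p_idx <- which(s$chain == ch & s$name == "P")
    ord <- p_idx[order(s$resno[p_idx])]
    d <- sqrt(rowSums(diff(xyz[ord, ])^2))
    expect_true(all(abs(d - 7.0) < 0.3))
  }
})

test_that("the fitted axis of an ideal duplex is straight", {
  s <- build_bdna(duplex_sequence())
  ann <- duplex_annotation(s)
  ax <- fit_axis(s, ann)
  pts <- cbind(ax$x, ax$y, ax$z)[!ax$flagged, ]
  c0 <- colMeans(pts)
  sv <- svd(sweep(pts, 2, c0))
  resid <- sweep(pts, 2, c0) - outer(as.vector(sweep(pts, 2, c0) %*% sv$v[, 1]), sv$v[, 1])
  expect_lt(sqrt(mean(rowSums(resid^2))), 0.3)
  tnorm <- sqrt(ax$tx^2 + ax$ty^2 + ax$tz^2)
  expect_equal(tnorm[!ax$flagged], rep(1, sum(!ax$flagged)), tolerance = 1e-8)
  bends <- axis_bend(ax)$bend
  expect_lt(max(bends, na.rm = TRUE), 1)
})

test_that("the axis is equivariant under rigid transforms", {
  s <- build_bdna(duplex_sequence())
  ann <- duplex_annotation(s)
  ax <- fit_axis(s, ann)
  set.seed(2)
  r <- random_rotation()
  shift <- c(5, -3, 11)
  xyz2 <- coords(s) %*% r + matrix(shift, nrow(s), 3, byrow = TRUE)
  ax2 <- fit_axis(s, ann, xyz = xyz2)
  ok <- !ax$flagged & !ax2$flagged
  expect_equal(cbind(ax2$x, ax2$y, ax2$z)[ok, ],
               cbind(ax$x, ax$y, ax$z)[ok, ] %*% r +
                 matrix(shift, sum(ok), 3, byrow = TRUE),
               tolerance = 1e-6)
  # groove widths and bends unchanged
  gw <- groove_widths(s, ann)
  gw2 <- groove_widths(s, ann, xyz = xyz2)
  expect_equal(gw2$major, gw$major, tolerance = 1e-8)
  expect_equal(axis_bend(ax2)$bend, axis_bend(ax)$bend, tolerance = 1e-5)
})

test_that("groove widths match canonical B-form values and the exhaustive oracle", {
  s <- build_bdna(duplex_sequence())
  ann <- duplex_annotation(s)
  gw <- groove_widths(s, ann)
  expect_lt(abs(mean(gw$major, na.rm = TRUE) - 12), 1)
  # interior uniformity
  interior <- gw$major[!is.na(gw$major)]
  expect_lt(diff(range(interior)), 0.5)
  # minor groove: exhaustive cross-strand P-P scan oracle (the global
  # cross-strand minimum is the minor-groove contact in B-DNA)
  xyz <- coords(s)
  pa <- xyz[s$chain == "A" & s$name == "P", , drop = FALSE]
  pb <- xyz[s$chain == "B" & s$name == "P", , drop = FALSE]
  k <- 12  # central level
  pk <- xyz[s$chain == "A" & s$name == "P" & s$resno == k, ]
  dists <- sqrt(colSums((t(pb) - pk)^2))
  expect_lt(abs(gw$minor[k] - (min(dists) - 5.8)), 0.2)
  # radial compression toward the axis shrinks every defined width
  radial <- xyz
  rho <- sqrt(rowSums(xyz[, 1:2]^2))
  shrink <- pmax(rho - 1, 0) / pmax(rho, 1e-9)
  radial[, 1:2] <- xyz[, 1:2] * shrink
  gw_c <- groove_widths(s, ann, xyz = radial)
  ok <- !is.na(gw$major)
  expect_true(all(gw_c$major[ok] < gw$major[ok]))
  expect_true(all(gw_c$minor[!is.na(gw$minor)] < gw$minor[!is.na(gw$minor)]))
})

test_that("planted circular arcs are recovered by the bend machinery", {
  sq <- duplex_sequence()
  tr <- gen_bent_duplex(sq, total_arc = 20)
  s <- tr$topology
  ann <- duplex_annotation(s)
  ax <- fit_axis(s, ann, xyz = frame_coords(tr, 1))
  tang <- cbind(ax$tx, ax$ty, ax$tz)
  ok <- which(!ax$flagged)
  turning <- three_point_angle(tang[ok[1], ], c(0, 0, 0), tang[ok[length(ok)], ])
  expect_lt(abs(turning - 20), 2)
  # per-level bend: 20 degrees spread over 22 steps, tangent span 2 levels
  bends <- axis_bend(ax)$bend
  interior <- bends[5:19]
  expect_true(all(abs(interior - 2 * 20 / 22) < 0.5))
  # doubling the window doubles the bend on a circular arc
  b2 <- axis_bend(ax, window = 2)$bend
  expect_equal(mean(b2[6:18] / bends[6:18]), 2, tolerance = 0.05)
})

test_that("bent duplexes reduce the gamma angle by half the arc", {
  # chords from the mid-arc point to the arc ends each subtend arc/2, so
  # the three-point gamma angle is 180 - arc/2 for a circular bend
  tr <- gen_bent_duplex(duplex_sequence(), total_arc = 40)
  s <- set_coords(tr$topology, frame_coords(tr, 1))
  ann <- duplex_annotation(s)
  g <- measure_angle(s, gamma_definition(ann))
  expect_lt(abs(g - (180 - 20)), 3)
  expect_error(gen_bent_duplex(duplex_sequence(), total_arc = 200), "< 180")
})

test_that("trajectory profiles aggregate per-frame recomputation exactly", {
  sq <- duplex_sequence()
  static <- gen_bent_duplex(sq, total_arc = 10, n_frames = 3)
  prof <- profile_over_trajectory(static, duplex_annotation(static$topology))
  expect_equal(max(prof$grooves$major_sd, na.rm = TRUE), 0)
  expect_equal(max(prof$bend$bend_sd, na.rm = TRUE), 0)
  # breathing duplex: means equal direct recomputation
  tr <- gen_bent_duplex(sq, total_arc = 15, thermal_sd = 0.05, n_frames = 4, seed = 8)
  ann <- duplex_annotation(tr$topology)
  prof2 <- profile_over_trajectory(tr, ann)
  direct <- sapply(1:4, function(k) {
    groove_widths(tr$topology, ann, xyz = frame_coords(tr, k))$major
  })
  expect_equal(prof2$grooves$major_mean, rowMeans(direct), tolerance = 1e-10)
  # two-frame alternation: mean is the midpoint
  fr1 <- frame_coords(tr, 1)
  fr2 <- frame_coords(tr, 2)
  tr2 <- md_trajectory(tr$topology, list(fr1, fr2), dt = 1)
  p2 <- profile_over_trajectory(tr2, ann)
  g1 <- groove_widths(tr$topology, ann, xyz = fr1)$major
  g2 <- groove_widths(tr$topology, ann, xyz = fr2)$major
  expect_equal(p2$grooves$major_mean, (g1 + g2) / 2, tolerance = 1e-10)
})
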