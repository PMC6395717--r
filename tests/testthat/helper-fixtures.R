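# Shared fixtures and independent oracles. Everything is generated in code;
# oracles are deliberately naive (loops, exhaustive search) and independent
# of the implementation paths they check.

toy_peptide <- function(n_res = 3, chain = "A") {
  at <- do.call(rbind, lapply(seq_len(n_res), function(i) {
    tibble::tibble(
      name = c("N", "CA", "C", "O"),
      resid = "ALA", resno = i, chain = chain,
      x = 3.8 * i + c(-0.5, 0, 0.5, 1.0),
      y = c(0.3, 0, -0.3, 0.8), z = c(0, 0.2, 0, -0.2)
    )
  }))
  md_structure(at)
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

# Dense rotation-search RMSD oracle: minimum over many random proper
# rotations of centred coordinates (translation handled by centring).
rmsd_rotation_search <- function(mobile, reference, n_rot = 40000) {
  a <- scale(mobile, scale = FALSE)
  b <- scale(reference, scale = FALSE)
  best <- Inf
  for (k in seq_len(n_rot)) {
    r <- random_rotation()
    best <- min(best, sqrt(mean(rowSums((a %*% r - b)^2))))
  }
  best
}

# Brute-force hydrogen-bond oracle: explicit loops over every
# donor-hydrogen-acceptor triple.
brute_force_hbonds <- function(structure, xyz, donors, acceptors, criteria) {
  donors <- donors[!structure$is_hydrogen[donors]]
  acceptors <- acceptors[!structure$is_hydrogen[acceptors]]
  res_key <- paste(structure$chain, structure$resno, structure$resid)
  h_all <- which(structure$is_hydrogen)
  out <- list()
  for (d in donors) {
    hs <- c()
    for (h in h_all) {
      if (res_key[h] == res_key[d]) {
        dd <- sqrt(sum((xyz[h, ] - xyz[d, ])^2))
        if (dd > 0 && dd <= 1.25) hs <- c(hs, h)
      }
    }
    if (length(hs) == 0) next
    for (a in acceptors) {
      if (a == d) next
      r <- sqrt(sum((xyz[d, ] - xyz[a, ])^2))
      if (r > criteria$distance_cut) next
      found <- FALSE
      for (h in hs) {
        ang <- if (criteria$angle_convention == "DHA-deviation") {
          u <- xyz[d, ] - xyz[h, ]; v <- xyz[a, ] - xyz[h, ]
          180 - acos(min(max(sum(u * v) / sqrt(sum(u^2) * sum(v^2)), -1), 1)) * 180 / pi
        } else {
          u <- xyz[h, ] - xyz[d, ]; v <- xyz[a, ] - xyz[d, ]
          acos(min(max(sum(u * v) / sqrt(sum(u^2) * sum(v^2)), -1), 1)) * 180 / pi
        }
        if (ang <= criteria$angle_cut) { found <- TRUE; break }
      }
      if (found) out[[length(out) + 1]] <- c(d, a)
    }
  }
  if (length(out) == 0) return(matrix(integer(), 0, 2))
  m <- do.call(rbind, out)
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

# Random small hydroxyl-donor/acceptor frames for oracle-equivalence tests.
random_hbond_frame <- function(n_groups = 20, seed = 1) {
  withr::with_seed(seed, {
    rows <- list()
    for (g in seq_len(n_groups)) {
      base <- stats::runif(3, -12, 12)
      hdir <- stats::rnorm(3); hdir <- hdir / sqrt(sum(hdir^2))
      rows[[length(rows) + 1]] <- tibble::tibble(
        name = c("OG", "HG", "O"),
        resid = c("SER", "SER", "GLY"),
        resno = g, chain = if (g %% 2 == 0) "A" else "B",
        x = base[1] + c(0, 0.96 * hdir[1], stats::runif(1, -4, 4)),
        y = base[2] + c(0, 0.96 * hdir[2], stats::runif(1, -4, 4)),
        z = base[3] + c(0, 0.96 * hdir[3], stats::runif(1, -4, 4))
      )
    }
  })
  md_structure(dplyr::bind_rows(rows))
}

# 23-bp sequence used throughout the DNA tests
duplex_sequence <- function() substr(strrep("ACGTT", 5), 1, 23)

expect_no_na <- function(x) expect_false(anyNA(x))
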