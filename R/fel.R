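#' Two-dimensional free-energy landscape by Boltzmann inversion
#'
#' Histograms two reaction-coordinate series (typically PC1 and PC2) and
#' converts bin populations to relative free energies,
#' `G = -k_B T ln(P / P_max)`, so the most populated bin sits at `G = 0`.
#' Energies are reported in units of `k_B T`; multiply by
#' `0.0019872041 * T_K` for kcal/mol. Empty bins carry `+Inf`.
#'
#' @param p1,p2 Numeric vectors of equal length (or tibbles from
#'   [project()], single mode each).
#' @param n_bins Number of bins per axis (>= 2; default 80).
#' @param T_K Temperature in kelvin (default 310, a typical simulation
#'   temperature); only used when converting out of `k_B T` units.
#' @param pad Fractional padding of the data range per side (default 0.05).
#' @return A `fel_grid` object: `axis1`/`axis2` bin edges, `counts`, `G`
#'   (k_B T), `T_K`, `n_frames`.
#' @export
fel_2d <- function(p1, p2, n_bins = 80, T_K = 310, pad = 0.05) {
  if (is.data.frame(p1)) p1 <- p1$value
  if (is.data.frame(p2)) p2 <- p2$value
  if (length(p1) != length(p2)) abort("reaction coordinates differ in length")
  if (n_bins < 2) abort("`n_bins` must be >= 2")
  if (T_K <= 0) abort("`T_K` must be positive")
  edges <- function(v) {
    r <- range(v)
    span <- diff(r)
    if (span == 0) span <- max(abs(r[1]), 1) * 1e-6
    seq(r[1] - pad * span, r[2] + pad * span, length.out = n_bins + 1)
  }
  a1 <- edges(p1)
  a2 <- edges(p2)
  i1 <- pmin(pmax(findInterval(p1, a1, rightmost.closed = TRUE), 1), n_bins)
  i2 <- pmin(pmax(findInterval(p2, a2, rightmost.closed = TRUE), 1), n_bins)
  counts <- matrix(0L, n_bins, n_bins)
  for (k in seq_along(i1)) counts[i1[k], i2[k]] <- counts[i1[k], i2[k]] + 1L
  if (sum(counts > 0) == 1) {
    warn("all frames fall into a single bin; landscape is degenerate")
  }
  G <- matrix(Inf, n_bins, n_bins)
  occ <- counts > 0
  G[occ] <- -log(counts[occ] / max(counts))
  structure(
    list(axis1 = a1, axis2 = a2, counts = counts, G = G, T_K = T_K,
         n_frames = length(p1)),
    class = "fel_grid"
  )
}

#' @export
print.fel_grid <- function(x, ...) {
  cat(sprintf(
    "<fel_grid> %d x %d bins, %d frames, T = %g K, max occupied G = %.2f kT\n",
    nrow(x$counts), ncol(x$counts), x$n_frames, x$T_K,
    max(x$G[is.finite(x$G)])
  ))
  invisible(x)
}

#' Tidy a free-energy grid into a long bin table
#'
#' One row per bin: `pc1`, `pc2` bin centres, `count`, `G` (k_B T) and
#' `G_kcal` (kcal/mol at the grid's temperature).
#'
#' @param x A `fel_grid` from [fel_2d()].
#' @param ... Unused.
#' @return A tibble with one row per bin.
#' @export
tidy.fel_grid <- function(x, ...) {
  mid <- function(e) (e[-1] + e[-length(e)]) / 2
  grid <- expand.grid(i = seq_len(nrow(x$counts)), j = seq_len(ncol(x$counts)))
  tibble(
    pc1 = mid(x$axis1)[grid$i],
    pc2 = mid(x$axis2)[grid$j],
    count = as.vector(x$counts),
    G = as.vector(x$G),
    G_kcal = as.vector(x$G) * KB_KCAL * x$T_K
  )
}

#' Detect local free-energy basins
#'
#' A basin is a contiguous (8-neighbourhood) region of occupied bins with
#' `G` below `depth_cut`, reported at its minimum bin; the minimum of each
#' region is necessarily a local minimum of the grid. Tying regions of
#' equal `G` (plateaus) are one basin, so a perfectly flat landscape
#' yields a single basin. Counting regions rather than raw local minima
#' keeps the basin count stable under bin-count sampling noise.
#'
#' @param grid A `fel_grid` from [fel_2d()].
#' @param depth_cut Threshold in k_B T above the global minimum (default
#'   2; small enough that sampling noise in sparsely populated bins stays
#'   above the cut).
#' @return A tibble sorted by `G_min` with bin coordinates (`i`, `j`),
#'   reaction-coordinate positions (`pc1`, `pc2`), `G_min`, `n_member_bins`
#'   and a list-column `members` of member bin index matrices.
#' @export
find_basins <- function(grid, depth_cut = 2) {
  G <- grid$G
  if (!any(is.finite(G))) abort("grid has no occupied bins")
  nb_i <- c(-1, -1, -1, 0, 0, 1, 1, 1)
  nb_j <- c(-1, 0, 1, -1, 1, -1, 0, 1)
  nr <- nrow(G)
  nc <- ncol(G)
  sub_cut <- is.finite(G) & G < depth_cut
  if (!any(sub_cut)) return(tibble(
    basin = integer(), i = integer(), j = integer(), pc1 = double(),
    pc2 = double(), G_min = double(), n_member_bins = integer(),
    members = list()
  ))
  # flood fill over a logical mask, 8-connectivity
  flood <- function(mask, si, sj) {
    comp <- matrix(FALSE, nr, nc)
    queue <- list(c(si, sj))
    comp[si, sj] <- TRUE
    while (length(queue) > 0) {
      cur <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      for (t in 1:8) {
        ii <- cur[1] + nb_i[t]; jj <- cur[2] + nb_j[t]
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
            mask[ii, jj] && !comp[ii, jj]) {
          comp[ii, jj] <- TRUE
          queue[[length(queue) + 1]] <- c(ii, jj)
        }
      }
    }
    which(comp, arr.ind = TRUE)
  }
  mid1 <- (grid$axis1[-1] + grid$axis1[-length(grid$axis1)]) / 2
  mid2 <- (grid$axis2[-1] + grid$axis2[-length(grid$axis2)]) / 2
  remaining <- sub_cut
  rows <- list()
  while (any(remaining)) {
    start <- which(remaining, arr.ind = TRUE)[1, ]
    members <- flood(remaining, start[1], start[2])
    remaining[members] <- FALSE
    gvals <- G[members]
    best <- members[which.min(gvals), , drop = FALSE]
    rows[[length(rows) + 1]] <- tibble(
      i = best[1, 1], j = best[1, 2],
      pc1 = mid1[best[1, 1]], pc2 = mid2[best[1, 2]],
      G_min = min(gvals),
      n_member_bins = nrow(members),
      members = list(members)
    )
  }
  out <- bind_rows(rows) |> arrange(.data$G_min)
  out$basin <- seq_len(nrow(out))
  select(out, "basin", "i", "j", "pc1", "pc2", "G_min", "n_member_bins", "members")
}

#' Export a free-energy grid as TSV files
#'
#' Writes the G matrix (k_B T) plus the two axis bin-centre files.
#'
#' @param grid A `fel_grid`.
#' @param prefix Output path prefix; writes `<prefix>_G.tsv`,
#'   `<prefix>_axis1.tsv`, `<prefix>_axis2.tsv`.
#' @return Invisibly, the paths written.
#' @export
write_fel_tsv <- function(grid, prefix) {
  gpath <- paste0(prefix, "_G.tsv")
  utils::write.table(grid$G, gpath, sep = "\t", row.names = FALSE, col.names = FALSE)
  mid <- function(e) (e[-1] + e[-length(e)]) / 2
  a1 <- paste0(prefix, "_axis1.tsv")
  a2 <- paste0(prefix, "_axis2.tsv")
  utils::write.table(mid(grid$axis1), a1, sep = "\t", row.names = FALSE, col.names = FALSE)
  utils::write.table(mid(grid$axis2), a2, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(c(gpath, a1, a2))
}
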