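#' Tile-bootstrap homogeneity of the aster distribution
#'
#' Splits the field into a `sqrt(n_tiles) x sqrt(n_tiles)` grid of equal
#' tiles, computes the filtered mean inter-vertex distance independently in
#' each tile, bootstraps the mean of the valid per-tile means (`B` resamples
#' with replacement) and summarises the bootstrap distribution with a
#' Gaussian kernel density estimate (Silverman's rule-of-thumb bandwidth).
#' A narrow density indicates a spatially homogeneous network. Tiles with
#' fewer than four vertices, a degenerate triangulation or no retained edge
#' are too small to analyse and are excluded.
#'
#' @param vertices A [vertex_set()].
#' @param extent_um `c(width, height)` of the field, micrometres; defaults
#'   to the vertex set's stored geometry.
#' @param n_tiles 16 or 64 (chosen by magnification).
#' @param B Number of bootstrap resamples (>= 100).
#' @param seed Integer seed for the resampling.
#' @param policy [edge_filter_policy()] applied within each tile.
#' @return An object of class `homogeneity_report`: `n_tiles`,
#'   `per_tile_mean_um` (NA for invalid tiles), `valid` (logical),
#'   `bootstrap_means_um` (length `B`), `kde_support`/`kde_density`, `B`,
#'   `seed`, and `insufficient` flag when fewer than two tiles are valid.
#' @export
tile_homogeneity <- function(vertices, extent_um = NULL, n_tiles = 16,
                             B = 1000, seed = 1L,
                             policy = edge_filter_policy()) {
  stopifnot(inherits(vertices, "vertex_set"))
  if (!n_tiles %in% c(16, 64)) stop("n_tiles must be 16 or 64")
  if (B < 100) stop("need at least 100 bootstrap resamples")
  if (is.null(extent_um)) {
    if (is.null(vertices$frame))
      stop("no image extent available: supply extent_um")
    extent_um <- c(vertices$frame$width_um, vertices$frame$height_um)
  }
  g <- as.integer(sqrt(n_tiles))
  tw <- extent_um[1] / g
  th <- extent_um[2] / g
  pos <- vertices$positions
  tx <- pmin(g - 1L, pmax(0L, floor(pos[, 1] / tw)))
  ty <- pmin(g - 1L, pmax(0L, floor(pos[, 2] / th)))
  tile_of <- tx + g * ty + 1L
  per_tile <- rep(NA_real_, n_tiles)
  for (t in seq_len(n_tiles)) {
    sel <- which(tile_of == t)
    if (length(sel) < 4) next
    mean_t <- tryCatch({
      del <- delaunay_edge_list(pos[sel, , drop = FALSE])
      len <- del$lengths
      len <- len[len >= policy$min_length_um & len <= policy$max_length_um]
      if (length(len) == 0) NA_real_ else mean(len)
    }, error = function(e) NA_real_)
    per_tile[t] <- mean_t
  }
  valid <- !is.na(per_tile)
  if (sum(valid) < 2) {
    return(structure(list(n_tiles = n_tiles, per_tile_mean_um = per_tile,
                          valid = valid, bootstrap_means_um = numeric(0),
                          kde_support = numeric(0), kde_density = numeric(0),
                          B = as.integer(B), seed = as.integer(seed),
                          insufficient = TRUE),
                     class = "homogeneity_report"))
  }
  means <- per_tile[valid]
  boot <- with_seed(seed, {
    vapply(seq_len(B), function(i) mean(sample(means, replace = TRUE)),
           numeric(1))
  })
  bw <- stats::bw.nrd0(boot)
  if (!is.finite(bw) || bw <= 0) {
    # degenerate case (all tile means identical): represent the point mass
    # as an extremely narrow Gaussian so the density still integrates to 1
    bw <- 1e-6 * max(1, abs(mean(boot)))
  }
  kde <- suppressWarnings(stats::density(boot, bw = bw, n = 512))
  structure(list(n_tiles = n_tiles, per_tile_mean_um = per_tile,
                 valid = valid, bootstrap_means_um = boot,
                 kde_support = kde$x, kde_density = kde$y,
                 B = as.integer(B), seed = as.integer(seed),
                 insufficient = FALSE),
            class = "homogeneity_report")
}

#' @export
print.homogeneity_report <- function(x, ...) {
  if (x$insufficient) {
    cat(sprintf("homogeneity_report: insufficient data (%d of %d tiles valid)\n",
                sum(x$valid), x$n_tiles))
    return(invisible(x))
  }
  cat(sprintf("homogeneity_report: %d tiles (%d valid), B = %d\n",
              x$n_tiles, sum(x$valid), x$B))
  cat(sprintf("  tile means: %.2f - %.2f um; bootstrap mean %.3f um (sd %.3f)\n",
              min(x$per_tile_mean_um, na.rm = TRUE),
              max(x$per_tile_mean_um, na.rm = TRUE),
              mean(x$bootstrap_means_um), stats::sd(x$bootstrap_means_um)))
  invisible(x)
}

#' @export
plot.homogeneity_report <- function(x, ...) {
  if (x$insufficient) stop("nothing to plot: insufficient tiles")
  graphics::plot(x$kde_support, x$kde_density, type = "l",
                 xlab = "bootstrap mean inter-vertex distance (um)",
                 ylab = "kernel density", ...)
  graphics::rug(x$per_tile_mean_um[x$valid])
  invisible(x)
}
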