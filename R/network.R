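# Delaunay connectivity and the network statistics derived from it.

# Unique Delaunay edge list of an n x 2 position matrix, via deldir.
# deldir resolves cocircular ties deterministically, so repeated calls on
# identical input give identical edge sets.
delaunay_edge_list <- function(positions) {
  n <- nrow(positions)
  if (n < 3) stop("degenerate input: need at least 3 vertices")
  if (qr(sweep(positions, 2, colMeans(positions)))$rank < 2)
    stop("degenerate input: all vertices are collinear")
  dd <- deldir::deldir(positions[, 1], positions[, 2], suppressMsge = TRUE)
  e <- as.matrix(dd$delsgs[, c("ind1", "ind2")])
  e <- t(apply(e, 1, sort))
  e <- unique(e)
  storage.mode(e) <- "integer"
  colnames(e) <- c("v1", "v2")
  lengths <- sqrt(rowSums((positions[e[, 1], , drop = FALSE] -
                           positions[e[, 2], , drop = FALSE])^2))
  list(edges = e, lengths = lengths)
}

#' Delaunay triangulation of detected vertices
#'
#' Connects the vertex set by a planar Delaunay triangulation — the
#' network's connectivity proxy — and records edge lengths in micrometres.
#' Vertices within `boundary_margin_um` of the image border are flagged:
#' their neighbourhoods are truncated by the field of view, so they are
#' excluded from degree statistics.
#'
#' @param vertices A [vertex_set()] with at least 3 non-collinear positions.
#' @param boundary_margin_um Width of the border exclusion zone,
#'   micrometres (default 20, the upper edge-length cut-off).
#' @param extent_um Optional `c(width, height)` of the field in micrometres;
#'   defaults to the geometry stored in the vertex set.
#' @return An object of class `aster_network`: `vertices`, `edges` (m x 2
#'   integer matrix), `lengths_um`, `boundary_flags`, `extent_um`,
#'   `boundary_margin_um`.
#' @examples
#' v <- vertex_set(cbind(c(0, 10, 5), c(0, 0, 8)))
#' triangulate(v, extent_um = c(10, 8))$edges
#' @export
triangulate <- function(vertices, boundary_margin_um = 20, extent_um = NULL) {
  stopifnot(inherits(vertices, "vertex_set"))
  pos <- vertices$positions
  del <- delaunay_edge_list(pos)
  if (is.null(extent_um)) {
    if (is.null(vertices$frame))
      stop("no image extent available: supply extent_um")
    extent_um <- c(vertices$frame$width_um, vertices$frame$height_um)
  }
  m <- boundary_margin_um
  flags <- pos[, 1] < m | pos[, 1] > extent_um[1] - m |
           pos[, 2] < m | pos[, 2] > extent_um[2] - m
  structure(list(
    vertices = vertices,
    edges = del$edges,
    lengths_um = del$lengths,
    boundary_flags = flags,
    extent_um = as.numeric(extent_um),
    boundary_margin_um = as.numeric(boundary_margin_um)
  ), class = "aster_network")
}

#' @export
print.aster_network <- function(x, ...) {
  cat(sprintf("aster_network: %d vertices, %d Delaunay edges (%d interior vertices)\n",
              nrow(x$vertices$positions), nrow(x$edges), sum(!x$boundary_flags)))
  invisible(x)
}

#' Edge-length filter policy
#'
#' Distances below `min_length_um` are handled at detection time by vertex
#' merging, and distances above `max_length_um` arise at the image edge or
#' in aster-free regions; triangulation edges outside the closed interval
#' `[min_length_um, max_length_um]` are excluded from all statistics.
#'
#' @param min_length_um Lower bound, micrometres (default 3).
#' @param max_length_um Upper bound, micrometres (default 20).
#' @return An object of class `edge_filter_policy`.
#' @export
edge_filter_policy <- function(min_length_um = 3, max_length_um = 20) {
  if (!(min_length_um > 0 && min_length_um < max_length_um))
    stop("need 0 < min_length_um < max_length_um")
  structure(list(min_length_um = as.numeric(min_length_um),
                 max_length_um = as.numeric(max_length_um)),
            class = "edge_filter_policy")
}

#' Filter triangulation edges by length
#'
#' @param network An `aster_network` from [triangulate()].
#' @param policy An [edge_filter_policy()].
#' @return A list of class `retained_edges`: `edges`, `lengths_um` (the
#'   retained subset), `retained` (logical over the network's edges),
#'   `n_short_rejected`, `n_long_rejected`.
#' @export
filter_edges <- function(network, policy = edge_filter_policy()) {
  stopifnot(inherits(network, "aster_network"))
  len <- network$lengths_um
  keep <- len >= policy$min_length_um & len <= policy$max_length_um
  structure(list(
    edges = network$edges[keep, , drop = FALSE],
    lengths_um = len[keep],
    retained = keep,
    n_short_rejected = sum(len < policy$min_length_um),
    n_long_rejected = sum(len > policy$max_length_um)
  ), class = "retained_edges")
}

#' Mean and standard deviation of retained edge lengths
#'
#' @param retained A `retained_edges` object (or numeric vector of lengths).
#' @return A list with `mean_um`, `sd_um`, `n`; all `NA` (flagged via
#'   `empty = TRUE`) when no edge survives the filter.
#' @export
edge_length_stats <- function(retained) {
  len <- if (inherits(retained, "retained_edges")) retained$lengths_um
         else as.numeric(retained)
  if (length(len) == 0)
    return(list(mean_um = NA_real_, sd_um = NA_real_, n = 0L, empty = TRUE))
  list(mean_um = mean(len),
       sd_um = if (length(len) > 1) stats::sd(len) else 0,
       n = length(len), empty = FALSE)
}

#' Neighbour-degree statistics over interior vertices
#'
#' Degree is the number of retained triangulation edges incident to a
#' vertex; statistics are taken over vertices away from the image border
#' (degrees below five occur only at the edge of the field, where the
#' neighbourhood is truncated). The median is reported because it is an
#' integer for any realistic degree distribution; spread is the
#' interquartile range with linear-interpolation quantiles.
#'
#' @param network An `aster_network`.
#' @param retained A `retained_edges` object; defaults to all edges.
#' @return A list with `median_degree`, `iqr`, `degrees` (interior-vertex
#'   degrees), `n_interior`; flagged empty when every vertex is a boundary
#'   vertex.
#' @export
degree_stats <- function(network, retained = NULL) {
  stopifnot(inherits(network, "aster_network"))
  edges <- if (is.null(retained)) network$edges else retained$edges
  nv <- nrow(network$vertices$positions)
  deg <- tabulate(c(edges[, 1], edges[, 2]), nbins = nv)
  interior <- !network$boundary_flags
  if (!any(interior))
    return(list(median_degree = NA_real_, iqr = NA_real_,
                degrees = integer(0), n_interior = 0L, empty = TRUE))
  d <- deg[interior]
  q <- stats::quantile(d, c(0.25, 0.75), type = 7, names = FALSE)
  list(median_degree = stats::median(d), iqr = q[2] - q[1],
       degrees = d, n_interior = sum(interior), empty = FALSE)
}

#' Vertex density scaled to one square millimetre
#'
#' The number of detected asters divided by the image area, scaled to
#' 1 mm^2. No edge correction is applied.
#'
#' @param vertices A [vertex_set()] (or a count).
#' @param extent_um `c(width, height)` of the analysed field in
#'   micrometres; defaults to the vertex set's stored geometry.
#' @return Vertices per square millimetre.
#' @export
vertex_density <- function(vertices, extent_um = NULL) {
  n <- if (inherits(vertices, "vertex_set")) nrow(vertices$positions)
       else as.numeric(vertices)
  if (is.null(extent_um)) {
    if (!inherits(vertices, "vertex_set") || is.null(vertices$frame))
      stop("no image extent available: supply extent_um")
    extent_um <- c(vertices$frame$width_um, vertices$frame$height_um)
  }
  area_mm2 <- extent_um[1] * extent_um[2] / 1e6
  if (!is.finite(area_mm2) || area_mm2 <= 0) stop("image area must be positive")
  n / area_mm2
}

#' Vertex count of the equilateral-hexagon packing model
#'
#' In a perfectly regular triangular (equilateral-hexagon) arrangement with
#' lattice constant `a` (the average inter-vertex distance), neighbouring
#' rows are `sqrt(3)/2 * a` apart, so 1 mm^2 holds
#' `N(a) = (1000 / a) * (1000 / (sqrt(3)/2 * a))` vertices.
#'
#' @param a_um Average inter-vertex distance in micrometres (> 0).
#' @return Model vertex count per square millimetre.
#' @examples
#' hexagon_model_count(10)   # 11547.005
#' @export
hexagon_model_count <- function(a_um) {
  if (any(!is.finite(a_um)) || any(a_um <= 0))
    stop("lattice constant must be positive")
  (1000 / a_um) * (1000 / (sqrt(3) / 2 * a_um))
}

#' Correlation of observed vertex density to the hexagon model
#'
#' Ratio of the observed density to the model count evaluated at the
#' observed mean spacing; values near 1 indicate the network packs like a
#' regular equilateral-hexagon lattice. The relative deviation is
#' `abs(ratio - 1)`.
#'
#' @param observed_density_per_mm2 Observed vertices per mm^2 (>= 0).
#' @param a_um Observed average inter-vertex distance, micrometres.
#' @return The dimensionless ratio observed / model.
#' @examples
#' round(hexagon_correlation(7697, 11.8), 3)  # 0.928
#' @export
hexagon_correlation <- function(observed_density_per_mm2, a_um) {
  if (any(observed_density_per_mm2 < 0)) stop("density must be non-negative")
  observed_density_per_mm2 / hexagon_model_count(a_um)
}
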