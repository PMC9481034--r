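# Shared fixtures and independent oracles for the test suite.

PX <- 0.366  # default pixel calibration, um per pixel

# A single 6-limb aster centred at (cx, cy) with limb length r.
make_star_truth <- function(cx, cy, r = 11, field = 60) {
  ang <- (0:5) * pi / 3
  pos <- rbind(c(cx, cy), cbind(cx + r * cos(ang), cy + r * sin(ang)))
  colnames(pos) <- c("x_um", "y_um")
  structure(list(positions = pos, edges = cbind(1L, 2:7),
                 lattice_constant_um = r,
                 field_width_um = field, field_height_um = field),
            class = "ground_truth_network")
}

# Spec for rendering sparse hand-built truths: single strand, no offset.
sparse_render_spec <- function(field = 60, seed = 2) {
  aster_field_spec(field_width_um = field, field_height_um = field,
                   lattice_constant_um = min(11, field / 3), pixel_size_um = PX,
                   strand_count_min = 1, strand_count_max = 1,
                   strand_offset_um = 0, seed = seed)
}

# Small dense synthetic field shared by several detection tests.
small_dense_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- aster_field_spec(field_width_um = 180, field_height_um = 180,
                               lattice_constant_um = 11, jitter_fraction = 0.1,
                               pixel_size_um = PX, seed = 7)
      cache <<- simulate_aster_field(spec)
    }
    cache
  }
})

# O(n^4) empty-circumcircle Delaunay oracle: an edge (i, j) is Delaunay iff
# some circle through i and j contains no other point. For small n we test
# every triangle's circumcircle plus the convex-hull edges.
brute_delaunay_edges <- function(pts) {
  n <- nrow(pts)
  stopifnot(n >= 3)
  edges <- matrix(integer(0), 0, 2)
  add_edge <- function(i, j) {
    e <- sort(c(i, j))
    if (!any(edges[, 1] == e[1] & edges[, 2] == e[2]))
      edges <<- rbind(edges, e)
  }
  circumcircle <- function(a, b, c) {
    d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) + c[1] * (a[2] - b[2]))
    if (abs(d) < 1e-12) return(NULL)
    ux <- (sum(a^2) * (b[2] - c[2]) + sum(b^2) * (c[2] - a[2]) +
             sum(c^2) * (a[2] - b[2])) / d
    uy <- (sum(a^2) * (c[1] - b[1]) + sum(b^2) * (a[1] - c[1]) +
             sum(c^2) * (b[1] - a[1])) / d
    c(ux, uy, sqrt((a[1] - ux)^2 + (a[2] - uy)^2))
  }
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    cc <- circumcircle(pts[i, ], pts[j, ], pts[k, ])
    if (is.null(cc)) next
    others <- setdiff(seq_len(n), c(i, j, k))
    dists <- sqrt((pts[others, 1] - cc[1])^2 + (pts[others, 2] - cc[2])^2)
    if (all(dists > cc[3] + 1e-9)) {
      add_edge(i, j); add_edge(j, k); add_edge(i, k)
    }
  }
  edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
}

# Brute-force transitive closure of the strict proximity relation, the
# oracle for single-linkage merge clusters.
brute_proximity_clusters <- function(pos, min_sep) {
  n <- nrow(pos)
  cl <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i != j && sqrt(sum((pos[i, ] - pos[j, ])^2)) < min_sep &&
          cl[i] != cl[j]) {
        cl[cl == cl[j]] <- cl[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  as.integer(factor(cl))
}

# Perfect triangular-lattice points (for degree and density oracles).
triangular_lattice <- function(a, n_cols, n_rows) {
  do.call(rbind, lapply(seq_len(n_rows) - 1L, function(j) {
    off <- if (j %% 2L == 1L) a / 2 else 0
    cbind(x_um = (seq_len(n_cols) - 1L) * a + off,
          y_um = j * sqrt(3) / 2 * a)
  }))
}
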