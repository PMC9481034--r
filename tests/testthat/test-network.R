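test_that("triangulation handles canonical small configurations", {
  # 3 non-collinear points: one triangle
  n3 <- triangulate(vertex_set(rbind(c(0, 0), c(10, 0), c(5, 8))),
                    extent_um = c(10, 8))
  expect_equal(nrow(n3$edges), 3)
  # unit square: 5 edges, one diagonal picked deterministically
  sq <- triangulate(vertex_set(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))),
                    extent_um = c(1, 1))
  expect_equal(nrow(sq$edges), 5)
  sq2 <- triangulate(vertex_set(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))),
                     extent_um = c(1, 1))
  expect_identical(sq$edges, sq2$edges)
  # degenerate inputs
  expect_error(triangulate(vertex_set(rbind(c(0, 0), c(1, 1))),
                           extent_um = c(1, 1)), "degenerate|at least 3")
  expect_error(triangulate(vertex_set(rbind(c(0, 0), c(1, 1), c(2, 2), c(3, 3))),
                           extent_um = c(3, 3)), "collinear")
})

test_that("Delaunay edges match the brute-force empty-circumcircle oracle", {
  set.seed(17)
  for (rep in 1:8) {
    n <- sample(5:12, 1)
    pts <- cbind(runif(n, 0, 100), runif(n, 0, 100))
    net <- triangulate(vertex_set(pts), extent_um = c(100, 100))
    oracle <- brute_delaunay_edges(pts)
    got <- net$edges[order(net$edges[, 1], net$edges[, 2]), , drop = FALSE]
    expect_equal(unname(got), unname(oracle))
    expect_lte(nrow(net$edges), 3 * n - 6)
    expect_true(all(net$lengths_um > 0))
  }
})

test_that("perfect lattice interior vertices have six neighbours", {
  pts <- triangular_lattice(10, 7, 7)
  net <- triangulate(vertex_set(pts), boundary_margin_um = 12,
                     extent_um = c(max(pts[, 1]), max(pts[, 2])))
  ds <- degree_stats(net, filter_edges(net, edge_filter_policy(3, 20)))
  expect_equal(ds$median_degree, 6)
  expect_equal(ds$iqr, 0)
  expect_true(all(ds$degrees == 6))
  # hexagon of 6 points around a centre: centre has degree 6
  hexa <- rbind(c(0, 0), 10 * cbind(cos((0:5) * pi / 3), sin((0:5) * pi / 3)))
  hnet <- triangulate(vertex_set(hexa + 20), boundary_margin_um = 5,
                      extent_um = c(40, 40))
  deg <- tabulate(c(hnet$edges), nbins = 7)
  expect_equal(deg[1], 6)
})

test_that("edge filtering applies a closed interval and reports rejections", {
  # synthetic network object with known lengths {2, 5, 10, 25}
  pts <- rbind(c(0, 0), c(2, 0), c(7, 0), c(17, 0), c(42, 0), c(20, 30))
  net <- triangulate(vertex_set(pts), extent_um = c(42, 30))
  lengths <- c(2, 5, 10, 25)
  fake <- net
  fake$edges <- cbind(1:4, 2:5)
  fake$lengths_um <- lengths
  got <- filter_edges(fake, edge_filter_policy(3, 20))
  expect_equal(got$lengths_um, c(5, 10))
  expect_equal(got$n_short_rejected, 1)
  expect_equal(got$n_long_rejected, 1)
  # closed interval: boundary values retained
  fake$lengths_um <- c(3, 20, 2.999, 20.001)
  got2 <- filter_edges(fake, edge_filter_policy(3, 20))
  expect_equal(sort(got2$lengths_um), c(3, 20))
  # all inside -> identity
  fake$lengths_um <- c(5, 6, 7, 8)
  expect_equal(filter_edges(fake, edge_filter_policy(3, 20))$lengths_um,
               c(5, 6, 7, 8))
})

test_that("edge-length statistics match a streaming oracle", {
  expect_equal(edge_length_stats(c(5, 10))$mean_um, 7.5)
  pts <- triangular_lattice(10, 6, 6)
  net <- triangulate(vertex_set(pts), extent_um = c(60, 52))
  # the hull staircase contributes sqrt(3)*a edges; keep only lattice edges
  fil <- filter_edges(net, edge_filter_policy(3, 12))
  st <- edge_length_stats(fil)
  expect_equal(st$mean_um, 10, tolerance = 1e-9)
  expect_equal(st$sd_um, 0, tolerance = 1e-6)
  # one-pass (Welford) oracle against the two-pass implementation
  set.seed(3)
  x <- runif(1e4, 3, 20)
  m <- 0; s <- 0
  for (i in seq_along(x)) {
    d <- x[i] - m
    m <- m + d / i
    s <- s + d * (x[i] - m)
  }
  st2 <- edge_length_stats(x)
  expect_equal(st2$mean_um, m, tolerance = 1e-12)
  expect_equal(st2$sd_um, sqrt(s / (length(x) - 1)), tolerance = 1e-12)
  expect_true(edge_length_stats(numeric(0))$empty)
})

test_that("vertex density scales counts to one square millimetre", {
  # 100 vertices in 0.1 mm^2
  expect_equal(vertex_density(100, extent_um = c(500, 200)), 1000)
  # translation invariance
  pts <- cbind(runif(50, 0, 100), runif(50, 0, 100))
  v1 <- vertex_density(vertex_set(pts), extent_um = c(100, 100))
  v2 <- vertex_density(vertex_set(pts + 5), extent_um = c(100, 100))
  expect_equal(v1, v2)
  expect_error(vertex_density(10, extent_um = c(0, 100)), "positive")
  # growing windows of a perfect lattice approach 2 / (sqrt(3) a^2)
  a <- 10
  pts_big <- triangular_lattice(a, 120, 139)  # ~1190 x 1195 um
  for (w in c(400, 800, 1100)) {
    sel <- pts_big[, 1] <= w & pts_big[, 2] <= w
    dens <- sum(sel) / (w * w / 1e6)
    expect_lt(abs(dens / hexagon_model_count(a) - 1), 0.04)
  }
})

test_that("hexagon packing model evaluates and inverts correctly", {
  # oracle: N(a) = 2e6 / (sqrt(3) a^2)
  expect_equal(hexagon_model_count(10), 2e6 / (sqrt(3) * 100),
               tolerance = 1e-12)
  expect_equal(hexagon_model_count(10), 11547.005, tolerance = 1e-7)
  expect_equal(hexagon_model_count(1000), 1.1547005, tolerance = 1e-6)
  a <- c(5, 8, 13, 21)
  expect_true(all(diff(hexagon_model_count(a)) < 0))
  expect_equal(var(hexagon_model_count(a) * a^2), 0, tolerance = 1e-12)
  expect_error(hexagon_model_count(0))
  expect_equal(hexagon_correlation(hexagon_model_count(7.3), 7.3), 1)
})

test_that("printed worked example: 7697 per mm^2 at 11.8 um gives 0.928", {
  expect_equal(round(hexagon_correlation(7697, 11.8), 3), 0.928)
})

test_that("statistics are scale-equivariant", {
  set.seed(8)
  pts <- cbind(runif(40, 0, 200), runif(40, 0, 200))
  for (s in c(0.5, 2, 3.7)) {
    n1 <- triangulate(vertex_set(pts), extent_um = c(200, 200))
    n2 <- triangulate(vertex_set(pts * s), extent_um = c(200, 200) * s)
    m1 <- mean(n1$lengths_um)
    m2 <- mean(n2$lengths_um)
    expect_equal(m2, s * m1, tolerance = 1e-9)
    d1 <- vertex_density(vertex_set(pts), extent_um = c(200, 200))
    d2 <- vertex_density(vertex_set(pts * s), extent_um = c(200, 200) * s)
    expect_equal(d2, d1 / s^2, tolerance = 1e-9)
    expect_equal(hexagon_correlation(d2, m2), hexagon_correlation(d1, m1),
                 tolerance = 1e-9)
  }
})

test_that("jittered lattices stay within 5% of the hexagon model", {
  for (seed in c(2, 12)) {
    spec <- aster_field_spec(field_width_um = 600, field_height_um = 600,
                             lattice_constant_um = 11, jitter_fraction = 0.15,
                             pixel_size_um = 1, seed = seed)
    gt <- generate_vertex_layout(spec)
    net <- triangulate(vertex_set(gt$positions), extent_um = c(600, 600))
    fil <- filter_edges(net, edge_filter_policy(3, 20))
    dens <- vertex_density(nrow(gt$positions), extent_um = c(600, 600))
    corr <- hexagon_correlation(dens, mean(fil$lengths_um))
    expect_lt(abs(corr - 1), 0.05)
  }
})

test_that("tile bootstrap summarises spatial homogeneity reproducibly", {
  spec <- aster_field_spec(field_width_um = 600, field_height_um = 600,
                           lattice_constant_um = 11, jitter_fraction = 0.1,
                           pixel_size_um = 1, seed = 4)
  gt <- generate_vertex_layout(spec)
  v <- vertex_set(gt$positions)
  h1 <- tile_homogeneity(v, extent_um = c(600, 600), n_tiles = 16,
                         B = 500, seed = 99)
  h2 <- tile_homogeneity(v, extent_um = c(600, 600), n_tiles = 16,
                         B = 500, seed = 99)
  expect_identical(h1$bootstrap_means_um, h2$bootstrap_means_um)
  expect_false(h1$insufficient)
  expect_equal(sum(h1$valid), 16)
  # KDE integrates to 1 on its support
  integral <- sum(diff(h1$kde_support) *
                    (head(h1$kde_density, -1) + tail(h1$kde_density, -1)) / 2)
  expect_lt(abs(integral - 1), 1e-3)
  # bootstrap grand mean within 3 standard errors of the tile-mean average
  means <- h1$per_tile_mean_um[h1$valid]
  se <- sd(means) / sqrt(length(means)) / sqrt(h1$B)
  expect_lt(abs(mean(h1$bootstrap_means_um) - mean(means)), 3 * se)
  # 64 tiles also valid on this field
  h64 <- tile_homogeneity(v, extent_um = c(600, 600), n_tiles = 64,
                          B = 200, seed = 1)
  expect_false(h64$insufficient)
  expect_error(tile_homogeneity(v, extent_um = c(600, 600), n_tiles = 25,
                                B = 200), "16 or 64")
  expect_error(tile_homogeneity(v, extent_um = c(600, 600), n_tiles = 16,
                                B = 50), "100")
})

test_that("degenerate tile patterns are flagged, identical tiles give a spike", {
  # too few populated tiles
  pos <- cbind(runif(20, 0, 140), runif(20, 0, 140))  # one tile of a 600-field
  h <- tile_homogeneity(vertex_set(pos), extent_um = c(600, 600),
                        n_tiles = 16, B = 100, seed = 1)
  expect_true(h$insufficient)
  # identical per-tile patterns: bootstrap spread 0, KDE a spike at the mean
  base <- triangular_lattice(10, 4, 4)
  tiles <- do.call(rbind, lapply(0:15, function(t) {
    sweep(base, 2, c((t %% 4) * 150 + 20, (t %/% 4) * 150 + 20), `+`)
  }))
  hs <- tile_homogeneity(vertex_set(tiles), extent_um = c(600, 600),
                         n_tiles = 16, B = 100, seed = 2)
  expect_false(hs$insufficient)
  expect_equal(sd(hs$bootstrap_means_um), 0)
  common <- mean(hs$per_tile_mean_um)
  expect_lt(diff(range(hs$kde_support)), 1e-3 * max(1, common))
  expect_lt(abs(hs$kde_support[which.max(hs$kde_density)] - common), 1e-4)
})
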