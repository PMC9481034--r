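test_that("line kernels are zero-mean, unit-norm and symmetric in angle", {
  bank <- build_line_kernels(15, 21)
  expect_length(bank$kernels, 15)
  expect_equal(bank$angles, (0:14) * pi / 15)
  for (k in bank$kernels) {
    expect_equal(sum(k), 0, tolerance = 1e-12)
    expect_equal(sum(k^2), 1, tolerance = 1e-12)
  }
  # undirected lines: kernel at theta equals kernel at theta + pi
  for (th in c(0, 0.4, 1.1, 2.2)) {
    expect_equal(asternet:::line_kernel(th, 21),
                 asternet:::line_kernel(th + pi, 21), tolerance = 1e-9)
  }
  # n_angles = 2: horizontal and vertical
  b2 <- build_line_kernels(2, 9)
  expect_equal(b2$kernels[[1]], t(b2$kernels[[2]]), tolerance = 1e-9)
  expect_error(build_line_kernels(1, 9))
  expect_error(build_line_kernels(4, 2))
})

test_that("constant images give zero orientation response everywhere", {
  img <- image_frame(matrix(37, 64, 64), 1)
  resp <- orientation_correlation(img, build_line_kernels(4, 9))
  expect_lt(max(abs(resp$combined_map)), 1e-6)
})

test_that("per-angle responses identify the orientation of a bright line", {
  # 64 x 64 image with one bright anti-aliased line through the centre
  n_ang <- 8
  for (j in c(1, 3, 6)) {
    theta <- (j - 1) * pi / n_ang
    img <- matrix(0, 64, 64)
    ctr <- c(31.5, 31.5)
    seg <- asternet:::segment_coverage(c(64, 64),
                                       ctr - 28 * c(cos(theta), sin(theta)),
                                       ctr + 28 * c(cos(theta), sin(theta)), 0.7)
    img[seg$idx] <- img[seg$idx] + seg$cov
    resp <- orientation_correlation(image_frame(img, 1),
                                    build_line_kernels(n_ang, 15))
    centre_vals <- vapply(resp$per_angle_maps, function(m) m[32, 32], numeric(1))
    expect_equal(which.max(centre_vals), j)
  }
})

test_that("combined response peaks at a star junction above its limbs", {
  spec <- sparse_render_spec(field = 60)
  truth <- make_star_truth(30, 30, r = 11, field = 60)
  img <- render_aster_image(truth, spec)
  bank <- build_line_kernels(15, round(8 / PX))
  resp <- orientation_correlation(img, bank)
  px <- spec$pixel_size_um
  at <- function(map, x, y) map[round(y / px) + 1, round(x / px) + 1]
  junction <- at(resp$combined_map, 30, 30)
  # points along one limb, away from both endpoints
  limb_vals <- sapply(seq(3.5, 8.5, by = 1), function(r)
    at(resp$combined_map, 30 + r * cos(pi / 3), 30 + r * sin(pi / 3)))
  expect_true(junction > max(limb_vals))
  # elongation must not reduce the junction-to-limb contrast
  respE <- elongate_responses(resp, detection_params())
  junctionE <- at(respE$combined_map, 30, 30)
  limbE <- sapply(seq(3.5, 8.5, by = 1), function(r)
    at(respE$combined_map, 30 + r * cos(pi / 3), 30 + r * sin(pi / 3)))
  expect_gte(junctionE / max(limbE), junction / max(limb_vals))
})

test_that("elongation is linear and validates its factor", {
  img <- image_frame(matrix(5, 48, 48), 1)
  resp <- orientation_correlation(img, build_line_kernels(4, 9))
  out <- elongate_responses(resp, detection_params())
  expect_lt(max(abs(out$combined_map)), 1e-6)  # zero in, zero out
  p_bad <- detection_params()
  p_bad$elongation_factor <- 1
  expect_error(elongate_responses(resp, p_bad), "elongation_factor")
})

test_that("segmentation finds isolated asters to sub-micrometre accuracy", {
  # sparse scenes: threshold above the star's limb responses
  p_sparse <- detection_params(threshold_quantile = 0.99)
  spec <- sparse_render_spec(field = 60)
  img1 <- add_noise(render_aster_image(make_star_truth(30, 30), spec), spec)
  v1 <- detect_vertices(img1, p_sparse)
  expect_equal(nrow(v1$positions), 1)
  expect_lt(sqrt(sum((v1$positions[1, ] - c(30, 30))^2)), 1)

  spec2 <- aster_field_spec(field_width_um = 90, field_height_um = 90,
                            lattice_constant_um = 11, pixel_size_um = PX,
                            strand_count_min = 1, strand_count_max = 1,
                            strand_offset_um = 0, seed = 4)
  s1 <- make_star_truth(30, 45, field = 90)
  s2 <- make_star_truth(60, 45, field = 90)
  two <- structure(list(positions = rbind(s1$positions, s2$positions),
                        edges = rbind(cbind(1L, 2:7), cbind(8L, 9:14)),
                        lattice_constant_um = 11,
                        field_width_um = 90, field_height_um = 90),
                   class = "ground_truth_network")
  v2 <- detect_vertices(add_noise(render_aster_image(two, spec2), spec2),
                        p_sparse)
  expect_equal(nrow(v2$positions), 2)
  d <- evaluate_detection(v2, rbind(c(30, 45), c(60, 45)), tol_um = 1)
  expect_equal(d$n_matched, 2)
})

test_that("signal-free images produce an empty, flagged vertex set", {
  spec <- sparse_render_spec(field = 80)
  blank <- add_noise(image_frame(matrix(spec$background_level,
                                        219, 219), PX), spec, seed = 5)
  v <- detect_vertices(blank)
  expect_equal(nrow(v$positions), 0)
  expect_true(v$empty)
  vc <- detect_vertices(image_frame(matrix(7, 219, 219), PX))
  expect_equal(nrow(vc$positions), 0)
})

test_that("sub-separation merging follows the strict 3 um rule", {
  # two vertices 2 um apart, equal scores -> single vertex at the midpoint
  v <- vertex_set(rbind(c(10, 10), c(12, 10)), c(1, 1))
  m <- merge_close_vertices(v, 3)
  expect_equal(nrow(m$positions), 1)
  expect_equal(unname(m$positions[1, ]), c(11, 10))
  # exactly 3.0 um apart -> both kept (strictly-less-than threshold)
  v2 <- vertex_set(rbind(c(10, 10), c(13, 10)), c(1, 1))
  expect_equal(nrow(merge_close_vertices(v2, 3)$positions), 2)
  # collinear chain 0, 2, 4 um -> one vertex by transitive closure
  v3 <- vertex_set(rbind(c(0, 5), c(2, 5), c(4, 5)), c(1, 1, 1))
  expect_equal(nrow(merge_close_vertices(v3, 3)$positions), 1)
  # weighted centroid: scores 3 and 1 pull the merged vertex to the heavier
  v4 <- vertex_set(rbind(c(0, 0), c(2, 0)), c(3, 1))
  expect_equal(unname(merge_close_vertices(v4, 3)$positions[1, ]), c(0.5, 0))
})

test_that("merge clusters agree with a brute-force transitive closure", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    pos <- cbind(runif(n, 0, 15), runif(n, 0, 15))
    cl <- brute_proximity_clusters(pos, 3)
    merged <- merge_close_vertices(vertex_set(pos, rep(1, n)), 3)
    # at least as many merges as the one-pass closure; all final pairs >= 3
    expect_lte(nrow(merged$positions), length(unique(cl)))
    if (nrow(merged$positions) >= 2)
      expect_gte(min(dist(merged$positions)), 3)
    # idempotence
    again <- merge_close_vertices(merged, 3)
    expect_equal(again$positions, merged$positions, tolerance = 1e-12)
  }
})

test_that("dense-field detection recovers the planted vertices", {
  sim <- small_dense_sim()
  v <- detect_vertices(sim$image)
  ev <- evaluate_detection(v, sim$truth$positions, tol_um = 2,
                           boundary_margin_um = 11,
                           extent_um = c(sim$image$width_um,
                                         sim$image$height_um))
  expect_gte(ev$precision, 0.95)
  expect_gte(ev$recall, 0.95)
  expect_lt(ev$mean_match_error_um, 1)
})

test_that("raising the threshold quantile does not inflate vertex counts", {
  sim <- small_dense_sim()
  counts <- vapply(c(0.6, 0.7, 0.8, 0.9, 0.95), function(q) {
    nrow(detect_vertices(sim$image,
                         detection_params(threshold_quantile = q))$positions)
  }, numeric(1))
  # non-increasing up to a 1% slack for threshold-split component topology
  expect_true(all(diff(counts) <= pmax(1, 0.01 * counts[-length(counts)])))
  expect_lt(counts[length(counts)], counts[1])
})

test_that("detection commutes with a 90-degree rotation of the image", {
  sim <- small_dense_sim()
  m <- sim$image$intensities
  rot <- image_frame(t(m[nrow(m):1, ]), PX)  # clockwise rotation
  v0 <- detect_vertices(sim$image)
  v1 <- detect_vertices(rot)
  h_um <- (nrow(m) - 1) * PX
  mapped <- cbind(h_um - v0$positions[, 2], v0$positions[, 1])
  ev <- evaluate_detection(v1$positions, mapped, tol_um = PX,
                           boundary_margin_um = 11,
                           extent_um = c(rot$width_um, rot$height_um))
  expect_gte(ev$precision, 0.95)
  expect_gte(ev$recall, 0.95)
})

test_that("staged and fused detection paths agree away from the border", {
  sim <- small_dense_sim()
  img <- sim$image
  p <- detection_params()
  len_px <- as.integer(round(p$line_length_um / PX))
  bank <- build_line_kernels(p$n_angles, len_px, p$line_width_px)
  staged <- segment_vertices(elongate_responses(
    orientation_correlation(img, bank), p), img, p)
  staged <- merge_close_vertices(staged, p$min_separation_um)
  fused <- detect_vertices(img, p)
  ev <- evaluate_detection(fused, staged, tol_um = 0.25,
                           boundary_margin_um = 17,
                           extent_um = c(img$width_um, img$height_um))
  expect_gte(ev$precision, 0.98)
  expect_gte(ev$recall, 0.98)
})
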