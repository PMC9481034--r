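#' Generate the ground-truth vertex layout of a synthetic aster field
#'
#' Places vertices on a triangular lattice (row spacing `sqrt(3)/2 * a`,
#' alternate rows offset by `a/2`), displaces each by an isotropic uniform
#' jitter drawn from a disc of radius `jitter_fraction * a`, and deletes each
#' vertex independently with probability `missing_vertex_prob`. Ground-truth
#' connectivity is the Delaunay triangulation of the final (jittered)
#' positions — the same connectivity proxy the analysis uses.
#'
#' @param spec An [aster_field_spec()].
#' @param seed Seed for the jitter/dropout draws; defaults to `spec$seed`.
#' @return An object of class `ground_truth_network`: a list with
#'   `positions` (n x 2 matrix, columns `x_um`, `y_um`), `edges` (m x 2
#'   integer matrix of vertex indices), `lattice_constant_um`, and the field
#'   extent.
#' @examples
#' spec <- aster_field_spec(field_width_um = 30, field_height_um = 30,
#'                          lattice_constant_um = 10, jitter_fraction = 0)
#' nrow(generate_vertex_layout(spec)$positions)  # 14
#' @export
generate_vertex_layout <- function(spec, seed = spec$seed) {
  spec <- validate_aster_field_spec(spec)
  a <- spec$lattice_constant_um
  w <- spec$field_width_um
  h <- spec$field_height_um
  row_h <- sqrt(3) / 2 * a
  tol <- 1e-9 * a
  n_rows <- floor(h / row_h + tol) + 1L
  if (n_rows < 3L)
    stop("configuration error: field too small for >= 3 lattice rows")
  pts <- do.call(rbind, lapply(seq_len(n_rows) - 1L, function(j) {
    off <- if (j %% 2L == 1L) a / 2 else 0
    if (off > w + tol) return(NULL)
    x <- seq(off, w + tol, by = a)
    cbind(x_um = x, y_um = rep(j * row_h, length(x)))
  }))
  pts <- with_seed(seed, {
    n <- nrow(pts)
    r <- spec$jitter_fraction * a * sqrt(stats::runif(n))
    phi <- stats::runif(n, 0, 2 * pi)
    jittered <- pts + cbind(r * cos(phi), r * sin(phi))
    keep <- stats::runif(n) >= spec$missing_vertex_prob
    jittered[keep, , drop = FALSE]
  })
  # jitter may push points marginally outside the field; clamp back in
  pts[, 1] <- pmin(w, pmax(0, pts[, 1]))
  pts[, 2] <- pmin(h, pmax(0, pts[, 2]))
  colnames(pts) <- c("x_um", "y_um")
  edges <- if (nrow(pts) >= 3) delaunay_edge_list(pts)$edges
           else matrix(integer(0), 0, 2)
  structure(list(
    positions = pts,
    edges = edges,
    lattice_constant_um = a,
    field_width_um = w,
    field_height_um = h
  ), class = "ground_truth_network")
}

#' @export
print.ground_truth_network <- function(x, ...) {
  cat(sprintf("ground_truth_network: %d vertices, %d Delaunay edges, a = %.3g um in %.1f x %.1f um\n",
              nrow(x$positions), nrow(x$edges), x$lattice_constant_um,
              x$field_width_um, x$field_height_um))
  invisible(x)
}

#' Render a noiseless fluorescence image of an aster network
#'
#' Draws every ground-truth edge as `k` bright anti-aliased strands
#' (`k` uniform on `[strand_count_min, strand_count_max]`), each offset
#' perpendicular to the edge by a uniform draw within
#' `strand_offset_um`, with sub-pixel endpoints and width
#' `bundle_width_um`. The strand image is scaled by `signal_amplitude`,
#' placed over `background_level` and convolved with the Gaussian
#' point-spread function.
#'
#' @param truth A `ground_truth_network` from [generate_vertex_layout()].
#' @param spec The [aster_field_spec()] used to generate `truth`.
#' @param seed Seed for the strand draws; defaults to `spec$seed + 1`.
#' @return An [image_frame()] of expected intensities (no noise).
#' @export
render_aster_image <- function(truth, spec, seed = spec$seed + 1L) {
  spec <- validate_aster_field_spec(spec)
  stopifnot(inherits(truth, "ground_truth_network"))
  px <- spec$pixel_size_um
  wpx <- max(1L, as.integer(round(spec$field_width_um / px)))
  hpx <- max(1L, as.integer(round(spec$field_height_um / px)))
  img <- matrix(0, hpx, wpx)
  half_w <- spec$bundle_width_um / 2 / px   # strand half-width in px
  ne <- nrow(truth$edges)
  if (ne > 0) {
    pos_px <- truth$positions / px          # 0-based pixel-centre coords
    strands <- with_seed(seed, {
      counts <- seq.int(spec$strand_count_min, spec$strand_count_max)
      ks <- counts[sample.int(length(counts), ne, replace = TRUE)]
      offs <- stats::runif(sum(ks), -spec$strand_offset_um, spec$strand_offset_um) / px
      list(ks = ks, offs = offs)
    })
    oi <- 0L
    for (e in seq_len(ne)) {
      p0 <- pos_px[truth$edges[e, 1], ]
      p1 <- pos_px[truth$edges[e, 2], ]
      d <- p1 - p0
      nrm <- sqrt(sum(d^2))
      if (nrm == 0) next
      perp <- c(-d[2], d[1]) / nrm
      for (s in seq_len(strands$ks[e])) {
        oi <- oi + 1L
        off <- strands$offs[oi] * perp
        seg <- segment_coverage(dim(img), p0 + off, p1 + off, half_w)
        if (length(seg$idx))
          img[seg$idx] <- img[seg$idx] + seg$cov
      }
    }
  }
  signal <- spec$background_level + spec$signal_amplitude * img
  if (spec$psf_sigma_um > 0) {
    sig_px <- spec$psf_sigma_um / px
    signal <- xcorr2_reflect(signal, gaussian_kernel_2d(sig_px))
    signal[signal < 0] <- 0  # FFT blur can undershoot by numerical noise
  }
  image_frame(signal, pixel_size_um = px)
}

# Anti-aliased coverage of a capsule (segment with half-width half_w, pixel
# units, 0-based centre coordinates): returns the linear indices into a
# matrix of dimension `dims` and the coverage values to add there. Kept
# separate from the accumulation so the caller can modify its image matrix
# in place instead of copying it per strand.
segment_coverage <- function(dims, p0, p1, half_w) {
  pad <- half_w + 1.5
  j0 <- max(0L, floor(min(p0[1], p1[1]) - pad))
  j1 <- min(dims[2] - 1L, ceiling(max(p0[1], p1[1]) + pad))
  i0 <- max(0L, floor(min(p0[2], p1[2]) - pad))
  i1 <- min(dims[1] - 1L, ceiling(max(p0[2], p1[2]) + pad))
  if (j1 < j0 || i1 < i0) return(list(idx = integer(0), cov = numeric(0)))
  xs <- j0:j1
  ys <- i0:i1
  gx <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  gy <- matrix(ys, length(ys), length(xs))
  d <- dist_to_segment(gx, gy, p0, p1)
  cov <- pmin(1, pmax(0, half_w + 0.5 - d))
  keep <- which(cov > 0)
  idx <- (rep(xs, each = length(ys))[keep]) * dims[1] +
    rep(ys, length(xs))[keep] + 1L
  list(idx = idx, cov = cov[keep])
}

#' Apply the camera noise model
#'
#' Resamples each pixel as a Poisson count with the noiseless image as
#' expectation, adds zero-mean Gaussian read noise, and clips at zero.
#'
#' @param image An [image_frame()] of non-negative expected intensities.
#' @param spec An [aster_field_spec()] (supplies `read_noise_sigma`).
#' @param seed Seed; defaults to `spec$seed + 2`.
#' @return An [image_frame()] with noise applied.
#' @export
add_noise <- function(image, spec, seed = spec$seed + 2L) {
  stopifnot(inherits(image, "image_frame"))
  spec <- validate_aster_field_spec(spec)
  lam <- image$intensities
  if (any(lam < 0)) stop("negative input intensity")
  noisy <- with_seed(seed, {
    n <- length(lam)
    shot <- stats::rpois(n, lam)
    if (spec$read_noise_sigma > 0)
      shot <- shot + stats::rnorm(n, 0, spec$read_noise_sigma)
    shot
  })
  noisy <- matrix(pmax(0, noisy), nrow(lam), ncol(lam))
  image_frame(noisy, image$pixel_size_um)
}

#' Simulate a complete synthetic aster field
#'
#' Convenience wrapper chaining [generate_vertex_layout()],
#' [render_aster_image()] and [add_noise()] with seeds derived from
#' `spec$seed` (layout: `seed`, rendering: `seed + 1`, noise: `seed + 2`).
#'
#' @param spec An [aster_field_spec()].
#' @param noise If `FALSE`, return the noiseless rendering.
#' @return A list of class `aster_field_sim` with `spec`, `truth`
#'   (ground-truth network) and `image` (the [image_frame()]).
#' @examples
#' spec <- aster_field_spec(field_width_um = 60, field_height_um = 60,
#'                          lattice_constant_um = 12, pixel_size_um = 1)
#' sim <- simulate_aster_field(spec)
#' sim$image
#' @export
simulate_aster_field <- function(spec, noise = TRUE) {
  spec <- validate_aster_field_spec(spec)
  truth <- generate_vertex_layout(spec)
  image <- render_aster_image(truth, spec)
  if (noise) image <- add_noise(image, spec)
  structure(list(spec = spec, truth = truth, image = image),
            class = "aster_field_sim")
}

#' @export
print.aster_field_sim <- function(x, ...) {
  cat("Synthetic aster field\n")
  print(x$truth)
  print(x$image)
  invisible(x)
}

#' Write a synthetic fixture to disk
#'
#' Persists a 16-bit grayscale TIFF of the image, a CSV of true vertex
#' positions (`id, x_um, y_um`) and a JSON sidecar holding the full
#' generating specification including its seed, so the fixture can be
#' regenerated bit-for-bit.
#'
#' @param truth A `ground_truth_network`.
#' @param image An [image_frame()]; intensities are rounded to integer
#'   counts and must not exceed 65535.
#' @param spec The generating [aster_field_spec()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the named character vector of files written.
#' @export
write_fixture <- function(truth, image, spec, out_dir) {
  stopifnot(inherits(truth, "ground_truth_network"),
            inherits(image, "image_frame"))
  spec <- validate_aster_field_spec(spec)
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory: ", out_dir)
  counts <- round(image$intensities)
  if (max(counts) > 65535)
    stop("intensities exceed the 16-bit range; rescale before writing")
  files <- c(image = file.path(out_dir, "image.tif"),
             vertices = file.path(out_dir, "vertices.csv"),
             spec = file.path(out_dir, "spec.json"))
  ok <- tiff::writeTIFF(counts / 65535, files[["image"]],
                        bits.per.sample = 16, compression = "none")
  if (!isTRUE(ok == 1L)) stop("failed to write TIFF: ", files[["image"]])
  utils::write.csv(
    data.frame(id = seq_len(nrow(truth$positions)),
               x_um = truth$positions[, 1],
               y_um = truth$positions[, 2]),
    files[["vertices"]], row.names = FALSE)
  jsonlite::write_json(unclass(spec), files[["spec"]],
                       auto_unbox = TRUE, digits = NA)
  invisible(files)
}

#' Read a synthetic fixture written by [write_fixture()]
#'
#' @param dir Directory containing `image.tif`, `vertices.csv`, `spec.json`.
#' @return A list with `image` ([image_frame()]), `positions` (matrix) and
#'   `spec` ([aster_field_spec()]).
#' @export
read_fixture <- function(dir) {
  sj <- jsonlite::read_json(file.path(dir, "spec.json"), simplifyVector = TRUE)
  spec <- do.call(aster_field_spec, sj)
  image <- read_image(file.path(dir, "image.tif"), spec$pixel_size_um)
  v <- utils::read.csv(file.path(dir, "vertices.csv"))
  list(image = image,
       positions = as.matrix(v[, c("x_um", "y_um")]),
       spec = spec)
}
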