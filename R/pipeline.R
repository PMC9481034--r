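#' Pipeline configuration
#'
#' Bundles every parameter of the end-to-end analysis. All randomness (the
#' tile bootstrap) flows from the explicit seed recorded here; nothing is
#' taken from the global random state.
#'
#' @param pixel_size_um Calibration, micrometres per pixel. Required for
#'   any analysis; never guessed from image metadata.
#' @param detection A [detection_params()].
#' @param edge_filter An [edge_filter_policy()].
#' @param n_tiles,bootstrap_B,bootstrap_seed Tile-bootstrap settings
#'   (see [tile_homogeneity()]).
#' @param boundary_margin_um Border exclusion zone for degree statistics;
#'   defaults to the edge filter's upper cut-off.
#' @param output_dir Optional directory for [write_report()].
#' @param log_level `"info"` or `"quiet"`.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(pixel_size_um,
                            detection = detection_params(),
                            edge_filter = edge_filter_policy(),
                            n_tiles = 16,
                            bootstrap_B = 1000,
                            bootstrap_seed = 1L,
                            boundary_margin_um = edge_filter$max_length_um,
                            output_dir = NULL,
                            log_level = c("info", "quiet")) {
  if (missing(pixel_size_um) || !is.numeric(pixel_size_um) ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("configuration error: pixel_size_um must be a positive number")
  stopifnot(inherits(detection, "detection_params"),
            inherits(edge_filter, "edge_filter_policy"))
  if (!n_tiles %in% c(16, 64)) stop("n_tiles must be 16 or 64")
  structure(list(
    pixel_size_um = as.numeric(pixel_size_um),
    detection = detection,
    edge_filter = edge_filter,
    n_tiles = as.integer(n_tiles),
    bootstrap_B = as.integer(bootstrap_B),
    bootstrap_seed = as.integer(bootstrap_seed),
    boundary_margin_um = as.numeric(boundary_margin_um),
    output_dir = output_dir,
    log_level = match.arg(log_level)
  ), class = "pipeline_config")
}

#' Write a pipeline configuration to YAML
#' @param config A [pipeline_config()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
config_to_yaml <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- list(pixel_size_um = config$pixel_size_um,
            detection = unclass(config$detection),
            edge_filter = unclass(config$edge_filter),
            n_tiles = config$n_tiles,
            bootstrap_B = config$bootstrap_B,
            bootstrap_seed = config$bootstrap_seed,
            boundary_margin_um = config$boundary_margin_um,
            output_dir = config$output_dir,
            log_level = config$log_level)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#' @param path YAML file written by [config_to_yaml()] (or hand-written;
#'   missing blocks fall back to defaults).
#' @return A [pipeline_config()].
#' @export
config_from_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  pipeline_config(
    pixel_size_um = x$pixel_size_um,
    detection = do.call(detection_params, x$detection %||% list()),
    edge_filter = do.call(edge_filter_policy, x$edge_filter %||% list()),
    n_tiles = x$n_tiles %||% 16,
    bootstrap_B = x$bootstrap_B %||% 1000,
    bootstrap_seed = x$bootstrap_seed %||% 1L,
    boundary_margin_um = x$boundary_margin_um %||%
      (x$edge_filter$max_length_um %||% 20),
    output_dir = x$output_dir,
    log_level = x$log_level %||% "info"
  )
}

# Assemble the headline statistics into a `network_summary`.
make_network_summary <- function(len_stats, deg_stats, density, n_vertices,
                                 n_retained) {
  a <- len_stats$mean_um
  model <- if (is.finite(a) && a > 0) hexagon_model_count(a) else NA_real_
  structure(list(
    mean_edge_length_um = len_stats$mean_um,
    sd_edge_length_um = len_stats$sd_um,
    median_degree = deg_stats$median_degree,
    degree_iqr = deg_stats$iqr,
    vertex_density_per_mm2 = density,
    hexagon_model_per_mm2 = model,
    hexagon_correlation = if (is.finite(model)) density / model else NA_real_,
    n_vertices = n_vertices,
    n_edges_retained = n_retained
  ), class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat("Network summary\n")
  cat(sprintf("  %-28s %s\n", "vertices / retained edges",
              sprintf("%d / %d", x$n_vertices, x$n_edges_retained)))
  cat(sprintf("  %-28s %.2f +/- %.2f\n", "Av Dist (um)",
              x$mean_edge_length_um, x$sd_edge_length_um))
  cat(sprintf("  %-28s %s (IQR %.2g)\n", "Neighb (median)",
              format(x$median_degree), x$degree_iqr))
  cat(sprintf("  %-28s %.0f\n", "Vert. Dens (per mm^2)",
              x$vertex_density_per_mm2))
  cat(sprintf("  %-28s %.3f\n", "Corr. Hex", x$hexagon_correlation))
  invisible(x)
}

#' Run the full aster-network analysis on a calibrated image
#'
#' Executes the whole chain — oriented-line correlation, elongation,
#' segmentation, sub-separation merging, Delaunay triangulation,
#' edge-length filtering, spacing/degree/density statistics, hexagon-model
#' comparison and tile-bootstrap homogeneity — and returns a classed report.
#' The hexagon model is evaluated at the measured mean inter-vertex
#' distance. An image in which no vertex is found yields a flagged empty
#' report rather than an error.
#'
#' `aster_analysis()` is an alias taking a path or an [image_frame()].
#'
#' @param image An [image_frame()].
#' @param config A [pipeline_config()]; its `pixel_size_um` must match the
#'   frame.
#' @return An object of class `aster_report` with elements `summary`
#'   ([print.network_summary()]), `homogeneity`, `vertices`, `network`,
#'   `retained`, `counts` (per-stage bookkeeping), `provenance` and
#'   `empty`.
#' @export
run_full_analysis <- function(image, config) {
  stopifnot(inherits(image, "image_frame"), inherits(config, "pipeline_config"))
  if (abs(image$pixel_size_um - config$pixel_size_um) >
      1e-9 * config$pixel_size_um)
    stop("configuration error: config pixel size does not match the image")
  info <- config$log_level == "info"
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    if (info) message(line)
    invisible(NULL)
  }
  say("image: %d x %d px at %.4g um/px", image$width_px, image$height_px,
      image$pixel_size_um)
  p <- config$detection
  say("detection: %d angles, line %.3g um, elongation x%.3g, blur %.3g um, q %.3g",
      p$n_angles, p$line_length_um, p$elongation_factor, p$blur_sigma_um,
      p$threshold_quantile)
  core <- detect_core(image, p)
  raw <- core$raw
  say("segmented %d candidate vertices", nrow(raw$positions))
  vertices <- core$vertices
  n_merged <- nrow(raw$positions) - nrow(vertices$positions)
  say("merged %d sub-%.3g-um candidates -> %d vertices", n_merged,
      p$min_separation_um, nrow(vertices$positions))
  provenance <- list(
    package_version = as.character(utils::packageVersion("asternet")),
    config_hash = object_hash(config),
    input_checksum = object_hash(image$intensities),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  counts <- list(n_segmented = nrow(raw$positions), n_merged = n_merged,
                 n_vertices = nrow(vertices$positions))
  if (nrow(vertices$positions) < 3) {
    say("empty result: fewer than 3 vertices detected")
    return(structure(list(summary = NULL, homogeneity = NULL,
                          vertices = vertices, network = NULL,
                          retained = NULL, counts = counts,
                          provenance = provenance, log = log_lines,
                          config = config, empty = TRUE),
                     class = "aster_report"))
  }
  network <- triangulate(vertices, config$boundary_margin_um)
  retained <- filter_edges(network, config$edge_filter)
  counts$n_edges <- nrow(network$edges)
  counts$n_short_rejected <- retained$n_short_rejected
  counts$n_long_rejected <- retained$n_long_rejected
  say("triangulated %d edges; rejected %d short (< %.3g um), %d long (> %.3g um)",
      nrow(network$edges), retained$n_short_rejected,
      config$edge_filter$min_length_um, retained$n_long_rejected,
      config$edge_filter$max_length_um)
  len_stats <- edge_length_stats(retained)
  deg_stats <- degree_stats(network, retained)
  density <- vertex_density(vertices)
  summary <- make_network_summary(len_stats, deg_stats, density,
                                  nrow(vertices$positions),
                                  length(retained$lengths_um))
  say("Av Dist %.2f +/- %.2f um; median degree %s; %.0f per mm^2; Corr. Hex %.3f",
      summary$mean_edge_length_um, summary$sd_edge_length_um,
      format(summary$median_degree), summary$vertex_density_per_mm2,
      summary$hexagon_correlation)
  homogeneity <- tile_homogeneity(vertices, n_tiles = config$n_tiles,
                                  B = config$bootstrap_B,
                                  seed = config$bootstrap_seed,
                                  policy = config$edge_filter)
  structure(list(summary = summary, homogeneity = homogeneity,
                 vertices = vertices, network = network, retained = retained,
                 counts = counts, provenance = provenance, log = log_lines,
                 config = config, empty = FALSE),
            class = "aster_report")
}

#' @rdname run_full_analysis
#' @param x A file path (TIFF/PNG) or an [image_frame()].
#' @param pixel_size_um Calibration used when `x` is a path and no config is
#'   given.
#' @param ... Passed to [pipeline_config()] when `config` is `NULL`.
#' @param config Optional [pipeline_config()].
#' @export
aster_analysis <- function(x, pixel_size_um = NULL, config = NULL, ...) {
  if (is.character(x)) {
    px <- pixel_size_um %||% config$pixel_size_um
    x <- read_image(x, px)
  }
  stopifnot(inherits(x, "image_frame"))
  if (is.null(config))
    config <- pipeline_config(pixel_size_um = x$pixel_size_um, ...)
  run_full_analysis(x, config)
}

#' @export
print.aster_report <- function(x, ...) {
  if (x$empty) {
    cat("aster_report: EMPTY (", x$counts$n_vertices, "vertices detected)\n")
    return(invisible(x))
  }
  print(x$summary)
  print(x$homogeneity)
  invisible(x)
}

#' @export
summary.aster_report <- function(object, ...) {
  print(object)
  invisible(object$summary)
}

#' @export
plot.aster_report <- function(x, ...) {
  if (x$empty) stop("nothing to plot: empty report")
  pos <- x$vertices$positions
  ext <- x$network$extent_um
  graphics::plot(NA, xlim = c(0, ext[1]), ylim = rev(c(0, ext[2])), asp = 1,
                 xlab = "x (um)", ylab = "y (um)", ...)
  e <- x$retained$edges
  graphics::segments(pos[e[, 1], 1], pos[e[, 1], 2],
                     pos[e[, 2], 1], pos[e[, 2], 2], col = "grey60")
  graphics::points(pos, pch = 20, cex = 0.5, col = "red3")
  invisible(x)
}

#' Persist an analysis report
#'
#' Writes `summary.json`, `homogeneity.json` (KDE on its fixed support),
#' `vertices.csv` (`id, x_um, y_um, score`), `edges.csv`
#' (`v1, v2, length_um, retained`), a plain-text table mirroring the
#' headline columns (Av Dist, Neighb, Vert. Dens, Corr. Hex) and the run
#' log. JSON statistics are written at full float precision and contain no
#' timestamps, so identical runs produce byte-identical statistic files.
#'
#' @param report An `aster_report`.
#' @param out_dir Output directory (created if absent); defaults to the
#'   config's `output_dir`.
#' @return Invisibly, the named vector of files written.
#' @export
write_report <- function(report, out_dir = report$config$output_dir) {
  stopifnot(inherits(report, "aster_report"))
  if (is.null(out_dir)) stop("no output directory given")
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory: ", out_dir)
  files <- c(summary = file.path(out_dir, "summary.json"),
             homogeneity = file.path(out_dir, "homogeneity.json"),
             vertices = file.path(out_dir, "vertices.csv"),
             edges = file.path(out_dir, "edges.csv"),
             table = file.path(out_dir, "report.txt"),
             log = file.path(out_dir, "run.log"))
  jsonlite::write_json(
    c(if (report$empty) list(empty = TRUE) else unclass(report$summary),
      report$counts),
    files[["summary"]], auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(report$homogeneity)) {
    h <- report$homogeneity
    jsonlite::write_json(
      list(n_tiles = h$n_tiles, B = h$B, seed = h$seed,
           insufficient = h$insufficient,
           per_tile_mean_um = h$per_tile_mean_um,
           bootstrap_means_um = h$bootstrap_means_um,
           kde_support = h$kde_support, kde_density = h$kde_density),
      files[["homogeneity"]], auto_unbox = TRUE, digits = NA, null = "null")
  }
  pos <- report$vertices$positions
  utils::write.csv(data.frame(id = seq_len(nrow(pos)),
                              x_um = pos[, 1], y_um = pos[, 2],
                              score = report$vertices$scores),
                   files[["vertices"]], row.names = FALSE)
  if (!is.null(report$network)) {
    utils::write.csv(data.frame(v1 = report$network$edges[, 1],
                                v2 = report$network$edges[, 2],
                                length_um = report$network$lengths_um,
                                retained = report$retained$retained),
                     files[["edges"]], row.names = FALSE)
  }
  con <- file(files[["table"]], "w")
  if (report$empty) {
    writeLines("Av Dist\tNeighb\tVert. Dens\tCorr. Hex", con)
    writeLines("empty result: no network detected", con)
  } else {
    s <- report$summary
    writeLines(c("Av Dist\tNeighb\tVert. Dens\tCorr. Hex",
                 sprintf("%.1f\t%s\t%s\t%.3f", s$mean_edge_length_um,
                         format(s$median_degree),
                         format(round(s$vertex_density_per_mm2), big.mark = ","),
                         s$hexagon_correlation)), con)
  }
  close(con)
  writeLines(c(report$log,
               sprintf("config_hash: %s", report$provenance$config_hash),
               sprintf("input_checksum: %s", report$provenance$input_checksum),
               sprintf("package_version: %s", report$provenance$package_version),
               sprintf("timestamp: %s", report$provenance$timestamp)),
             files[["log"]])
  invisible(files)
}

#' Load a vertex CSV written by [write_report()] or [write_fixture()]
#'
#' @param path CSV with columns `x_um`, `y_um` and optionally `score`.
#' @param extent_um `c(width, height)` of the originating field,
#'   micrometres.
#' @return A [vertex_set()].
#' @export
read_vertex_csv <- function(path, extent_um) {
  v <- utils::read.csv(path)
  sc <- if ("score" %in% names(v)) v$score else rep(1, nrow(v))
  vertex_set(cbind(v$x_um, v$y_um), sc,
             frame = list(width_px = NA_integer_, height_px = NA_integer_,
                          pixel_size_um = NA_real_,
                          width_um = extent_um[1], height_um = extent_um[2]))
}

#' Match detected vertices to ground truth
#'
#' Greedy nearest-pair matching within `tol_um`: the closest unmatched
#' detected/true pair is matched repeatedly until no pair is within
#' tolerance. Precision is matched/detected, recall matched/true.
#'
#' @param detected,truth n x 2 position matrices or [vertex_set()]s.
#' @param tol_um Matching tolerance in micrometres (default 2).
#' @param boundary_margin_um Optional border band, with `extent_um`, inside
#'   which vertices are excluded from the evaluation: asters on the rim of
#'   the field of view are truncated by the border, and edge effects are
#'   excluded from all other statistics of the pipeline as well.
#' @param extent_um `c(width, height)` of the field; required when
#'   `boundary_margin_um > 0`.
#' @return A list with `n_matched`, `precision`, `recall`,
#'   `mean_match_error_um`.
#' @export
evaluate_detection <- function(detected, truth, tol_um = 2,
                               boundary_margin_um = 0, extent_um = NULL) {
  getpos <- function(x) if (inherits(x, "vertex_set")) x$positions else
    matrix(as.numeric(x), ncol = 2)
  d <- getpos(detected); tr <- getpos(truth)
  if (boundary_margin_um > 0) {
    if (is.null(extent_um)) stop("extent_um required with a boundary margin")
    inside <- function(p) p[, 1] >= boundary_margin_um &
      p[, 1] <= extent_um[1] - boundary_margin_um &
      p[, 2] >= boundary_margin_um &
      p[, 2] <= extent_um[2] - boundary_margin_um
    d <- d[inside(d), , drop = FALSE]
    tr <- tr[inside(tr), , drop = FALSE]
  }
  nd <- nrow(d); nt <- nrow(tr)
  if (nd == 0 || nt == 0)
    return(list(n_matched = 0L, precision = 0, recall = 0,
                mean_match_error_um = NA_real_))
  # candidate pairs within tolerance via cell binning, then greedy by distance
  cell <- tol_um
  key <- function(cx, cy) paste(cx, cy)
  tcx <- floor(tr[, 1] / cell); tcy <- floor(tr[, 2] / cell)
  bins <- split(seq_len(nt), key(tcx, tcy))
  pairs_i <- integer(0); pairs_j <- integer(0); pairs_d <- numeric(0)
  dcx <- floor(d[, 1] / cell); dcy <- floor(d[, 2] / cell)
  for (i in seq_len(nd)) {
    cand <- unlist(bins[key(rep(dcx[i] + (-1:1), each = 3),
                             rep(dcy[i] + (-1:1), 3))], use.names = FALSE)
    if (is.null(cand) || !length(cand)) next
    dd <- sqrt((d[i, 1] - tr[cand, 1])^2 + (d[i, 2] - tr[cand, 2])^2)
    ok <- dd <= tol_um
    if (any(ok)) {
      pairs_i <- c(pairs_i, rep.int(i, sum(ok)))
      pairs_j <- c(pairs_j, cand[ok])
      pairs_d <- c(pairs_d, dd[ok])
    }
  }
  ord <- order(pairs_d)
  used_d <- logical(nd); used_t <- logical(nt)
  errs <- numeric(0)
  for (k in ord) {
    i <- pairs_i[k]; j <- pairs_j[k]
    if (used_d[i] || used_t[j]) next
    used_d[i] <- TRUE; used_t[j] <- TRUE
    errs <- c(errs, pairs_d[k])
  }
  matched <- length(errs)
  list(n_matched = matched, precision = matched / nd, recall = matched / nt,
       mean_match_error_um = if (matched) mean(errs) else NA_real_)
}
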