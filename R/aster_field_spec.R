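#' Specification of a synthetic aster field
#'
#' Collects every parameter of the synthetic fluorescence-image generator:
#' the near-hexagonal vertex lattice (lattice constant, positional jitter,
#' random vertex dropout), the rendering of inter-vertex bundles as one or
#' more offset strands, the microscope model (Gaussian point-spread function,
#' pixel calibration) and the noise model (Poisson shot noise plus Gaussian
#' read noise). The defaults emulate the imaging conditions the analysis is
#' designed for: a roughly 750 x 750 micrometre field recorded on a
#' 2048 x 2048 pixel grid with an average inter-vertex distance of 11
#' micrometres.
#'
#' @param field_width_um,field_height_um Field extent in micrometres. Both
#'   must be at least three lattice constants so the triangular lattice has
#'   enough rows to be a network.
#' @param lattice_constant_um Average inter-vertex distance `a` in
#'   micrometres; the triangular lattice has row spacing `sqrt(3)/2 * a`.
#' @param jitter_fraction Each vertex is displaced by a uniform random draw
#'   from a disc of radius `jitter_fraction * a`. Must be below 0.5 so the
#'   lattice topology (interior degree 6) is preserved in expectation.
#' @param missing_vertex_prob Independent probability of deleting each
#'   lattice vertex.
#' @param strand_count_min,strand_count_max Each bundle is drawn as `k`
#'   parallel strands with `k` uniform on this integer range (asters often
#'   connect via multiple strands).
#' @param strand_offset_um Maximum perpendicular offset of a strand from the
#'   vertex-to-vertex line, micrometres.
#' @param bundle_width_um Width of a single rendered strand, micrometres.
#' @param psf_sigma_um Standard deviation of the isotropic Gaussian
#'   point-spread function, micrometres.
#' @param signal_amplitude Peak intensity (expected photon counts) added by
#'   one strand.
#' @param background_level Uniform background intensity.
#' @param read_noise_sigma Standard deviation of the additive Gaussian read
#'   noise.
#' @param pixel_size_um Calibration, micrometres per pixel.
#' @param seed Integer seed; all generator randomness derives from it.
#'
#' @return An object of class `aster_field_spec` (a validated list).
#' @seealso [generate_vertex_layout()], [render_aster_image()],
#'   [simulate_aster_field()]
#' @examples
#' spec <- aster_field_spec(field_width_um = 100, field_height_um = 100)
#' spec$lattice_constant_um
#' @export
aster_field_spec <- function(field_width_um = 2048 * 0.366,
                             field_height_um = 2048 * 0.366,
                             lattice_constant_um = 11,
                             jitter_fraction = 0.1,
                             missing_vertex_prob = 0,
                             strand_count_min = 1,
                             strand_count_max = 3,
                             strand_offset_um = 0.6,
                             bundle_width_um = 0.8,
                             psf_sigma_um = 0.5,
                             signal_amplitude = 600,
                             background_level = 100,
                             read_noise_sigma = 5,
                             pixel_size_um = 0.366,
                             seed = 1L) {
  spec <- list(
    field_width_um = as.numeric(field_width_um),
    field_height_um = as.numeric(field_height_um),
    lattice_constant_um = as.numeric(lattice_constant_um),
    jitter_fraction = as.numeric(jitter_fraction),
    missing_vertex_prob = as.numeric(missing_vertex_prob),
    strand_count_min = as.integer(strand_count_min),
    strand_count_max = as.integer(strand_count_max),
    strand_offset_um = as.numeric(strand_offset_um),
    bundle_width_um = as.numeric(bundle_width_um),
    psf_sigma_um = as.numeric(psf_sigma_um),
    signal_amplitude = as.numeric(signal_amplitude),
    background_level = as.numeric(background_level),
    read_noise_sigma = as.numeric(read_noise_sigma),
    pixel_size_um = as.numeric(pixel_size_um),
    seed = as.integer(seed)
  )
  class(spec) <- "aster_field_spec"
  validate_aster_field_spec(spec)
}

validate_aster_field_spec <- function(spec) {
  stopifnot(inherits(spec, "aster_field_spec"))
  a <- spec$lattice_constant_um
  if (!is.finite(a) || a <= 0) stop("lattice_constant_um must be positive")
  if (!is.finite(spec$pixel_size_um) || spec$pixel_size_um <= 0)
    stop("pixel_size_um must be positive")
  if (spec$field_width_um < 3 * a || spec$field_height_um < 3 * a)
    stop("field must span at least 3 lattice constants in each direction")
  if (spec$jitter_fraction < 0 || spec$jitter_fraction >= 0.5)
    stop("jitter_fraction must lie in [0, 0.5)")
  if (spec$missing_vertex_prob < 0 || spec$missing_vertex_prob >= 1)
    stop("missing_vertex_prob must lie in [0, 1)")
  if (spec$strand_count_min < 1L || spec$strand_count_min > spec$strand_count_max)
    stop("need 1 <= strand_count_min <= strand_count_max")
  if (spec$strand_offset_um < 0 || spec$bundle_width_um <= 0)
    stop("strand_offset_um must be >= 0 and bundle_width_um > 0")
  if (spec$psf_sigma_um < 0 || spec$signal_amplitude <= 0 ||
      spec$background_level < 0 || spec$read_noise_sigma < 0)
    stop("optical/noise parameters out of range")
  spec
}

#' @export
print.aster_field_spec <- function(x, ...) {
  cat("Synthetic aster field specification\n")
  cat(sprintf("  field: %.1f x %.1f um at %.4g um/px (%d x %d px)\n",
              x$field_width_um, x$field_height_um, x$pixel_size_um,
              round(x$field_width_um / x$pixel_size_um),
              round(x$field_height_um / x$pixel_size_um)))
  cat(sprintf("  lattice constant a = %.3g um, jitter %.3g a, dropout %.3g\n",
              x$lattice_constant_um, x$jitter_fraction, x$missing_vertex_prob))
  cat(sprintf("  strands %d-%d (offset <= %.3g um, width %.3g um), PSF sigma %.3g um\n",
              x$strand_count_min, x$strand_count_max, x$strand_offset_um,
              x$bundle_width_um, x$psf_sigma_um))
  cat(sprintf("  signal %.3g over background %.3g, read noise sd %.3g, seed %d\n",
              x$signal_amplitude, x$background_level, x$read_noise_sigma, x$seed))
  invisible(x)
}
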