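#' Simulation configuration for synthetic light-sheet volumes
#'
#' Collects the image-formation parameters of the synthetic ultramicroscope:
#' grid geometry, intensity levels, optics (lateral and axial PSF width,
#' Gaussian-sheet waist and wavelength, which together set the Rayleigh range
#' `x_R = pi * w0^2 / lambda`), depth attenuation, and camera noise.
#'
#' @param grid_shape integer length-3, voxels per axis in `(z, y, x)` order
#'   (`z` = optical-section axis, `x` = illumination axis).
#' @param voxel_size_um voxel size per axis in micrometres (default 2 um
#'   isotropic, matching the lateral resolution bound of the instrument).
#' @param bit_depth camera bit depth (8, 12 or 16; default 12).
#' @param background_level parenchyma intensity in camera counts.
#' @param plaque_amplitude plaque intensity in camera counts; must exceed the
#'   background and fit the bit depth.
#' @param lateral_fwhm_um lateral PSF full width at half maximum (default 2).
#' @param axial_fwhm_um axial (light-sheet) FWHM at the sheet waist (default 5).
#' @param sheet_waist_halfwidth_w0_um Gaussian-sheet waist half-width `w0`;
#'   controls how fast the sheet thickens off-waist.
#' @param wavelength_um excitation wavelength (default 0.405, violet diode).
#' @param field_center_x_um position of the sheet waist along `x` in
#'   micrometres; `NULL` means the centre of the field of view.
#' @param attenuation_mu_per_mm exponential intensity loss per millimetre of
#'   imaging depth (0 disables attenuation).
#' @param noise_gaussian_sd additive Gaussian (read) noise sd in counts.
#' @param noise_poisson logical; apply Poisson (shot) noise before read noise.
#' @param rng_seed integer seed recorded with the configuration.
#'
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(grid_shape = c(64L, 64L, 64L),
                              voxel_size_um = c(2, 2, 2),
                              bit_depth = 12L,
                              background_level = 100,
                              plaque_amplitude = 3000,
                              lateral_fwhm_um = 2,
                              axial_fwhm_um = 5,
                              sheet_waist_halfwidth_w0_um = 4,
                              wavelength_um = 0.405,
                              field_center_x_um = NULL,
                              attenuation_mu_per_mm = 0,
                              noise_gaussian_sd = 20,
                              noise_poisson = FALSE,
                              rng_seed = 1L) {
  if (length(voxel_size_um) == 1L) voxel_size_um <- rep(voxel_size_um, 3L)
  grid_shape <- as.integer(grid_shape)
  cfg <- list(
    grid_shape = stats::setNames(grid_shape, c("z", "y", "x")),
    voxel_size_um = stats::setNames(as.numeric(voxel_size_um), c("z", "y", "x")),
    bit_depth = as.integer(bit_depth),
    background_level = background_level,
    plaque_amplitude = plaque_amplitude,
    lateral_fwhm_um = lateral_fwhm_um,
    axial_fwhm_um = axial_fwhm_um,
    sheet_waist_halfwidth_w0_um = sheet_waist_halfwidth_w0_um,
    wavelength_um = wavelength_um,
    field_center_x_um = field_center_x_um,
    attenuation_mu_per_mm = attenuation_mu_per_mm,
    noise_gaussian_sd = noise_gaussian_sd,
    noise_poisson = isTRUE(noise_poisson),
    rng_seed = as.integer(rng_seed)
  )
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  if (length(cfg$grid_shape) != 3L || any(cfg$grid_shape <= 0L)) {
    stop("grid_shape must be 3 positive voxel counts", call. = FALSE)
  }
  if (any(cfg$voxel_size_um <= 0) || any(!is.finite(cfg$voxel_size_um))) {
    stop("voxel_size_um must be positive", call. = FALSE)
  }
  if (!cfg$bit_depth %in% c(8L, 12L, 16L)) {
    stop("bit_depth must be one of 8, 12, 16", call. = FALSE)
  }
  max_count <- 2^cfg$bit_depth - 1
  if (cfg$background_level < 0 || cfg$background_level >= cfg$plaque_amplitude ||
      cfg$plaque_amplitude > max_count) {
    stop(sprintf(
      "need 0 <= background_level < plaque_amplitude <= %d", max_count
    ), call. = FALSE)
  }
  if (cfg$lateral_fwhm_um < 0 || cfg$axial_fwhm_um < 0) {
    stop("PSF widths must be non-negative", call. = FALSE)
  }
  if (cfg$sheet_waist_halfwidth_w0_um <= 0 || cfg$wavelength_um <= 0) {
    stop("sheet waist and wavelength must be positive", call. = FALSE)
  }
  if (cfg$attenuation_mu_per_mm < 0) {
    stop("attenuation_mu_per_mm must be non-negative", call. = FALSE)
  }
  if (cfg$noise_gaussian_sd < 0) {
    stop("noise_gaussian_sd must be non-negative", call. = FALSE)
  }
  invisible(cfg)
}

#' Plaque size distribution specification
#'
#' Two modes: `empirical_bins` draws a bin by probability and then uniformly
#' within the bin (used with the published adult size table); a
#' `truncated_lognormal` draws from a lognormal restricted to
#' `[d_min, d_max]`.
#'
#' @param mode `"empirical_bins"` or `"truncated_lognormal"`.
#' @param bin_edges_um strictly increasing bin edges in micrometres
#'   (empirical mode; `length(probs) + 1` values).
#' @param probs bin probabilities, must sum to 1 (within 1e-9).
#' @param meanlog,sdlog lognormal parameters (lognormal mode).
#' @param d_min_um,d_max_um truncation bounds in micrometres.
#'
#' @return A list of class `size_dist_spec`.
#' @export
size_dist_spec <- function(mode = c("empirical_bins", "truncated_lognormal"),
                           bin_edges_um = NULL, probs = NULL,
                           meanlog = NULL, sdlog = NULL,
                           d_min_um = 0, d_max_um = Inf) {
  mode <- match.arg(mode)
  if (mode == "empirical_bins") {
    if (is.null(bin_edges_um) || is.null(probs)) {
      stop("empirical_bins mode needs `bin_edges_um` and `probs`", call. = FALSE)
    }
    if (length(bin_edges_um) != length(probs) + 1L) {
      stop("need length(bin_edges_um) == length(probs) + 1", call. = FALSE)
    }
    if (any(diff(bin_edges_um) <= 0)) {
      stop("bin edges must be strictly increasing", call. = FALSE)
    }
    if (any(probs < 0) || abs(sum(probs) - 1) > 1e-9) {
      stop("bin probabilities must be non-negative and sum to 1", call. = FALSE)
    }
    if (bin_edges_um[1] < 0) stop("diameters must be non-negative", call. = FALSE)
  } else {
    if (is.null(meanlog) || is.null(sdlog) || sdlog <= 0) {
      stop("truncated_lognormal mode needs `meanlog` and positive `sdlog`",
           call. = FALSE)
    }
    if (d_min_um < 0 || d_max_um <= d_min_um) {
      stop("need 0 <= d_min_um < d_max_um", call. = FALSE)
    }
  }
  structure(
    list(mode = mode, bin_edges_um = bin_edges_um, probs = probs,
         meanlog = meanlog, sdlog = sdlog,
         d_min_um = d_min_um, d_max_um = d_max_um),
    class = "size_dist_spec"
  )
}

#' Adult-group empirical plaque size distribution
#'
#' The published adult (7-8.5 month) equivalent-diameter distribution:
#' bins 8-10, 10-20, 20-30, 30-40 um with relative frequencies 11.7%, 38.7%,
#' 27.7% and 21.9%.
#'
#' @return A [size_dist_spec()] in `empirical_bins` mode.
#' @export
adult_size_distribution <- function() {
  size_dist_spec(
    mode = "empirical_bins",
    bin_edges_um = c(8, 10, 20, 30, 40),
    probs = c(0.117, 0.387, 0.277, 0.219)
  )
}

#' Segmentation parameters
#'
#' @param threshold_mode `"fixed"` (per-volume manual threshold, the default,
#'   mirroring manual-threshold practice) or `"otsu"`.
#' @param fixed_threshold threshold in camera counts (fixed mode).
#' @param connectivity voxel adjacency for component labeling: 6 (faces),
#'   18 (faces+edges) or 26 (faces+edges+corners, default).
#' @param vessel_elongation_max objects with principal-axis elongation above
#'   this are flagged as blood-vessel artifacts.
#' @param vessel_length_max_um objects whose longest principal axis exceeds
#'   this are flagged as vessels regardless of elongation.
#' @param stripe_anisotropy_min objects whose bounding-box x-extent is at
#'   least this multiple of both the y- and z-extents are flagged as
#'   illumination stripes.
#' @param min_diameter_um counting floor on the equivalent diameter
#'   (default 8 um); smaller objects are not retained.
#'
#' @return A list of class `segmentation_params`.
#' @export
segmentation_params <- function(threshold_mode = c("fixed", "otsu"),
                                fixed_threshold = 825,
                                connectivity = 26L,
                                vessel_elongation_max = 5,
                                vessel_length_max_um = 150,
                                stripe_anisotropy_min = 8,
                                min_diameter_um = 8) {
  threshold_mode <- match.arg(threshold_mode)
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L)) {
    stop("connectivity must be 6, 18 or 26", call. = FALSE)
  }
  if (min_diameter_um < 0) stop("min_diameter_um must be >= 0", call. = FALSE)
  if (vessel_elongation_max < 1) {
    stop("vessel_elongation_max must be >= 1", call. = FALSE)
  }
  if (stripe_anisotropy_min <= 1) {
    stop("stripe_anisotropy_min must be > 1", call. = FALSE)
  }
  structure(
    list(threshold_mode = threshold_mode,
         fixed_threshold = fixed_threshold,
         connectivity = connectivity,
         vessel_elongation_max = vessel_elongation_max,
         vessel_length_max_um = vessel_length_max_um,
         stripe_anisotropy_min = stripe_anisotropy_min,
         min_diameter_um = min_diameter_um),
    class = "segmentation_params"
  )
}

#' Quantification parameters
#'
#' @param cubes_per_hemisphere number of sample cubes per hemisphere
#'   (default 6, the published sampling design).
#' @param cube_volume_fraction each cube's volume as a fraction of the
#'   segmented cortex volume (default 0.001, i.e. 0.1%).
#' @param histogram_edges_um equivalent-diameter bin edges; the first bin
#'   starts at the 8 um counting floor, later bins are 10 um wide.
#' @param shrinkage_fraction assumed linear tissue shrinkage `s` from
#'   dehydration/clearing (default 0.20); correction divides measured
#'   diameters by `1 - s` and is applied only on request.
#' @param membership_rule how a plaque is assigned to a cube; only
#'   `"centroid_in_cube"` (half-open faces) is implemented.
#'
#' @return A list of class `quant_params`.
#' @export
quant_params <- function(cubes_per_hemisphere = 6L,
                         cube_volume_fraction = 0.001,
                         histogram_edges_um = c(8, 10, 20, 30, 40, 50, Inf),
                         shrinkage_fraction = 0.20,
                         membership_rule = "centroid_in_cube") {
  if (cube_volume_fraction <= 0 || cube_volume_fraction >= 1) {
    stop("cube_volume_fraction must be in (0, 1)", call. = FALSE)
  }
  if (any(diff(histogram_edges_um) <= 0)) {
    stop("histogram edges must be strictly increasing", call. = FALSE)
  }
  if (shrinkage_fraction < 0 || shrinkage_fraction >= 1) {
    stop("shrinkage_fraction must be in [0, 1)", call. = FALSE)
  }
  membership_rule <- match.arg(membership_rule, "centroid_in_cube")
  structure(
    list(cubes_per_hemisphere = as.integer(cubes_per_hemisphere),
         cube_volume_fraction = cube_volume_fraction,
         histogram_edges_um = histogram_edges_um,
         shrinkage_fraction = shrinkage_fraction,
         membership_rule = membership_rule),
    class = "quant_params"
  )
}
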