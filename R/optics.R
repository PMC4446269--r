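fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# Gaussian convolution along the first array dimension with a constant sigma
# (in voxels). Edges are renormalized so flat inputs stay flat.
conv_dim1 <- function(arr, sigma_vox) {
  if (sigma_vox < 0.02) return(arr)
  n <- dim(arr)[1]
  h <- max(1L, ceiling(4 * sigma_vox))
  off <- (-h):h
  w <- exp(-off^2 / (2 * sigma_vox^2))
  m <- matrix(arr, nrow = n)
  num <- matrix(0, nrow = n, ncol = ncol(m))
  den <- numeric(n)
  for (k in seq_along(off)) {
    o <- off[k]
    src <- seq_len(n) + o
    ok <- src >= 1L & src <= n
    num[ok, ] <- num[ok, ] + w[k] * m[src[ok], , drop = FALSE]
    den[ok] <- den[ok] + w[k]
  }
  array(num / den, dim(arr))
}

# Gaussian blur along one axis (1 = z, 2 = y, 3 = x) with constant sigma
blur_axis <- function(arr, sigma_vox, axis) {
  if (sigma_vox < 0.02) return(arr)
  if (axis == 1L) return(conv_dim1(arr, sigma_vox))
  perm <- switch(axis, NULL, c(2L, 1L, 3L), c(3L, 2L, 1L))
  aperm(conv_dim1(aperm(arr, perm), sigma_vox), perm)
}

#' Apply light-sheet image formation blur
#'
#' Constant lateral blur (detection PSF) plus axial blur along `z` whose
#' width grows away from the sheet waist: for a Gaussian sheet of waist
#' half-width `w0` the thickness follows
#' `sigma_z(x) = sigma_z0 * sqrt(1 + ((x - x0)/x_R)^2)` with Rayleigh range
#' `x_R = pi * w0^2 / lambda`. The volume is blurred slab-by-slab along the
#' illumination axis with the local axial sigma.
#'
#' @param grid a [voxel_grid()].
#' @param config a [simulation_config()]; uses `lateral_fwhm_um`,
#'   `axial_fwhm_um`, `sheet_waist_halfwidth_w0_um`, `wavelength_um`,
#'   `field_center_x_um`.
#' @return Blurred [voxel_grid()].
#' @export
apply_lightsheet_blur <- function(grid, config) {
  stopifnot(is_voxel_grid(grid), inherits(config, "simulation_config"))
  if (config$sheet_waist_halfwidth_w0_um <= 0 || config$wavelength_um <= 0) {
    stop("sheet waist and wavelength must be positive", call. = FALSE)
  }
  arr <- grid$data
  vs <- unname(grid$voxel_size_um)
  dims <- dim(arr)
  sigma_lat <- fwhm_to_sigma(config$lateral_fwhm_um)
  sigma_z0 <- fwhm_to_sigma(config$axial_fwhm_um)

  if (sigma_z0 > 0) {
    x_cent <- voxel_centers_um(dims[3], vs[3])
    x0 <- config$field_center_x_um %||% (dims[3] * vs[3] / 2)
    x_R <- pi * config$sheet_waist_halfwidth_w0_um^2 / config$wavelength_um
    sig_um <- sigma_z0 * sqrt(1 + ((x_cent - x0) / x_R)^2)
    sig_vox <- sig_um / vs[1]
    nz <- dims[1]
    D2 <- outer(seq_len(nz), seq_len(nz), "-")^2
    # group x slabs whose sigma agrees to ~1% to reuse the kernel matrix
    key <- round(log(sig_vox) / 0.01)
    for (k in unique(key)) {
      xs <- which(key == k)
      s <- mean(sig_vox[xs])
      if (s < 0.02) next
      K <- exp(-D2 / (2 * s^2))
      K[D2 > (4 * s)^2] <- 0
      K <- K / rowSums(K)
      for (ix in xs) arr[, , ix] <- K %*% arr[, , ix]
    }
  }
  if (sigma_lat > 0) {
    arr <- blur_axis(arr, sigma_lat / vs[2], 2L)
    arr <- blur_axis(arr, sigma_lat / vs[3], 3L)
  }
  voxel_grid(arr, vs, grid$bit_depth)
}

#' Apply exponential depth attenuation
#'
#' Intensity is multiplied by `exp(-mu * depth)` where depth is measured in
#' millimetres from the volume surface (index 1) along the stated axis,
#' emulating light loss with imaging depth in incompletely cleared tissue.
#'
#' @param grid a [voxel_grid()].
#' @param mu_per_mm attenuation coefficient per millimetre (0 = identity).
#' @param depth_axis `"y"` (default), `"z"` or `"x"`.
#' @return Attenuated [voxel_grid()].
#' @export
apply_attenuation <- function(grid, mu_per_mm, depth_axis = c("y", "z", "x")) {
  stopifnot(is_voxel_grid(grid))
  depth_axis <- match.arg(depth_axis)
  if (mu_per_mm < 0) stop("mu_per_mm must be >= 0", call. = FALSE)
  if (mu_per_mm == 0) return(grid)
  ax <- match(depth_axis, c("z", "y", "x"))
  n <- dim(grid$data)[ax]
  depth_mm <- voxel_centers_um(n, grid$voxel_size_um[ax]) / 1000
  f <- exp(-mu_per_mm * depth_mm)
  arr <- sweep(grid$data, ax, f, "*")
  voxel_grid(arr, grid$voxel_size_um, grid$bit_depth)
}

#' Add camera noise and quantize to integer counts
#'
#' Optional Poisson (shot) noise on the expected counts, additive Gaussian
#' read noise, then rounding and clipping to `[0, 2^bit_depth - 1]`.
#'
#' @param grid a [voxel_grid()].
#' @param config a [simulation_config()]; uses `noise_poisson`,
#'   `noise_gaussian_sd`, `bit_depth`.
#' @param seed optional integer seed.
#' @return Integer-valued [voxel_grid()].
#' @export
add_noise_and_quantize <- function(grid, config, seed = NULL) {
  stopifnot(is_voxel_grid(grid), inherits(config, "simulation_config"))
  arr <- grid$data
  maybe_with_seed(seed, {
    if (config$noise_poisson) {
      arr <- array(stats::rpois(length(arr), pmax(arr, 0)), dim(arr))
    }
    if (config$noise_gaussian_sd > 0) {
      arr <- arr + stats::rnorm(length(arr), 0, config$noise_gaussian_sd)
    }
  })
  arr <- round(arr)
  maxv <- 2^config$bit_depth - 1
  arr[arr < 0] <- 0
  arr[arr > maxv] <- maxv
  voxel_grid(arr, grid$voxel_size_um, config$bit_depth)
}
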