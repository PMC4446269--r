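#' 3D intensity volume with physical voxel sizes
#'
#' A `voxel_grid` wraps a 3D numeric array together with the per-axis voxel
#' size in micrometres and the camera bit depth. The array axis order is
#' `(z, y, x)`: `z` is the optical-section (stack) axis so `grid$data[k, , ]`
#' is the k-th image plane, `y` is the depth-from-surface axis used for
#' attenuation, and `x` is the illumination axis along which the light sheet
#' thickens away from its waist.
#'
#' @param data 3D numeric array, axis order `(z, y, x)`.
#' @param voxel_size_um numeric length-3 voxel size in micrometres, in axis
#'   order `(z, y, x)`; all entries must be positive. A single value is
#'   recycled to an isotropic grid.
#' @param bit_depth integer camera bit depth; one of 8, 12, 16.
#'
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(data, voxel_size_um = c(2, 2, 2), bit_depth = 12L) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3D array in (z, y, x) order", call. = FALSE)
  }
  if (length(voxel_size_um) == 1L) voxel_size_um <- rep(voxel_size_um, 3L)
  if (length(voxel_size_um) != 3L || any(!is.finite(voxel_size_um)) ||
      any(voxel_size_um <= 0)) {
    stop("`voxel_size_um` must be 3 positive finite values", call. = FALSE)
  }
  if (!bit_depth %in% c(8L, 12L, 16L)) {
    stop("`bit_depth` must be one of 8, 12, 16", call. = FALSE)
  }
  structure(
    list(
      data = data,
      voxel_size_um = stats::setNames(as.numeric(voxel_size_um), c("z", "y", "x")),
      bit_depth = as.integer(bit_depth)
    ),
    class = "voxel_grid"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<voxel_grid> %d x %d x %d voxels (z,y,x), voxel %s um, %d-bit\n",
    d[1], d[2], d[3], paste(signif(x$voxel_size_um, 4), collapse = " x "),
    x$bit_depth
  ))
  cat(sprintf(
    "  physical extent %.1f x %.1f x %.1f um, intensity range [%g, %g]\n",
    d[1] * x$voxel_size_um[1], d[2] * x$voxel_size_um[2],
    d[3] * x$voxel_size_um[3], min(x$data), max(x$data)
  ))
  invisible(x)
}

#' @export
dim.voxel_grid <- function(x) dim(x$data)

#' Physical volume of one voxel in cubic micrometres
#' @param grid a [voxel_grid()].
#' @return Scalar voxel volume in um^3.
#' @export
voxel_volume_um3 <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  prod(grid$voxel_size_um)
}

# voxel centre coordinate (um) of 1-based index i along an axis
voxel_centers_um <- function(n, size_um) (seq_len(n) - 0.5) * size_um

is_voxel_grid <- function(x) inherits(x, "voxel_grid")
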