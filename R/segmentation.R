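#' Compute a segmentation threshold
#'
#' `"fixed"` mode returns the configured manual threshold unchanged (the
#' workflow mirrors manual-threshold practice on rendering software);
#' `"otsu"` maximizes the between-class variance of the intensity histogram
#' and returns the midpoint between the two classes' adjacent levels, so the
#' value falls strictly between the modes of a well-separated bimodal image.
#'
#' @param grid a [voxel_grid()].
#' @param params a [segmentation_params()].
#' @return Scalar threshold in camera counts.
#' @export
compute_threshold <- function(grid, params = segmentation_params()) {
  stopifnot(is_voxel_grid(grid), inherits(params, "segmentation_params"))
  if (params$threshold_mode == "fixed") return(params$fixed_threshold)
  x <- as.vector(grid$data)
  rng <- range(x)
  if (rng[1] == rng[2]) {
    stop("otsu threshold undefined on a constant image", call. = FALSE)
  }
  whole <- all(x == round(x))
  if (whole && diff(rng) <= 65535) {
    levels <- rng[1]:rng[2]
    counts <- tabulate(x - rng[1] + 1, nbins = length(levels))
  } else {
    nb <- 4096L
    width <- diff(rng) / nb
    bin <- pmin(floor((x - rng[1]) / width) + 1L, nb)
    counts <- tabulate(bin, nbins = nb)
    levels <- rng[1] + (seq_len(nb) - 0.5) * width
  }
  p <- counts / sum(counts)
  w0 <- cumsum(p)
  mu <- cumsum(p * levels)
  mu_tot <- mu[length(mu)]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, length(p))
  sigma_b[valid] <- (mu_tot * w0[valid] - mu[valid])^2 / (w0[valid] * w1[valid])
  # the criterion is flat across empty histogram gaps; take the plateau
  # midpoint so the threshold sits centrally between the classes
  top <- which(sigma_b >= max(sigma_b) * (1 - 1e-12))
  k <- as.integer(round(mean(top)))
  (levels[k] + levels[k + 1L]) / 2
}

#' Binarize an intensity volume
#'
#' Voxels with intensity greater than or equal to the threshold are
#' foreground (a tie at the threshold counts as foreground).
#'
#' @param grid a [voxel_grid()].
#' @param threshold scalar intensity threshold.
#' @return A [voxel_grid()] with logical data.
#' @export
binarize <- function(grid, threshold) {
  stopifnot(is_voxel_grid(grid))
  voxel_grid(grid$data >= threshold, grid$voxel_size_um, grid$bit_depth)
}

#' Label 3D connected components
#'
#' Maximal connected sets of foreground voxels under the chosen adjacency
#' (6 = faces, 18 = faces+edges, 26 = faces+edges+corners) each receive one
#' positive integer label; background stays 0.
#'
#' @param mask a logical [voxel_grid()] (as from [binarize()]) or a 3D
#'   logical array.
#' @param connectivity 6, 18 or 26 (default 26).
#' @return Integer label array with attribute `n_labels`.
#' @export
label_components <- function(mask, connectivity = 26L) {
  arr <- if (is_voxel_grid(mask)) mask$data else mask
  stopifnot(is.array(arr), length(dim(arr)) == 3L)
  labels <- label3d_cpp(as.logical(arr), dim(arr), as.integer(connectivity))
  dim(labels) <- dim(arr)
  labels
}

#' Measure labeled components
#'
#' One row per labeled object: voxel count, physical volume, centroid,
#' bounding box, equivalent spherical diameter `d = 2 (3V / 4 pi)^(1/3)`, and
#' principal-axis lengths from the voxel-coordinate covariance (with the
#' voxel's own second moment added, so single-voxel objects have unit
#' elongation). Axis lengths use the uniform-rod convention
#' `L = sqrt(12 lambda)`; `elongation` is longest/shortest.
#'
#' @param labels integer label array from [label_components()].
#' @param voxel_size_um voxel size per axis `(z, y, x)` in micrometres.
#' @return Tibble of component measurements sorted by id.
#' @export
component_table <- function(labels, voxel_size_um) {
  if (length(voxel_size_um) == 1L) voxel_size_um <- rep(voxel_size_um, 3L)
  vs <- as.numeric(voxel_size_um)
  dims <- dim(labels)
  idx <- which(labels > 0L)
  empty <- tibble::tibble(
    id = integer(0), voxel_count = integer(0), volume_um3 = numeric(0),
    centroid_z_um = numeric(0), centroid_y_um = numeric(0),
    centroid_x_um = numeric(0),
    bbox_z_min_um = numeric(0), bbox_z_max_um = numeric(0),
    bbox_y_min_um = numeric(0), bbox_y_max_um = numeric(0),
    bbox_x_min_um = numeric(0), bbox_x_max_um = numeric(0),
    extent_z_um = numeric(0), extent_y_um = numeric(0),
    extent_x_um = numeric(0),
    equivalent_diameter_um = numeric(0),
    axis_long_um = numeric(0), axis_mid_um = numeric(0),
    axis_short_um = numeric(0), elongation = numeric(0)
  )
  if (length(idx) == 0L) return(empty)
  i0 <- idx - 1L
  zi <- i0 %% dims[1] + 1L
  yi <- (i0 %/% dims[1]) %% dims[2] + 1L
  xi <- i0 %/% (dims[1] * dims[2]) + 1L
  df <- tibble::tibble(
    id = as.integer(labels[idx]),
    zu = (zi - 0.5) * vs[1], yu = (yi - 0.5) * vs[2], xu = (xi - 0.5) * vs[3],
    z_lo = (zi - 1) * vs[1], z_hi = zi * vs[1],
    y_lo = (yi - 1) * vs[2], y_hi = yi * vs[2],
    x_lo = (xi - 1) * vs[3], x_hi = xi * vs[3]
  )
  vox_vol <- prod(vs)
  agg <- df |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(
      voxel_count = dplyr::n(),
      centroid_z_um = mean(.data$zu), centroid_y_um = mean(.data$yu),
      centroid_x_um = mean(.data$xu),
      bbox_z_min_um = min(.data$z_lo), bbox_z_max_um = max(.data$z_hi),
      bbox_y_min_um = min(.data$y_lo), bbox_y_max_um = max(.data$y_hi),
      bbox_x_min_um = min(.data$x_lo), bbox_x_max_um = max(.data$x_hi),
      szz = mean(.data$zu^2), syy = mean(.data$yu^2), sxx = mean(.data$xu^2),
      szy = mean(.data$zu * .data$yu), szx = mean(.data$zu * .data$xu),
      syx = mean(.data$yu * .data$xu),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$id)
  # principal axes from the per-object covariance plus the voxel's own
  # uniform second moment vs^2 / 12
  ax <- t(vapply(seq_len(nrow(agg)), function(i) {
    mz <- agg$centroid_z_um[i]; my <- agg$centroid_y_um[i]
    mx <- agg$centroid_x_um[i]
    C <- matrix(c(
      agg$szz[i] - mz^2, agg$szy[i] - mz * my, agg$szx[i] - mz * mx,
      agg$szy[i] - mz * my, agg$syy[i] - my^2, agg$syx[i] - my * mx,
      agg$szx[i] - mz * mx, agg$syx[i] - my * mx, agg$sxx[i] - mx^2
    ), 3, 3)
    C <- C + diag(vs^2 / 12)
    ev <- pmax(eigen(C, symmetric = TRUE, only.values = TRUE)$values, 0)
    sqrt(12 * ev)
  }, numeric(3)))
  agg |>
    dplyr::mutate(
      volume_um3 = .data$voxel_count * vox_vol,
      extent_z_um = .data$bbox_z_max_um - .data$bbox_z_min_um,
      extent_y_um = .data$bbox_y_max_um - .data$bbox_y_min_um,
      extent_x_um = .data$bbox_x_max_um - .data$bbox_x_min_um,
      equivalent_diameter_um = equivalent_diameter(.data$volume_um3),
      axis_long_um = ax[, 1], axis_mid_um = ax[, 2], axis_short_um = ax[, 3],
      elongation = .data$axis_long_um / .data$axis_short_um
    ) |>
    dplyr::select(dplyr::all_of(names(empty)))
}

#' Flag vessel and stripe artifacts by shape
#'
#' Blood vessels (from incomplete perfusion) are flagged when the
#' principal-axis elongation exceeds `vessel_elongation_max` or the longest
#' axis exceeds `vessel_length_max_um`. Light-sheet stripes are flagged when
#' the bounding-box x-extent is at least `stripe_anisotropy_min` times both
#' the y- and z-extents. The flags automate exclusions that were done under
#' manual control in semi-automatic workflows.
#'
#' @param records component tibble from [component_table()].
#' @param params a [segmentation_params()].
#' @return `records` with logical columns `flag_vessel` and `flag_stripe`.
#' @export
classify_artifacts <- function(records, params = segmentation_params()) {
  records |>
    dplyr::mutate(
      flag_vessel = .data$elongation > params$vessel_elongation_max |
        .data$axis_long_um > params$vessel_length_max_um,
      flag_stripe = .data$extent_x_um >= params$stripe_anisotropy_min *
        pmax(.data$extent_y_um, .data$extent_z_um)
    )
}

#' Apply the minimum-diameter counting floor
#'
#' An object is retained iff its equivalent diameter is at least
#' `min_diameter_um` (inclusive at the boundary) and no artifact flag is set.
#'
#' @param records component tibble with artifact flags (see
#'   [classify_artifacts()]); missing flag columns are treated as all-false.
#' @param min_diameter_um counting floor in micrometres (default 8).
#' @return `records` with `flag_below_min_diameter` and `retained` columns.
#' @export
filter_min_diameter <- function(records, min_diameter_um = 8) {
  if (!"flag_vessel" %in% names(records)) records$flag_vessel <- FALSE
  if (!"flag_stripe" %in% names(records)) records$flag_stripe <- FALSE
  records |>
    dplyr::mutate(
      flag_below_min_diameter = .data$equivalent_diameter_um < min_diameter_um,
      retained = !.data$flag_vessel & !.data$flag_stripe &
        !.data$flag_below_min_diameter
    )
}

#' Segment plaques in an intensity volume
#'
#' Full segmentation chain: threshold, binarize, 3D connected components,
#' per-object measurement, shape-based artifact flags, and the
#' minimum-diameter counting floor.
#'
#' @param grid a [voxel_grid()].
#' @param params a [segmentation_params()].
#' @param exclusion_mask optional logical array/voxel_grid; foreground voxels
#'   under the mask are removed before labeling (parity with manual exclusion
#'   workflows).
#' @return Object of class `plaque_seg`: list with `records` (tibble),
#'   `labels` (integer array), `threshold`, `params`.
#' @export
segment_plaques <- function(grid, params = segmentation_params(),
                            exclusion_mask = NULL) {
  thr <- compute_threshold(grid, params)
  mask <- binarize(grid, thr)
  if (!is.null(exclusion_mask)) {
    ex <- if (is_voxel_grid(exclusion_mask)) exclusion_mask$data else exclusion_mask
    mask$data <- mask$data & !ex
  }
  labels <- label_components(mask, params$connectivity)
  records <- component_table(labels, grid$voxel_size_um) |>
    classify_artifacts(params) |>
    filter_min_diameter(params$min_diameter_um)
  structure(
    list(records = records, labels = labels, threshold = thr, params = params),
    class = "plaque_seg"
  )
}

#' @export
print.plaque_seg <- function(x, ...) {
  cat(sprintf(
    "<plaque_seg> %d objects (%d retained) at threshold %.4g\n",
    nrow(x$records), sum(x$records$retained), x$threshold
  ))
  invisible(x)
}

#' @rdname segment_plaques
#' @param x a `plaque_seg` object.
#' @param ... unused.
#' @method tidy plaque_seg
#' @export
tidy.plaque_seg <- function(x, ...) x$records
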