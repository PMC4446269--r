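#' Equivalent spherical diameter from volume
#'
#' Converts an object volume `V` (um^3) to the diameter of the sphere of the
#' same volume, `d = 2 * (3 V / (4 pi))^(1/3)`. Strictly increasing in `V`.
#'
#' @param volume_um3 numeric vector of positive volumes in cubic micrometres.
#' @return Diameters in micrometres.
#' @export
equivalent_diameter <- function(volume_um3) {
  if (any(!is.finite(volume_um3)) || any(volume_um3 <= 0)) {
    stop("volumes must be positive and finite", call. = FALSE)
  }
  2 * (3 * volume_um3 / (4 * pi))^(1 / 3)
}

# binary box dilation with half-width 1 along every axis (3x3x3 structuring
# element), implemented as separable running maxima
dilate_box <- function(mask) {
  for (ax in 1:3) {
    n <- dim(mask)[ax]
    if (n < 2) next
    shift_lo <- switch(ax,
      mask[c(2:n, n), , , drop = FALSE],
      mask[, c(2:n, n), , drop = FALSE],
      mask[, , c(2:n, n), drop = FALSE])
    shift_hi <- switch(ax,
      mask[c(1, 1:(n - 1)), , , drop = FALSE],
      mask[, c(1, 1:(n - 1)), , drop = FALSE],
      mask[, , c(1, 1:(n - 1)), drop = FALSE])
    mask <- mask | shift_lo | shift_hi
  }
  mask
}

erode_box <- function(mask) !dilate_box(!mask)

#' Segment the cortex and measure its volume
#'
#' In `"mask"` mode a provided binary cortex mask is accepted as-is and its
#' volume is `voxel count x voxel volume`. In `"intensity"` mode a low-
#' resolution overview volume is thresholded (Otsu), the largest connected
#' component is kept and a morphological closing (3x3x3 box, `closing_iter`
#' passes) fills plaque-scale holes.
#'
#' @param x a [voxel_grid()]: binary mask (`"mask"` mode) or intensity
#'   overview (`"intensity"` mode).
#' @param mode `"mask"` or `"intensity"`.
#' @param closing_iter closing passes in intensity mode.
#' @return Object of class `cortex_seg`: list with `mask` (logical
#'   [voxel_grid()]) and `volume_mm3`.
#' @export
segment_cortex <- function(x, mode = c("mask", "intensity"),
                           closing_iter = 1L) {
  mode <- match.arg(mode)
  stopifnot(is_voxel_grid(x))
  if (mode == "mask") {
    mask <- x$data != 0
  } else {
    thr <- compute_threshold(x, segmentation_params(threshold_mode = "otsu"))
    mask <- x$data >= thr
    labels <- label_components(mask, 26L)
    if (max(labels) == 0L) stop("no foreground after thresholding", call. = FALSE)
    counts <- tabulate(labels[labels > 0L])
    mask <- labels == which.max(counts)
    for (i in seq_len(closing_iter)) mask <- dilate_box(mask)
    for (i in seq_len(closing_iter)) mask <- erode_box(mask)
  }
  if (!any(mask)) stop("cortex mask is empty", call. = FALSE)
  structure(
    list(mask = voxel_grid(mask, x$voxel_size_um, x$bit_depth),
         volume_mm3 = sum(mask) * prod(x$voxel_size_um) / 1e9),
    class = "cortex_seg"
  )
}

#' @export
print.cortex_seg <- function(x, ...) {
  cat(sprintf("<cortex_seg> volume %.4g mm^3 (%d voxels)\n",
              x$volume_mm3, sum(x$mask$data)))
  invisible(x)
}

#' Place sample cubes of fixed cortex-volume fraction
#'
#' Each cube's volume is fixed to `cube_volume_fraction` of the segmented
#' cortex volume (default 0.1%), which normalises the sampling unit across
#' animals. The edge is `(fraction * V_cortex)^(1/3)` rounded to whole
#' voxels per axis; cubes are placed at seeded-random positions fully inside
#' the cortex mask and pairwise non-overlapping.
#'
#' @param cortex a `cortex_seg` (from [segment_cortex()]) or a binary
#'   [voxel_grid()] mask.
#' @param params a [quant_params()].
#' @param seed optional integer seed.
#' @param n_cubes number of cubes; default `params$cubes_per_hemisphere`.
#' @param hemisphere tag recorded with the cubes.
#' @param max_tries placement attempts per cube before a placement error
#'   naming the achieved count.
#' @return Tibble of cubes: id, voxel origin (`z0`,`y0`,`x0`, 1-based),
#'   per-axis voxel extents, origin in micrometres, `edge_um`, `volume_mm3`,
#'   `hemisphere`.
#' @export
place_sample_cubes <- function(cortex, params = quant_params(), seed = NULL,
                               n_cubes = NULL, hemisphere = "right",
                               max_tries = 5000L) {
  if (inherits(cortex, "cortex_seg")) cortex <- cortex$mask
  stopifnot(is_voxel_grid(cortex))
  mask <- cortex$data != 0
  vs <- unname(cortex$voxel_size_um)
  dims <- dim(mask)
  n_cubes <- n_cubes %||% params$cubes_per_hemisphere
  v_cortex_um3 <- sum(mask) * prod(vs)
  edge_um <- (params$cube_volume_fraction * v_cortex_um3)^(1 / 3)
  evox <- pmax(1L, as.integer(round(edge_um / vs)))
  if (any(evox > dims)) {
    stop("cube does not fit inside the mask bounding box", call. = FALSE)
  }
  S <- integral_volume(mask)
  idx_mask <- which(mask)
  placed <- matrix(NA_integer_, n_cubes, 3)
  maybe_with_seed(seed, {
    for (i in seq_len(n_cubes)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        v <- idx_mask[sample.int(length(idx_mask), 1L)]
        o <- arrayInd(v, dims)[1, ]
        hi <- o + evox - 1L
        if (any(hi > dims)) next
        if (box_mask_count(S, o, hi) != prod(evox)) next
        if (i > 1L) {
          prev <- placed[seq_len(i - 1L), , drop = FALSE]
          overlap <- apply(prev, 1, function(p) {
            all(o <= p + evox - 1L & p <= hi)
          })
          if (any(overlap)) next
        }
        placed[i, ] <- o
        ok <- TRUE
        break
      }
      if (!ok) {
        stop(sprintf("cube placement failed: placed %d of %d cubes",
                     i - 1L, n_cubes), call. = FALSE)
      }
    }
  })
  tibble::tibble(
    cube_id = seq_len(n_cubes),
    z0 = placed[, 1], y0 = placed[, 2], x0 = placed[, 3],
    ez = evox[1], ey = evox[2], ex = evox[3],
    vs_z = vs[1], vs_y = vs[2], vs_x = vs[3],
    origin_z_um = (placed[, 1] - 1) * vs[1],
    origin_y_um = (placed[, 2] - 1) * vs[2],
    origin_x_um = (placed[, 3] - 1) * vs[3],
    edge_um = edge_um,
    volume_mm3 = prod(evox * vs) / 1e9,
    hemisphere = hemisphere
  )
}

#' Plaque count and count density per sample cube
#'
#' A retained plaque belongs to a cube iff its centroid lies inside the
#' half-open box `[origin, origin + edge)`; a centroid exactly on an upper
#' face is not counted, so adjacent cubes never double-count.
#'
#' @param records plaque tibble with centroid columns; if a `retained`
#'   column is present only retained plaques are counted.
#' @param cubes cube tibble from [place_sample_cubes()].
#' @return `cubes` with `count` and `density_per_mm3` columns.
#' @export
cube_count_density <- function(records, cubes) {
  if ("retained" %in% names(records)) {
    records <- dplyr::filter(records, .data$retained)
  }
  counts <- vapply(seq_len(nrow(cubes)), function(i) {
    sum(records$centroid_z_um >= cubes$origin_z_um[i] &
          records$centroid_z_um <
            cubes$origin_z_um[i] + cubes$ez[i] * cubes$vs_z[i] &
          records$centroid_y_um >= cubes$origin_y_um[i] &
          records$centroid_y_um <
            cubes$origin_y_um[i] + cubes$ey[i] * cubes$vs_y[i] &
          records$centroid_x_um >= cubes$origin_x_um[i] &
          records$centroid_x_um <
            cubes$origin_x_um[i] + cubes$ex[i] * cubes$vs_x[i])
  }, integer(1))
  cubes |>
    dplyr::mutate(count = counts,
                  density_per_mm3 = counts / .data$volume_mm3)
}

#' Plaque load (volume percent) per sample cube
#'
#' `100 x` (retained plaque voxels inside the cube) / (cube voxels). Uses
#' voxel membership, not the centroid rule, because load is a volume
#' fraction.
#'
#' @param labels integer label array from [label_components()].
#' @param retained_ids integer label ids counted as plaques.
#' @param cubes cube tibble from [place_sample_cubes()].
#' @return `cubes` with a `load_percent` column.
#' @export
cube_plaque_load <- function(labels, retained_ids, cubes) {
  loads <- vapply(seq_len(nrow(cubes)), function(i) {
    zi <- cubes$z0[i]:(cubes$z0[i] + cubes$ez[i] - 1L)
    yi <- cubes$y0[i]:(cubes$y0[i] + cubes$ey[i] - 1L)
    xi <- cubes$x0[i]:(cubes$x0[i] + cubes$ex[i] - 1L)
    sub <- labels[zi, yi, xi]
    100 * sum(sub %in% retained_ids) / length(sub)
  }, numeric(1))
  dplyr::mutate(cubes, load_percent = loads)
}

#' Bin equivalent diameters into a size histogram
#'
#' Half-open bins `[e_i, e_{i+1})`. The first default bin starts at the 8 um
#' counting floor; later bins are the 10 um size groups. Relative
#' percentages are over all input diameters and sum to 100 when any input is
#' present; an empty input reports zero counts and percentages with
#' `empty = TRUE`.
#'
#' @param diameters_um numeric vector of diameters; every value must fall
#'   inside `[min(edges), max(edges))`.
#' @param edges_um strictly increasing bin edges (last may be `Inf`).
#' @return A tibble of class `size_histogram` with `bin`, `bin_lo_um`,
#'   `bin_hi_um`, `count`, `rel_percent`; attributes `n` and `empty`.
#' @export
size_histogram <- function(diameters_um,
                           edges_um = c(8, 10, 20, 30, 40, 50, Inf)) {
  if (any(diff(edges_um) <= 0)) {
    stop("bin edges must be strictly increasing", call. = FALSE)
  }
  k <- length(edges_um) - 1L
  n <- length(diameters_um)
  if (n > 0 && (any(diameters_um < edges_um[1]) ||
                any(diameters_um >= edges_um[k + 1L]))) {
    stop("diameters outside the histogram range", call. = FALSE)
  }
  counts <- if (n == 0) integer(k) else {
    bin <- findInterval(diameters_um, edges_um, rightmost.closed = FALSE)
    tabulate(bin, nbins = k)
  }
  lab_hi <- ifelse(is.finite(edges_um[-1]), format(edges_um[-1], trim = TRUE),
                   "Inf")
  out <- tibble::tibble(
    bin = paste0(format(edges_um[-(k + 1L)], trim = TRUE), "-", lab_hi),
    bin_lo_um = edges_um[-(k + 1L)],
    bin_hi_um = edges_um[-1],
    count = counts,
    rel_percent = if (n > 0) 100 * counts / n else rep(0, k)
  )
  structure(out, class = c("size_histogram", class(out)),
            n = n, empty = n == 0)
}

#' Correct diameters for clearing shrinkage
#'
#' Dehydration and clearing shrink the tissue, biasing measured sizes low by
#' a linear fraction `s` (default 0.20): `measured = true * (1 - s)`, so the
#' correction is `measured / (1 - s)`. Off by default in pipeline outputs;
#' applied only when explicitly requested.
#'
#' @param diameters_um measured diameters in micrometres.
#' @param s linear shrinkage fraction in `[0, 1)` (default 0.20).
#' @return Corrected diameters.
#' @export
correct_shrinkage <- function(diameters_um, s = 0.20) {
  if (!is.finite(s) || s < 0 || s >= 1) {
    stop("shrinkage fraction must be in [0, 1)", call. = FALSE)
  }
  diameters_um / (1 - s)
}

#' Compare per-bin plaque size fractions between two groups
#'
#' For each animal the relative fraction of its plaques per diameter bin is
#' computed; for each bin the animal-level fractions are compared between
#' the two groups with a two-sided Mann-Whitney test (see
#' [mann_whitney_u()]). With fewer than two animals in a group the p-value
#' is reported as `NA` (not computable).
#'
#' @param data tibble with columns `animal`, `group`, `diameter_um`; exactly
#'   two groups.
#' @param edges_um histogram bin edges.
#' @param group_order optional length-2 character giving which group is
#'   first (differences are second minus first).
#' @return Tibble per bin: mean fractions per group, `diff_percent`
#'   (group 2 - group 1, percentage points), `statistic`, `p_value`,
#'   `stars`.
#' @export
compare_group_fractions <- function(data,
                                    edges_um = c(8, 10, 20, 30, 40, 50, Inf),
                                    group_order = NULL) {
  stopifnot(all(c("animal", "group", "diameter_um") %in% names(data)))
  groups <- group_order %||% sort(unique(as.character(data$group)))
  if (length(groups) != 2L) {
    stop("exactly two groups are required", call. = FALSE)
  }
  per_animal <- data |>
    dplyr::group_by(.data$group, .data$animal) |>
    dplyr::group_modify(function(d, key) {
      h <- size_histogram(d$diameter_um, edges_um)
      tibble::tibble(bin = h$bin, bin_lo_um = h$bin_lo_um,
                     bin_hi_um = h$bin_hi_um, fraction = h$rel_percent)
    }) |>
    dplyr::ungroup()
  per_animal |>
    dplyr::group_by(.data$bin, .data$bin_lo_um, .data$bin_hi_um) |>
    dplyr::group_modify(function(d, key) {
      a <- d$fraction[d$group == groups[1]]
      b <- d$fraction[d$group == groups[2]]
      res <- if (length(a) >= 2 && length(b) >= 2) {
        mann_whitney_u(a, b)
      } else {
        list(statistic = NA_real_, p_value = NA_real_)
      }
      tibble::tibble(
        !!paste0("mean_", groups[1]) := mean(a),
        !!paste0("mean_", groups[2]) := mean(b),
        diff_percent = mean(b) - mean(a),
        statistic = res$statistic,
        p_value = res$p_value,
        stars = significance_stars(res$p_value)
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$bin_lo_um)
}
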