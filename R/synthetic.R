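#' @importFrom rlang %||%
NULL

# run expr under a local seed when one is given, otherwise use the ambient RNG
maybe_with_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

#' Draw plaque equivalent diameters from a size distribution
#'
#' In `empirical_bins` mode a bin is drawn with its probability and the
#' diameter uniformly within the bin; in `truncated_lognormal` mode draws use
#' inverse-CDF sampling restricted to the truncation interval.
#'
#' @param dist a [size_dist_spec()].
#' @param n number of diameters to draw (may be 0).
#' @param seed optional integer seed; the ambient RNG is untouched when given.
#' @return Numeric vector of `n` diameters in micrometres.
#' @export
sample_diameters <- function(dist, n, seed = NULL) {
  stopifnot(inherits(dist, "size_dist_spec"))
  n <- as.integer(n)
  if (n < 0) stop("`n` must be >= 0", call. = FALSE)
  if (n == 0L) return(numeric(0))
  maybe_with_seed(seed, {
    if (dist$mode == "empirical_bins") {
      k <- length(dist$probs)
      bin <- sample.int(k, n, replace = TRUE, prob = dist$probs)
      lo <- dist$bin_edges_um[bin]
      hi <- dist$bin_edges_um[bin + 1L]
      stats::runif(n, lo, hi)
    } else {
      p_lo <- stats::plnorm(dist$d_min_um, dist$meanlog, dist$sdlog)
      p_hi <- stats::plnorm(dist$d_max_um, dist$meanlog, dist$sdlog)
      u <- stats::runif(n, p_lo, p_hi)
      stats::qlnorm(u, dist$meanlog, dist$sdlog)
    }
  })
}

# integral volume S with a zero border so box sums are S-lookups
integral_volume <- function(mask) {
  a <- array(0, dim(mask) + 1L)
  a[-1, -1, -1] <- mask + 0
  a <- apply(a, c(2, 3), cumsum)
  a <- aperm(apply(a, c(1, 3), cumsum), c(2, 1, 3))
  aperm(apply(a, c(1, 2), cumsum), c(2, 3, 1))
}

# number of TRUE mask voxels in the index box lo..hi (3-vectors, original
# 1-based coordinates), via the zero-padded integral volume
box_mask_count <- function(S, lo, hi) {
  a <- lo       # padded index of (lo - 1)
  b <- hi + 1L  # padded index of hi
  S[b[1], b[2], b[3]] - S[a[1], b[2], b[3]] - S[b[1], a[2], b[3]] -
    S[b[1], b[2], a[3]] + S[a[1], a[2], b[3]] + S[a[1], b[2], a[3]] +
    S[b[1], a[2], a[3]] - S[a[1], a[2], a[3]]
}

#' Place non-overlapping spheres inside a region mask
#'
#' Rejection sampling of sphere centres: candidates are drawn uniformly from
#' mask voxels (with sub-voxel jitter) and accepted when the sphere fits the
#' containment rule and clears every previously accepted sphere by more than
#' `min_separation_um` surface-to-surface. Larger spheres are placed first,
#' which makes dense packings feasible.
#'
#' @param region_mask a [voxel_grid()] whose data is logical/0-1, or a 3D
#'   logical array (then `voxel_size_um` must be given).
#' @param diameters_um sphere diameters in micrometres.
#' @param min_separation_um minimum surface-to-surface gap between spheres.
#' @param seed optional integer seed.
#' @param voxel_size_um voxel sizes when `region_mask` is a bare array.
#' @param contain `"sphere"` requires the sphere's bounding box to lie fully
#'   in mask voxels (exact containment for box-shaped regions, conservative
#'   otherwise); `"center"` only requires the centre voxel in the mask.
#' @param max_tries rejection-sampling cap per sphere; exceeding it raises a
#'   packing error naming the achieved count.
#'
#' @return Tibble with `z_um`, `y_um`, `x_um`, `diameter_um`, ordered by
#'   decreasing diameter.
#' @export
place_plaques <- function(region_mask, diameters_um, min_separation_um = 4,
                          seed = NULL, voxel_size_um = NULL,
                          contain = c("sphere", "center"),
                          max_tries = 2000L) {
  contain <- match.arg(contain)
  if (is_voxel_grid(region_mask)) {
    voxel_size_um <- region_mask$voxel_size_um
    mask <- region_mask$data != 0
  } else {
    if (is.null(voxel_size_um)) {
      stop("`voxel_size_um` required with a bare mask array", call. = FALSE)
    }
    if (length(voxel_size_um) == 1L) voxel_size_um <- rep(voxel_size_um, 3L)
    mask <- region_mask != 0
  }
  if (!any(mask)) stop("region mask is empty", call. = FALSE)
  n <- length(diameters_um)
  if (n == 0L) {
    return(tibble::tibble(z_um = numeric(0), y_um = numeric(0),
                          x_um = numeric(0), diameter_um = numeric(0)))
  }
  if (any(diameters_um <= 0)) stop("diameters must be positive", call. = FALSE)
  dims <- dim(mask)
  vs <- as.numeric(voxel_size_um)
  idx_mask <- which(mask)
  S <- if (contain == "sphere") integral_volume(mask) else NULL
  d_sorted <- sort(diameters_um, decreasing = TRUE)
  centers <- matrix(NA_real_, n, 3) # columns z,y,x in um
  radii <- d_sorted / 2

  maybe_with_seed(seed, {
    for (i in seq_len(n)) {
      r <- radii[i]
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        v <- idx_mask[sample.int(length(idx_mask), 1L)]
        co <- arrayInd(v, dims)[1, ]
        cen <- (co - stats::runif(3)) * vs # uniform within the voxel
        if (contain == "sphere") {
          lo <- floor((cen - r) / vs) + 1L
          hi <- ceiling((cen + r) / vs)
          if (any(lo < 1L) || any(hi > dims)) next
          if (box_mask_count(S, as.integer(lo), as.integer(hi)) !=
              prod(hi - lo + 1)) next
        }
        if (i > 1L) {
          prev <- centers[seq_len(i - 1L), , drop = FALSE]
          dd <- sqrt(colSums((t(prev) - cen)^2))
          if (any(dd <= radii[seq_len(i - 1L)] + r + min_separation_um)) next
        }
        centers[i, ] <- cen
        placed <- TRUE
        break
      }
      if (!placed) {
        stop(sprintf(
          "packing failed: placed %d of %d spheres before exceeding %d tries",
          i - 1L, n, max_tries
        ), call. = FALSE)
      }
    }
  })
  tibble::tibble(z_um = centers[, 1], y_um = centers[, 2], x_um = centers[, 3],
                 diameter_um = d_sorted)
}

#' Rasterize planted spheres into an intensity volume
#'
#' A voxel takes the plaque amplitude when its centre lies inside any sphere
#' (strict voxel-centre membership, the exactly testable default), otherwise
#' the background level. With `supersample = TRUE` each boundary voxel is
#' subdivided 2x2x2 and painted with the fractional amplitude.
#'
#' @param plaques tibble with `z_um`, `y_um`, `x_um`, `diameter_um` (as from
#'   [place_plaques()]); may have zero rows.
#' @param config a [simulation_config()].
#' @param supersample logical; 2x supersampled partial-volume rasterization.
#' @return A [voxel_grid()].
#' @export
rasterize_plaques <- function(plaques, config, supersample = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  dims <- unname(config$grid_shape)
  vs <- unname(config$voxel_size_um)
  arr <- array(config$background_level, dims)
  extent <- dims * vs
  if (nrow(plaques) > 0) {
    if (any(plaques$z_um < 0 | plaques$z_um > extent[1] |
            plaques$y_um < 0 | plaques$y_um > extent[2] |
            plaques$x_um < 0 | plaques$x_um > extent[3])) {
      stop("plaque centre outside the grid", call. = FALSE)
    }
    amp <- config$plaque_amplitude
    bg <- config$background_level
    sub <- if (supersample) c(-0.25, 0.25) else 0
    for (i in seq_len(nrow(plaques))) {
      cen <- c(plaques$z_um[i], plaques$y_um[i], plaques$x_um[i])
      r <- plaques$diameter_um[i] / 2
      lo <- pmax(floor((cen - r) / vs) + 1L, 1L)
      hi <- pmin(ceiling((cen + r) / vs), dims)
      if (any(lo > hi)) next
      zi <- lo[1]:hi[1]; yi <- lo[2]:hi[2]; xi <- lo[3]:hi[3]
      if (!supersample) {
        dz2 <- ((zi - 0.5) * vs[1] - cen[1])^2
        dy2 <- ((yi - 0.5) * vs[2] - cen[2])^2
        dx2 <- ((xi - 0.5) * vs[3] - cen[3])^2
        inside <- outer(outer(dz2, dy2, "+"), dx2, "+") <= r^2
        block <- arr[zi, yi, xi, drop = FALSE]
        block[inside] <- amp
        arr[zi, yi, xi] <- block
      } else {
        frac <- array(0, c(length(zi), length(yi), length(xi)))
        for (oz in sub) for (oy in sub) for (ox in sub) {
          dz2 <- ((zi - 0.5 + oz) * vs[1] - cen[1])^2
          dy2 <- ((yi - 0.5 + oy) * vs[2] - cen[2])^2
          dx2 <- ((xi - 0.5 + ox) * vs[3] - cen[3])^2
          frac <- frac + (outer(outer(dz2, dy2, "+"), dx2, "+") <= r^2)
        }
        frac <- frac / 8
        block <- arr[zi, yi, xi, drop = FALSE]
        val <- bg + frac * (amp - bg)
        arr[zi, yi, xi] <- pmax(block, val)
      }
    }
  }
  voxel_grid(arr, vs, config$bit_depth)
}

# paint spheres of radius r_um at the given um points; returns affected
# linear voxel indices
paint_points <- function(arr, pts_um, r_um, vs, value) {
  dims <- dim(arr)
  touched <- integer(0)
  for (i in seq_len(nrow(pts_um))) {
    cen <- pts_um[i, ]
    lo <- pmax(floor((cen - r_um) / vs) + 1L, 1L)
    hi <- pmin(ceiling((cen + r_um) / vs), dims)
    if (any(lo > hi)) next
    zi <- lo[1]:hi[1]; yi <- lo[2]:hi[2]; xi <- lo[3]:hi[3]
    dz2 <- ((zi - 0.5) * vs[1] - cen[1])^2
    dy2 <- ((yi - 0.5) * vs[2] - cen[2])^2
    dx2 <- ((xi - 0.5) * vs[3] - cen[3])^2
    inside <- which(outer(outer(dz2, dy2, "+"), dx2, "+") <= r_um^2,
                    arr.ind = TRUE)
    if (nrow(inside) == 0) next
    lin <- (xi[inside[, 3]] - 1L) * dims[1] * dims[2] +
      (yi[inside[, 2]] - 1L) * dims[1] + zi[inside[, 1]]
    arr[lin] <- value
    touched <- c(touched, lin)
  }
  list(arr = arr, idx = unique(touched))
}

#' Add tubular blood-vessel artifacts
#'
#' Vessels from incomplete perfusion retain dye and appear as bright tubes.
#' Each vessel is a random-walk polyline of 3-6 segments dilated to a random
#' radius and painted at plaque-like intensity.
#'
#' @param grid a [voxel_grid()].
#' @param n_vessels number of vessels to add.
#' @param radius_um_range length-2 range of tube radii in micrometres.
#' @param segment_length_um_range length-2 range of per-segment lengths.
#' @param seed optional integer seed.
#' @param intensity painted intensity; default the current grid maximum.
#' @return List with `grid` (modified volume), `vessels` (tibble: id,
#'   radius_um, length_um, start coordinates), `paths` (list of polyline
#'   matrices in um, columns z,y,x) and `voxel_idx` (linear indices painted).
#' @export
add_vessels <- function(grid, n_vessels, radius_um_range = c(3, 8),
                        segment_length_um_range = c(60, 150),
                        seed = NULL, intensity = NULL) {
  stopifnot(is_voxel_grid(grid))
  if (n_vessels == 0L) {
    return(list(grid = grid,
                vessels = tibble::tibble(vessel_id = integer(0),
                                         radius_um = numeric(0),
                                         length_um = numeric(0),
                                         z_um = numeric(0), y_um = numeric(0),
                                         x_um = numeric(0)),
                paths = list(), voxel_idx = integer(0)))
  }
  dims <- dim(grid$data)
  vs <- unname(grid$voxel_size_um)
  extent <- dims * vs
  value <- intensity %||% max(grid$data)
  arr <- grid$data
  paths <- vector("list", n_vessels)
  info <- vector("list", n_vessels)
  all_idx <- integer(0)
  maybe_with_seed(seed, {
    for (v in seq_len(n_vessels)) {
      r <- stats::runif(1, radius_um_range[1], radius_um_range[2])
      n_seg <- sample(3:6, 1)
      start <- stats::runif(3, 0.15, 0.85) * extent
      # persistent random walk: new direction correlated with the previous
      dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
      pts <- matrix(start, 1, 3)
      for (s in seq_len(n_seg)) {
        len <- stats::runif(1, segment_length_um_range[1],
                            segment_length_um_range[2])
        turn <- stats::rnorm(3, sd = 0.4)
        dir <- dir + turn; dir <- dir / sqrt(sum(dir^2))
        nxt <- pmin(pmax(pts[nrow(pts), ] + dir * len, r + vs), extent - r - vs)
        pts <- rbind(pts, nxt)
      }
      # dense samples along the polyline, spaced at half the smallest voxel
      step <- min(vs) / 2
      dense <- do.call(rbind, lapply(seq_len(nrow(pts) - 1L), function(s) {
        a <- pts[s, ]; b <- pts[s + 1L, ]
        L <- sqrt(sum((b - a)^2))
        tt <- seq(0, 1, length.out = max(2L, ceiling(L / step)))
        cbind(a[1] + tt * (b[1] - a[1]), a[2] + tt * (b[2] - a[2]),
              a[3] + tt * (b[3] - a[3]))
      }))
      res <- paint_points(arr, dense, r, vs, value)
      arr <- res$arr
      all_idx <- c(all_idx, res$idx)
      paths[[v]] <- pts
      seg_len <- sum(sqrt(rowSums(diff(pts)^2)))
      info[[v]] <- tibble::tibble(vessel_id = v, radius_um = r,
                                  length_um = seg_len, z_um = start[1],
                                  y_um = start[2], x_um = start[3])
    }
  })
  list(grid = voxel_grid(arr, vs, grid$bit_depth),
       vessels = dplyr::bind_rows(info), paths = paths,
       voxel_idx = unique(all_idx))
}

#' Add fine stripe artifacts along the illumination axis
#'
#' Stripes are a light-sheet artifact: absorbing particles shadow the sheet,
#' leaving thin ridges running parallel to the illumination (x) axis, 1-2
#' voxels thick in y and z.
#'
#' @param grid a [voxel_grid()].
#' @param n_stripes number of stripes.
#' @param seed optional integer seed.
#' @param intensity painted intensity; default the current grid maximum.
#' @return List with `grid`, `stripes` (tibble: id, z/y voxel position,
#'   thickness), and `voxel_idx`.
#' @export
add_stripes <- function(grid, n_stripes, seed = NULL, intensity = NULL) {
  stopifnot(is_voxel_grid(grid))
  if (n_stripes == 0L) {
    return(list(grid = grid,
                stripes = tibble::tibble(stripe_id = integer(0),
                                         z_vox = integer(0), y_vox = integer(0),
                                         thickness_vox = integer(0)),
                voxel_idx = integer(0)))
  }
  dims <- dim(grid$data)
  vs <- unname(grid$voxel_size_um)
  value <- intensity %||% max(grid$data)
  arr <- grid$data
  rows <- vector("list", n_stripes)
  all_idx <- integer(0)
  maybe_with_seed(seed, {
    for (s in seq_len(n_stripes)) {
      th <- sample(1:2, 1)
      z0 <- sample.int(dims[1] - th + 1L, 1)
      y0 <- sample.int(dims[2] - th + 1L, 1)
      zi <- z0:(z0 + th - 1L); yi <- y0:(y0 + th - 1L)
      arr[zi, yi, ] <- value
      lin <- as.vector(outer(
        outer(zi, (yi - 1L) * dims[1], "+"),
        (seq_len(dims[3]) - 1L) * dims[1] * dims[2], "+"
      ))
      all_idx <- c(all_idx, lin)
      rows[[s]] <- tibble::tibble(stripe_id = s, z_vox = z0, y_vox = y0,
                                  thickness_vox = th)
    }
  })
  list(grid = voxel_grid(arr, vs, grid$bit_depth),
       stripes = dplyr::bind_rows(rows), voxel_idx = unique(all_idx))
}
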