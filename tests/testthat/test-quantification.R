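test_that("equivalent diameter inverts the sphere volume formula", {
  expect_equal(equivalent_diameter(4 / 3 * pi), 2) # unit-radius sphere
  expect_equal(equivalent_diameter(268.0826), 8, tolerance = 1e-4)
  v <- runif(50, 1, 1e5)
  expect_equal(equivalent_diameter(2 * v) / equivalent_diameter(v),
               rep(2^(1 / 3), 50)) # scaling law
  # closed-form inverse to 1e-9 relative
  d <- runif(100, 0.5, 70)
  expect_equal(equivalent_diameter(pi / 6 * d^3), d, tolerance = 1e-9)
  expect_error(equivalent_diameter(0), "positive")
  expect_error(equivalent_diameter(-5), "positive")
})

test_that("cortex volume in mask mode is count times voxel volume", {
  mask <- array(FALSE, c(50, 50, 50))
  mask[1:50, 1:50, 1:50] <- TRUE # 125000 voxels at 2 um -> 0.001 mm^3
  cx <- segment_cortex(voxel_grid(mask, 2, 12), "mask")
  expect_equal(cx$volume_mm3, 0.001)
  expect_identical(cx$mask$data, mask)
  expect_error(segment_cortex(voxel_grid(array(FALSE, c(4, 4, 4)), 2, 12),
                              "mask"), "empty")
})

test_that("intensity-mode cortex segmentation recovers a clean synthetic cortex", {
  dims <- c(40, 40, 40)
  truth <- array(FALSE, dims)
  cen <- c(40, 40, 40)
  for (z in 1:40) for (y in 1:40) for (x in 1:40) {
    p <- (c(z, y, x) - 0.5) * 2
    truth[z, y, x] <- sum(((p - cen) / c(30, 34, 26))^2) <= 1
  }
  arr <- ifelse(truth, 1200, 80)
  set.seed(8)
  arr <- arr + rnorm(length(arr), 0, 30)
  cx <- segment_cortex(voxel_grid(array(arr, dims), 2, 12), "intensity")
  inter <- sum(cx$mask$data & truth)
  union <- sum(cx$mask$data | truth)
  expect_gte(inter / union, 0.95)
})

test_that("sample cubes obey the 0.1% volume rule on any mask", {
  # 8 mm^3 box cortex at 10 um voxels -> 200 um cube edge
  mask <- array(TRUE, c(200, 200, 200))
  cx <- segment_cortex(voxel_grid(mask, 10, 12), "mask")
  expect_equal(cx$volume_mm3, 8)
  cubes <- place_sample_cubes(cx, quant_params(), seed = 1)
  expect_equal(nrow(cubes), 6)
  expect_true(all(cubes$ez == 20 & cubes$ey == 20 & cubes$ex == 20))
  expect_equal(unique(cubes$volume_mm3), 0.008) # 0.1% of 8 mm^3
  # seeded rerun is identical
  expect_identical(cubes, place_sample_cubes(cx, quant_params(), seed = 1))
  # brute-force pairwise interval intersection
  for (i in 1:5) for (j in (i + 1):6) {
    sep <- any(abs(cubes$z0[i] - cubes$z0[j]) >= 20,
               abs(cubes$y0[i] - cubes$y0[j]) >= 20,
               abs(cubes$x0[i] - cubes$x0[j]) >= 20)
    expect_true(sep)
  }
  # cube rule within voxel-rounding slack on an irregular mask
  blob <- random_mask(c(60, 60, 60), 0.5, seed = 3)
  blob[1:20, , ] <- TRUE
  cx2 <- segment_cortex(voxel_grid(blob, 5, 12), "mask")
  cubes2 <- place_sample_cubes(cx2, quant_params(cubes_per_hemisphere = 2L),
                               seed = 2)
  frac <- cubes2$volume_mm3 / cx2$volume_mm3
  edge_vox <- cubes2$ez[1]
  slack_lo <- ((edge_vox - 1) / edge_vox)^3
  slack_hi <- ((edge_vox + 1) / edge_vox)^3
  expect_true(all(frac >= 0.001 * slack_lo & frac <= 0.001 * slack_hi))
})

test_that("cube placement failure names the achieved count", {
  mask <- array(TRUE, c(12, 12, 12))
  cx <- segment_cortex(voxel_grid(mask, 10, 12), "mask")
  expect_error(
    place_sample_cubes(cx, quant_params(cubes_per_hemisphere = 60L,
                                        cube_volume_fraction = 0.05),
                       seed = 1, max_tries = 60),
    "placed [0-9]+ of 60"
  )
})

fake_cube <- function(origin_um, edge_vox, vs) {
  tibble::tibble(
    cube_id = 1L, z0 = as.integer(origin_um[1] / vs + 1),
    y0 = as.integer(origin_um[2] / vs + 1),
    x0 = as.integer(origin_um[3] / vs + 1),
    ez = edge_vox, ey = edge_vox, ex = edge_vox,
    vs_z = vs, vs_y = vs, vs_x = vs,
    origin_z_um = origin_um[1], origin_y_um = origin_um[2],
    origin_x_um = origin_um[3],
    edge_um = edge_vox * vs, volume_mm3 = (edge_vox * vs)^3 / 1e9,
    hemisphere = "right"
  )
}

test_that("centroid-in-cube counting uses half-open faces", {
  cube <- fake_cube(c(100, 100, 100), 50, 2) # [100, 200) um each axis
  rec <- tibble::tibble(
    centroid_z_um = c(150, 100, 200, 199.999, 50),
    centroid_y_um = c(150, 150, 150, 150, 150),
    centroid_x_um = c(150, 150, 150, 150, 150),
    retained = TRUE
  )
  out <- cube_count_density(rec, cube)
  # inside, on lower face (counted), on upper face (not), just inside, outside
  expect_equal(out$count, 4L - 1L)
  expect_equal(out$density_per_mm3, 3 / cube$volume_mm3)
  # empty cube
  out0 <- cube_count_density(rec[0, ], cube)
  expect_equal(out0$count, 0L)
  expect_equal(out0$density_per_mm3, 0)
  # point-in-box oracle on planted centroids
  set.seed(13)
  pts <- tibble::tibble(centroid_z_um = runif(200, 0, 300),
                        centroid_y_um = runif(200, 0, 300),
                        centroid_x_um = runif(200, 0, 300),
                        retained = TRUE)
  got <- cube_count_density(pts, cube)$count
  want <- sum(pts$centroid_z_um >= 100 & pts$centroid_z_um < 200 &
                pts$centroid_y_um >= 100 & pts$centroid_y_um < 200 &
                pts$centroid_x_um >= 100 & pts$centroid_x_um < 200)
  expect_equal(got, want)
  # only retained plaques are counted
  pts$retained <- rep(c(TRUE, FALSE), 100)
  got_r <- cube_count_density(pts, cube)$count
  expect_lte(got_r, want)
})

test_that("plaque load is the retained voxel fraction of the cube", {
  cube <- fake_cube(c(20, 20, 20), 10, 2) # voxels 11:20 each axis
  labels <- array(0L, c(40, 40, 40))
  expect_equal(cube_plaque_load(labels, integer(0), cube)$load_percent, 0)
  labels[] <- 1L
  expect_equal(cube_plaque_load(labels, 1L, cube)$load_percent, 100)
  # a planted sphere fully inside the cube: load = voxel volume ratio
  sim <- clean_sim(c(40, 40, 40))
  plq <- tibble::tibble(z_um = 30, y_um = 30, x_um = 30, diameter_um = 12)
  g <- rasterize_plaques(plq, sim)
  labs <- label_components(g$data > sim$background_level, 26)
  nvox <- sum(labs == 1L)
  load <- cube_plaque_load(labs, 1L, cube)$load_percent
  expect_equal(load, 100 * nvox / 1000, tolerance = 1e-9)
  # load is invariant to which id the component carries
  labs2 <- labs
  labs2[labs2 == 1L] <- 7L
  expect_equal(cube_plaque_load(labs2, 7L, cube)$load_percent, load)
})

test_that("size histograms use half-open bins and conserve counts", {
  h <- size_histogram(c(9, 15, 25, 35))
  expect_equal(h$count, c(1, 1, 1, 1, 0, 0))
  expect_equal(h$rel_percent, c(25, 25, 25, 25, 0, 0))
  expect_equal(sum(h$rel_percent), 100)
  h0 <- size_histogram(numeric(0))
  expect_true(all(h0$count == 0))
  expect_true(all(h0$rel_percent == 0))
  expect_true(attr(h0, "empty"))
  # boundary values fall in the upper bin (half-open)
  h1 <- size_histogram(c(10, 20))
  expect_equal(h1$count[2], 1)
  expect_equal(h1$count[3], 1)
  # brute-force binning oracle on random draws
  set.seed(17)
  d <- runif(500, 8, 49.99)
  edges <- c(8, 10, 20, 30, 40, 50, Inf)
  h2 <- size_histogram(d, edges)
  want <- vapply(seq_len(6), function(i) {
    sum(d >= edges[i] & d < edges[i + 1])
  }, numeric(1))
  expect_equal(as.numeric(h2$count), want)
  expect_equal(sum(h2$count), length(d))
  expect_error(size_histogram(c(5, 12)), "outside")
})

test_that("shrinkage correction divides by 1 - s", {
  expect_equal(correct_shrinkage(c(10, 20), 0), c(10, 20))
  expect_equal(correct_shrinkage(40, 0.20), 50)
  expect_error(correct_shrinkage(10, 1), "\\[0, 1\\)")
  expect_error(correct_shrinkage(10, 1.2), "\\[0, 1\\)")
  # volume consistency: correcting d then cubing == correcting V by (1-s)^-3
  d <- c(12, 25, 40)
  s <- 0.2
  expect_equal(correct_shrinkage(d, s)^3, d^3 / (1 - s)^3)
})

test_that("group fraction comparison detects a planted shift and not a null", {
  set.seed(23)
  edges <- c(8, 10, 20, 30, 40, 50, Inf)
  spec_a <- size_dist_spec("empirical_bins",
                           bin_edges_um = c(8, 10, 20, 30, 40),
                           probs = c(0.117, 0.387, 0.277, 0.219))
  # shift 10 pp of mass from [20,30) to [40,50)
  spec_b <- size_dist_spec("empirical_bins",
                           bin_edges_um = c(8, 10, 20, 30, 40, 50),
                           probs = c(0.117, 0.387, 0.177, 0.219, 0.10))
  make_group <- function(spec, g, seed0) {
    dplyr::bind_rows(lapply(1:5, function(a) {
      tibble::tibble(animal = sprintf("%s_%d", g, a), group = g,
                     diameter_um = sample_diameters(spec, 400,
                                                    seed = seed0 + a))
    }))
  }
  dat <- dplyr::bind_rows(make_group(spec_a, "young", 100),
                          make_group(spec_b, "adult", 200))
  cmp <- compare_group_fractions(dat, edges, group_order = c("young", "adult"))
  b2030 <- cmp[cmp$bin_lo_um == 20, ]
  b4050 <- cmp[cmp$bin_lo_um == 40, ]
  expect_lt(b2030$diff_percent, 0) # adult lost mass there
  expect_gt(b4050$diff_percent, 0) # and gained it here
  expect_lt(b2030$p_value, 0.05)
  expect_lt(b4050$p_value, 0.05)
  # identical groups: zero differences, no stars
  dat0 <- dat
  dat0$group <- rep(c("young", "adult"), each = nrow(dat) / 2)
  same <- dplyr::bind_rows(
    dat |> dplyr::filter(group == "young"),
    dat |> dplyr::filter(group == "young") |>
      dplyr::mutate(group = "adult", animal = paste0("x", animal))
  )
  cmp0 <- compare_group_fractions(same, edges,
                                  group_order = c("young", "adult"))
  expect_true(all(cmp0$diff_percent == 0))
  expect_true(all(cmp0$stars %in% c("ns", NA)))
  # single-animal groups: p not computable
  tiny <- dat |> dplyr::filter(animal %in% c("young_1", "adult_1"))
  cmp1 <- compare_group_fractions(tiny, edges,
                                  group_order = c("young", "adult"))
  expect_true(all(is.na(cmp1$p_value)))
})
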