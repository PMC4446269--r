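test_that("empirical diameter sampling reproduces the bin fractions", {
  spec <- adult_size_distribution()
  d <- sample_diameters(spec, 10000, seed = 42)
  expect_length(d, 10000)
  frac <- sapply(seq_along(spec$probs), function(i) {
    mean(d >= spec$bin_edges_um[i] & d < spec$bin_edges_um[i + 1])
  })
  expect_true(all(abs(frac - spec$probs) <= 0.015))
  # reproducible given the seed, ambient RNG untouched
  expect_identical(d, sample_diameters(spec, 10000, seed = 42))
})

test_that("diameter sampling handles edge cases and bad specs", {
  expect_identical(sample_diameters(adult_size_distribution(), 0), numeric(0))
  one_bin <- size_dist_spec("empirical_bins", bin_edges_um = c(10, 20),
                            probs = 1)
  d <- sample_diameters(one_bin, 1000, seed = 1)
  expect_true(all(d >= 10 & d < 20))
  expect_error(size_dist_spec("empirical_bins", bin_edges_um = c(10, 20),
                              probs = 0.7), "sum to 1")
  expect_error(size_dist_spec("empirical_bins", bin_edges_um = c(20, 10),
                              probs = 1), "increasing")
})

test_that("truncated lognormal sampling respects the truncation bounds", {
  spec <- size_dist_spec("truncated_lognormal", meanlog = log(15),
                         sdlog = 0.5, d_min_um = 8, d_max_um = 40)
  d <- sample_diameters(spec, 5000, seed = 7)
  expect_true(all(d >= 8 & d <= 40))
  # mass concentrated around the (truncated) median
  expect_gt(median(d), 10)
  expect_lt(median(d), 25)
})

test_that("sphere packing respects the mask and the separation rule", {
  expect_equal(nrow(place_plaques(array(TRUE, c(10, 10, 10)), numeric(0),
                                  voxel_size_um = 2)), 0)
  # 50 spheres of d = 20 um in a 1 mm^3 box at 4 um separation
  mask <- array(TRUE, c(100, 100, 100)) # (1 mm)^3 at 10 um voxels
  plq <- place_plaques(mask, rep(20, 50), min_separation_um = 4, seed = 11,
                       voxel_size_um = 10)
  expect_equal(nrow(plq), 50)
  cen <- as.matrix(plq[, c("z_um", "y_um", "x_um")])
  dmat <- as.matrix(stats::dist(cen))
  diag(dmat) <- Inf
  expect_true(all(dmat > 20 + 4)) # r_i + r_j + min_sep, brute force
  # spheres fully inside the mask box
  expect_true(all(cen >= 10 & cen <= 990))
})

test_that("infeasible packings raise a packing error naming the count", {
  mask <- array(FALSE, c(5, 5, 5))
  mask[3, 3, 3] <- TRUE
  expect_error(
    place_plaques(mask, c(4, 4), min_separation_um = 2, seed = 1,
                  voxel_size_um = 2, max_tries = 50),
    "placed [0-9]+ of 2"
  )
})

test_that("rasterization matches the exact voxel-centre oracle", {
  sim <- clean_sim(c(16, 16, 16))
  plq <- tibble::tibble(z_um = 15.3, y_um = 16.1, x_um = 17.2,
                        diameter_um = 10)
  g <- rasterize_plaques(plq, sim)
  n_fg <- sum(g$data == sim$plaque_amplitude)
  expect_equal(n_fg, oracle_sphere_voxels(c(15.3, 16.1, 17.2), 10,
                                          c(16, 16, 16), c(2, 2, 2)))
  # analytic volume check: (4/3) pi 5^3 / 8 voxels, within 15%
  expect_lt(abs(n_fg - (4 / 3) * pi * 125 / 8) / ((4 / 3) * pi * 125 / 8),
            0.15)
})

test_that("an empty plaque list rasterizes to uniform background", {
  sim <- clean_sim(c(8, 8, 8))
  g <- rasterize_plaques(tibble::tibble(z_um = numeric(0), y_um = numeric(0),
                                        x_um = numeric(0),
                                        diameter_um = numeric(0)), sim)
  expect_true(all(g$data == sim$background_level))
})

test_that("rasterized centroids sit within half a voxel of planted centres", {
  sim <- clean_sim(c(24, 24, 24))
  set.seed(3)
  for (i in 1:5) {
    cen <- runif(3, 18, 30)
    plq <- tibble::tibble(z_um = cen[1], y_um = cen[2], x_um = cen[3],
                          diameter_um = runif(1, 8, 16))
    g <- rasterize_plaques(plq, sim)
    labs <- label_components(g$data > sim$background_level, 26)
    rec <- component_table(labs, g$voxel_size_um)
    got <- c(rec$centroid_z_um, rec$centroid_y_um, rec$centroid_x_um)
    expect_true(all(abs(got - cen) <= 1)) # half a 2 um voxel
  }
})

test_that("out-of-grid centres are rejected", {
  sim <- clean_sim(c(8, 8, 8))
  expect_error(rasterize_plaques(
    tibble::tibble(z_um = 100, y_um = 2, x_um = 2, diameter_um = 4), sim
  ), "outside")
})

test_that("supersampled rasterization gives partial-volume boundaries", {
  sim <- clean_sim(c(16, 16, 16))
  plq <- tibble::tibble(z_um = 16, y_um = 16, x_um = 16, diameter_um = 11)
  g <- rasterize_plaques(plq, sim, supersample = TRUE)
  vals <- unique(as.vector(g$data))
  expect_true(any(vals > sim$background_level &
                    vals < sim$plaque_amplitude))
  # interior voxels still reach the full amplitude
  expect_true(max(vals) == sim$plaque_amplitude)
})
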