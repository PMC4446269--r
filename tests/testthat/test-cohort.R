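tiny_sim <- function() {
  simulation_config(grid_shape = c(32, 32, 32), voxel_size_um = 4,
                    sheet_waist_halfwidth_w0_um = 30, noise_gaussian_sd = 10)
}

test_that("a tiny two-group cohort writes stacks and matching truth", {
  dir <- withr::local_tempdir()
  groups <- list(
    cohort_group("young", 1L,
                 size_dist_spec("empirical_bins", c(10, 16), 1),
                 density_per_mm3 = 3000),
    cohort_group("adult", 1L,
                 size_dist_spec("empirical_bins", c(12, 20), 1),
                 density_per_mm3 = 6000)
  )
  res <- generate_cohort(groups, tiny_sim(), seed = 3, out_dir = dir)
  expect_length(res$animals, 2)
  expect_true(file.exists(file.path(dir, "young_1.tif")))
  expect_true(file.exists(file.path(dir, "adult_1.tif")))
  expect_true(file.exists(file.path(dir, "cortex_young_1.tif")))
  expect_true(file.exists(file.path(dir, "truth.csv")))
  expect_true(file.exists(file.path(dir, "config.json")))
  truth <- read_table(file.path(dir, "truth.csv"))
  v_mm3 <- prod(c(32, 32, 32) * 4) / 1e9
  expect_equal(sum(truth$group == "young"), round(3000 * v_mm3))
  expect_equal(sum(truth$group == "adult"), round(6000 * v_mm3))
  # volumes reload identically
  back <- read_volume(file.path(dir, "young_1.tif"))
  expect_identical(back$data, res$animals[[1]]$grid$data + 0)
})

test_that("exact-totals planting hits the requested cube total exactly", {
  grp <- cohort_group("young", 2L,
                      size_dist_spec("empirical_bins", c(10, 24), 1),
                      total_in_cubes = 100L)
  res <- generate_cohort(list(grp), recovery_sim_config(),
                         mode = "exact_totals", cube_edge_vox = 40L,
                         cube_layout = c(1L, 1L, 2L), cube_margin_vox = 6L,
                         seed = 5)
  plq <- res$truth[res$truth$object_type == "plaque", ]
  expect_equal(nrow(plq), 100)
  # every planted centre lies inside its declared cube
  cubes <- res$cubes
  for (i in seq_len(nrow(plq))) {
    cu <- cubes[cubes$animal == plq$animal[i] &
                  cubes$cube_id == plq$cube_id[i], ]
    expect_true(plq$z_um[i] >= cu$origin_z_um &&
                  plq$z_um[i] < cu$origin_z_um + cu$ez * cu$vs_z)
    expect_true(plq$x_um[i] >= cu$origin_x_um &&
                  plq$x_um[i] < cu$origin_x_um + cu$ex * cu$vs_x)
  }
  # non-overlap invariant, brute force over each animal's spheres
  for (an in unique(plq$animal)) {
    p <- plq[plq$animal == an, ]
    cen <- as.matrix(p[, c("z_um", "y_um", "x_um")])
    r <- p$diameter_um / 2
    dmat <- as.matrix(stats::dist(cen))
    need <- outer(r, r, "+")
    diag(dmat) <- Inf
    expect_true(all(dmat > need))
  }
})

test_that("different seeds give different volumes, same seed identical", {
  grp <- cohort_group("g", 1L, size_dist_spec("empirical_bins", c(10, 20), 1),
                      density_per_mm3 = 4000)
  a <- generate_cohort(list(grp), tiny_sim(), seed = 1)
  b <- generate_cohort(list(grp), tiny_sim(), seed = 2)
  c2 <- generate_cohort(list(grp), tiny_sim(), seed = 1)
  expect_false(identical(a$animals[[1]]$grid$data, b$animals[[1]]$grid$data))
  expect_identical(a$animals[[1]]$grid$data, c2$animals[[1]]$grid$data)
})

test_that("planted recovery is exact on a small exact-totals cohort", {
  groups <- list(
    cohort_group("young", 2L,
                 size_dist_spec("empirical_bins", c(10, 40), 1),
                 total_in_cubes = 60L),
    cohort_group("adult", 2L,
                 size_dist_spec("empirical_bins", c(10, 40), 1),
                 total_in_cubes = 240L)
  )
  res <- recover_planted_totals(groups, cube_edge_vox = 60L,
                                cube_layout = c(1L, 1L, 2L), seed = 9)
  expect_equal(res$group_totals$recovered, res$group_totals$planted)
  expect_equal(sort(res$group_totals$planted), c(60L, 240L))
  # per-cube accounting: recovered counts match planted per cube
  expect_equal(res$per_cube$count, res$per_cube$planted)
})
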