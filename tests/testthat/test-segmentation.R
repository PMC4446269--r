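test_that("otsu threshold separates a bimodal synthetic histogram", {
  set.seed(21)
  n <- 4000
  vals <- c(rnorm(n * 0.8, 100, 50), rnorm(n * 0.2, 3000, 50))
  vals <- pmax(round(vals), 0)
  g <- voxel_grid(array(vals, c(20, 20, 10)), 2, 12)
  thr <- compute_threshold(g, segmentation_params(threshold_mode = "otsu"))
  expect_gt(thr, 300)
  expect_lt(thr, 2900)
  # exhaustive sweep oracle: maximize between-class variance directly
  x <- as.vector(g$data)
  cand <- sort(unique(x))
  bcv <- vapply(cand[-1], function(t) {
    lo <- x[x < t]; hi <- x[x >= t]
    length(lo) / length(x) * length(hi) / length(x) *
      (mean(lo) - mean(hi))^2
  }, numeric(1))
  best <- cand[-1][which.max(bcv)]
  # same class split as the oracle's optimum
  expect_equal(sum(x >= thr), sum(x >= best))
})

test_that("fixed threshold mode returns the configured value", {
  g <- voxel_grid(array(runif(64, 0, 100), c(4, 4, 4)), 2, 12)
  expect_equal(compute_threshold(g, segmentation_params(
    threshold_mode = "fixed", fixed_threshold = 500)), 500)
})

test_that("otsu on a constant image is a degenerate-input error", {
  g <- voxel_grid(array(7, c(4, 4, 4)), 2, 12)
  expect_error(compute_threshold(g, segmentation_params("otsu")), "constant")
})

test_that("binarize uses >= with ties as foreground", {
  g <- voxel_grid(array(c(1, 2, 3, 4, 5, 6, 7, 8), c(2, 2, 2)), 2, 12)
  expect_true(all(binarize(g, 0)$data))
  expect_false(any(binarize(g, 9)$data))
  expect_equal(sum(binarize(g, 5)$data), sum(g$data >= 5)) # elementwise
  expect_true(binarize(g, 5)$data[which(g$data == 5)]) # tie is foreground
})

test_that("component labeling matches the flood-fill oracle", {
  for (conn in c(6L, 18L, 26L)) {
    for (s in 1:12) {
      mask <- random_mask(c(8, 8, 8), fill = 0.35, seed = 100 * conn + s)
      got <- label_components(mask, conn)
      want <- oracle_label3d(mask, conn)
      expect_identical(canonical_labels(got), canonical_labels(want))
      # label conservation: component sizes sum to the foreground count
      expect_equal(sum(tabulate(got[got > 0])), sum(mask))
    }
  }
})

test_that("connectivity semantics at diagonal touching voxels", {
  mask <- array(FALSE, c(4, 4, 4))
  mask[1, 1, 1] <- TRUE
  mask[2, 2, 2] <- TRUE # corner-adjacent
  expect_equal(max(label_components(mask, 26)), 1)
  expect_equal(max(label_components(mask, 18)), 2)
  expect_equal(max(label_components(mask, 6)), 2)
  mask2 <- array(FALSE, c(4, 4, 4))
  mask2[1, 1, 1] <- TRUE
  mask2[2, 2, 1] <- TRUE # edge-adjacent
  expect_equal(max(label_components(mask2, 18)), 1)
  expect_equal(max(label_components(mask2, 6)), 2)
})

test_that("two separated spheres give two components", {
  sim <- clean_sim(c(30, 20, 20))
  plq <- tibble::tibble(z_um = c(12, 44), y_um = c(20, 20),
                        x_um = c(20, 20), diameter_um = c(10, 10))
  g <- rasterize_plaques(plq, sim)
  seg <- segment_plaques(g)
  expect_equal(nrow(seg$records), 2)
})

test_that("artifact classification flags tubes and stripes, not spheres", {
  sim <- clean_sim(c(60, 60, 200))
  g0 <- voxel_grid(array(sim$background_level, c(60, 60, 200)), 2, 12)
  v <- add_vessels(g0, 1, radius_um_range = c(4, 5),
                   segment_length_um_range = c(100, 140), seed = 2,
                   intensity = sim$plaque_amplitude)
  s <- add_stripes(v$grid, 1, seed = 3, intensity = sim$plaque_amplitude)
  withplq <- s$grid
  # add a clean sphere away from the artifacts
  plq <- tibble::tibble(z_um = 100, y_um = 100, x_um = 350, diameter_um = 20)
  sphere <- rasterize_plaques(plq, clean_sim(c(60, 60, 200)))
  withplq$data <- pmax(withplq$data, sphere$data)
  seg <- segment_plaques(withplq)
  rec <- seg$records
  # the sphere: unflagged, retained
  sph <- rec[abs(rec$centroid_x_um - 350) < 10, ]
  expect_equal(nrow(sph), 1)
  expect_false(sph$flag_vessel)
  expect_false(sph$flag_stripe)
  expect_true(sph$retained)
  expect_lt(sph$elongation, 1.3)
  # everything else is flagged as some artifact
  other <- rec[abs(rec$centroid_x_um - 350) >= 10, ]
  expect_gte(nrow(other), 1)
  expect_true(all(other$flag_vessel | other$flag_stripe))
  expect_false(any(other$retained))
  # the stripe specifically carries the stripe flag
  expect_true(any(other$flag_stripe))
})

test_that("minimum-diameter filter is inclusive at the boundary", {
  rec <- tibble::tibble(
    id = 1:3,
    equivalent_diameter_um = c(8.0, 7.99, 12),
    flag_vessel = FALSE, flag_stripe = FALSE
  )
  out <- filter_min_diameter(rec, 8)
  expect_identical(out$retained, c(TRUE, FALSE, TRUE))
  # brute-force equivalence on random tables
  set.seed(5)
  rec2 <- tibble::tibble(
    id = 1:50,
    equivalent_diameter_um = runif(50, 4, 16),
    flag_vessel = runif(50) < 0.2, flag_stripe = runif(50) < 0.1
  )
  out2 <- filter_min_diameter(rec2, 8)
  want <- mapply(function(d, v, s) d >= 8 && !v && !s,
                 rec2$equivalent_diameter_um, rec2$flag_vessel,
                 rec2$flag_stripe)
  expect_identical(out2$retained, unname(want))
})

test_that("planted scenes are recovered object-for-object", {
  # noise-free, blur-free, artifact-free: retained count equals planted and
  # each centroid matches a distinct planted centre within one voxel
  sim <- clean_sim(c(80, 80, 80))
  mask <- array(TRUE, c(80, 80, 80))
  # diameters clear of the 8 um floor so rasterization jitter cannot drop
  # a planted object below the counting threshold
  d <- sample_diameters(size_dist_spec("empirical_bins",
                                       bin_edges_um = c(10, 40), probs = 1),
                        25, seed = 31)
  plq <- place_plaques(mask, d, min_separation_um = 5, seed = 32,
                       voxel_size_um = 2)
  seg <- segment_plaques(rasterize_plaques(plq, sim))
  rec <- seg$records[seg$records$retained, ]
  expect_equal(nrow(rec), nrow(plq))
  got <- as.matrix(rec[, c("centroid_z_um", "centroid_y_um",
                           "centroid_x_um")])
  want <- as.matrix(plq[, c("z_um", "y_um", "x_um")])
  dmat <- outer(seq_len(nrow(got)), seq_len(nrow(want)),
                Vectorize(function(i, j) sqrt(sum((got[i, ] - want[j, ])^2))))
  nearest <- apply(dmat, 1, which.min)
  expect_equal(sort(nearest), seq_len(nrow(want))) # one-to-one
  expect_true(all(dmat[cbind(seq_len(nrow(got)), nearest)] <= 2))
})

test_that("an explicit exclusion mask removes foreground before labeling", {
  sim <- clean_sim(c(30, 20, 20))
  plq <- tibble::tibble(z_um = c(12, 44), y_um = c(20, 20),
                        x_um = c(20, 20), diameter_um = c(10, 10))
  g <- rasterize_plaques(plq, sim)
  ex <- array(FALSE, c(30, 20, 20))
  ex[1:10, , ] <- TRUE # covers the first sphere
  seg <- segment_plaques(g, exclusion_mask = ex)
  expect_equal(nrow(seg$records), 1)
  expect_gt(seg$records$centroid_z_um, 20)
})
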