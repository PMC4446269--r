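#' Segment and quantify one animal volume over its sample cubes
#'
#' Runs [segment_plaques()] and then per-cube counting
#' ([cube_count_density()]) and plaque load ([cube_plaque_load()]).
#'
#' @param grid imaged [voxel_grid()].
#' @param cubes cube tibble (from [place_sample_cubes()] or the exact-totals
#'   layout of [generate_cohort()]).
#' @param seg_params a [segmentation_params()].
#' @return List with `records` (plaque tibble), `per_cube` (cube tibble with
#'   `count`, `density_per_mm3`, `load_percent`) and `threshold`.
#' @export
quantify_animal <- function(grid, cubes, seg_params = segmentation_params()) {
  seg <- segment_plaques(grid, seg_params)
  per_cube <- cube_count_density(seg$records, cubes)
  retained_ids <- seg$records$id[seg$records$retained]
  per_cube <- cube_plaque_load(seg$labels, retained_ids, per_cube)
  list(records = seg$records, per_cube = per_cube, threshold = seg$threshold)
}

#' Simulation conditions for planted-total recovery runs
#'
#' The validation scenario under which planted plaque totals are recovered
#' exactly: 4 um isotropic voxels, 12-bit camera, background 100 and plaque
#' amplitude 3000 counts, standard PSF widths (2 um lateral, 5 um axial
#' FWHM), a weakly focused sheet (waist half-width 30 um, Rayleigh range
#' ~7 mm) so the whole field is imaged near the waist, no attenuation, and
#' Gaussian read noise of 20 counts.
#'
#' @return A [simulation_config()].
#' @export
recovery_sim_config <- function() {
  simulation_config(
    voxel_size_um = c(4, 4, 4),
    bit_depth = 12L,
    background_level = 100,
    plaque_amplitude = 3000,
    lateral_fwhm_um = 2,
    axial_fwhm_um = 5,
    sheet_waist_halfwidth_w0_um = 30,
    wavelength_um = 0.405,
    attenuation_mu_per_mm = 0,
    noise_gaussian_sd = 20,
    noise_poisson = FALSE
  )
}

#' Plant exact group totals and recover them with the full pipeline
#'
#' Generates an exact-totals cohort (plaques planted only inside the
#' pre-declared sample cubes, summing to each group's requested total),
#' images it, and runs segmentation + cube counting per animal, streaming so
#' only one volume is in memory at a time.
#'
#' @param groups list of [cohort_group()]s with `total_in_cubes` set.
#' @param sim a [simulation_config()] (default [recovery_sim_config()]).
#' @param seg_params segmentation parameters.
#' @param cube_edge_vox,cube_layout,cube_margin_vox cube geometry per animal.
#' @param min_separation_um sphere separation floor.
#' @param seed integer master seed.
#' @return List: `per_cube` (tibble animal/group/cube with planted and
#'   recovered counts and density), `group_totals` (planted vs recovered per
#'   group), `diameters` (retained equivalent diameters per animal).
#' @export
recover_planted_totals <- function(groups,
                                   sim = recovery_sim_config(),
                                   seg_params = segmentation_params(),
                                   cube_edge_vox = 120L,
                                   cube_layout = c(1L, 2L, 3L),
                                   cube_margin_vox = 8L,
                                   min_separation_um = 10,
                                   seed = 1L) {
  res <- generate_cohort(
    groups, sim, mode = "exact_totals",
    cube_edge_vox = cube_edge_vox, cube_layout = cube_layout,
    cube_margin_vox = cube_margin_vox,
    min_separation_um = min_separation_um,
    n_vessels = 0L, n_stripes = 0L, seed = seed,
    process = function(animal) {
      an_id <- animal$animal
      an_grp <- animal$group
      q <- quantify_animal(animal$grid, animal$cubes, seg_params)
      planted <- animal$truth |>
        dplyr::filter(.data$object_type == "plaque") |>
        dplyr::count(.data$cube_id, name = "planted")
      per_cube <- q$per_cube |>
        dplyr::left_join(planted, by = "cube_id") |>
        dplyr::mutate(planted = dplyr::coalesce(.data$planted, 0L),
                      animal = an_id, group = an_grp)
      diams <- q$records |>
        dplyr::filter(.data$retained) |>
        dplyr::transmute(animal = an_id, group = an_grp,
                         diameter_um = .data$equivalent_diameter_um)
      list(per_cube = per_cube, diameters = diams)
    }
  )
  per_cube <- dplyr::bind_rows(lapply(res$processed, `[[`, "per_cube"))
  diameters <- dplyr::bind_rows(lapply(res$processed, `[[`, "diameters"))
  group_totals <- per_cube |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(planted = sum(.data$planted),
                     recovered = sum(.data$count), .groups = "drop")
  list(per_cube = per_cube, group_totals = group_totals,
       diameters = diameters)
}

#' Measure a recovered plaque size distribution through the pipeline
#'
#' Generates a cohort whose plaques follow a known size distribution,
#' rasterizes without blur or noise, segments with the default filter and
#' returns the recovered equivalent diameters and their binned fractions —
#' the end-to-end check that pipeline size fractions reproduce the planted
#' distribution.
#'
#' @param size_dist a [size_dist_spec()].
#' @param n_animals animals to spread the plaques over.
#' @param n_per_animal planted plaques per animal.
#' @param grid_shape per-animal grid in voxels `(z, y, x)`.
#' @param voxel_size_um voxel size (default 2 um isotropic).
#' @param min_separation_um sphere separation floor.
#' @param seg_params segmentation parameters.
#' @param edges_um histogram bin edges.
#' @param seed integer master seed.
#' @return List: `diameters` (tibble animal, diameter_um of retained
#'   objects), `histogram` (a [size_histogram()]) and `n_planted`.
#' @export
measure_size_distribution <- function(size_dist = adult_size_distribution(),
                                      n_animals = 5L,
                                      n_per_animal = 1000L,
                                      grid_shape = c(320L, 220L, 220L),
                                      voxel_size_um = c(2, 2, 2),
                                      min_separation_um = 4,
                                      seg_params = segmentation_params(),
                                      edges_um = c(8, 10, 20, 30, 40, 50, Inf),
                                      seed = 1L) {
  sim <- simulation_config(
    grid_shape = grid_shape, voxel_size_um = voxel_size_um,
    background_level = 100, plaque_amplitude = 3000,
    noise_gaussian_sd = 0, noise_poisson = FALSE
  )
  out <- vector("list", n_animals)
  for (a in seq_len(n_animals)) {
    d <- sample_diameters(size_dist, n_per_animal,
                          seed = derive_seed(seed, 2L * a))
    mask <- array(TRUE, unname(sim$grid_shape))
    plq <- place_plaques(mask, d, min_separation_um,
                         seed = derive_seed(seed, 2L * a + 1L),
                         voxel_size_um = unname(sim$voxel_size_um))
    grid <- rasterize_plaques(plq, sim)
    seg <- segment_plaques(grid, seg_params)
    out[[a]] <- seg$records |>
      dplyr::filter(.data$retained) |>
      dplyr::transmute(animal = sprintf("animal_%d", a),
                       diameter_um = .data$equivalent_diameter_um)
  }
  diameters <- dplyr::bind_rows(out)
  list(diameters = diameters,
       histogram = size_histogram(diameters$diameter_um, edges_um),
       n_planted = n_animals * n_per_animal)
}

#' Default demonstration pipeline configuration
#'
#' A small two-group, two-animal cohort on coarse grids: quick to run while
#' exercising every pipeline stage (simulation with artifacts, segmentation
#' with exclusion, cube quantification, group statistics).
#'
#' @return Config list for [run_pipeline()].
#' @export
demo_config <- function() {
  list(
    groups = list(
      cohort_group("young", n_animals = 2L,
                   size_dist = size_dist_spec("empirical_bins",
                                              bin_edges_um = c(9, 16, 24),
                                              probs = c(0.7, 0.3)),
                   density_per_mm3 = 2500),
      cohort_group("adult", n_animals = 2L,
                   size_dist = size_dist_spec("empirical_bins",
                                              bin_edges_um = c(9, 20, 34),
                                              probs = c(0.5, 0.5)),
                   density_per_mm3 = 7000)
    ),
    sim = simulation_config(
      grid_shape = c(96L, 96L, 96L), voxel_size_um = c(4, 4, 4),
      background_level = 100, plaque_amplitude = 3000,
      sheet_waist_halfwidth_w0_um = 30, noise_gaussian_sd = 15
    ),
    segmentation = segmentation_params(),
    quantification = quant_params(histogram_edges_um = c(8, 10, 20, 30, 40,
                                                         50, Inf)),
    n_vessels = 1L,
    n_stripes = 1L
  )
}

#' Run the full simulate-segment-quantify-stats pipeline
#'
#' Executes all stages on a configured cohort and assembles a report:
#' per-cube counts/densities/loads, per-animal summaries, group-level
#' Mann-Whitney tests on per-animal means (per-animal values are the
#' statistical unit, avoiding pseudo-replication; per-cube tests are emitted
#' as exploratory), a within-group Kruskal-Wallis across animals, size
#' histograms and per-bin group fraction comparisons. A supplementary
#' two-sample t statistic on plaque load is reported alongside the primary
#' Mann-Whitney result.
#'
#' @param config config list as from [demo_config()].
#' @param seed integer master seed; every stage seed derives from it.
#' @param out_dir optional output directory for the report bundle (JSON +
#'   CSV tables).
#' @return Report list (invisibly when `out_dir` is given).
#' @export
run_pipeline <- function(config = demo_config(), seed = 1L, out_dir = NULL) {
  t0 <- Sys.time()
  log_stage <- function(...) message(sprintf("[%s] %s",
                                             format(Sys.time(), "%H:%M:%S"),
                                             sprintf(...)))
  log_stage("simulate: %d group(s)", length(config$groups))
  qp <- config$quantification %||% quant_params()
  sp <- config$segmentation %||% segmentation_params()
  cohort <- generate_cohort(
    config$groups, config$sim, mode = "density",
    n_vessels = config$n_vessels %||% 0L,
    n_stripes = config$n_stripes %||% 0L,
    seed = seed
  )
  log_stage("segment + quantify: %d animals", length(cohort$animals))
  per_cube <- list()
  records_all <- list()
  for (animal in cohort$animals) {
    cortex <- segment_cortex(
      voxel_grid(array(TRUE, dim(animal$grid$data)),
                 animal$grid$voxel_size_um, animal$grid$bit_depth),
      mode = "mask"
    )
    cubes <- place_sample_cubes(cortex, qp,
                                seed = derive_seed(seed, 1000L +
                                                     length(per_cube)))
    q <- quantify_animal(animal$grid, cubes, sp)
    an_id <- animal$animal
    an_grp <- animal$group
    per_cube[[an_id]] <- q$per_cube |>
      dplyr::mutate(animal = an_id, group = an_grp)
    records_all[[an_id]] <- q$records |>
      dplyr::mutate(animal = an_id, group = an_grp)
  }
  per_cube <- dplyr::bind_rows(per_cube)
  records <- dplyr::bind_rows(records_all)

  log_stage("stats")
  per_animal <- per_cube |>
    dplyr::group_by(.data$animal, .data$group) |>
    dplyr::summarise(total_count = sum(.data$count),
                     mean_density_per_mm3 = mean(.data$density_per_mm3),
                     mean_load_percent = mean(.data$load_percent),
                     .groups = "drop")
  groups <- vapply(config$groups, `[[`, character(1), "name")
  split_by <- function(col) {
    lapply(groups, function(g) per_animal[[col]][per_animal$group == g])
  }
  dens <- split_by("mean_density_per_mm3")
  load <- split_by("mean_load_percent")
  group_tests <- dplyr::bind_rows(
    dplyr::mutate(tidy(mann_whitney_u(dens[[1]], dens[[2]])),
                  quantity = "density_per_mm3", scope = "per_animal"),
    dplyr::mutate(tidy(mann_whitney_u(load[[1]], load[[2]])),
                  quantity = "load_percent", scope = "per_animal"),
    {
      tt <- stats::t.test(load[[1]], load[[2]])
      tibble::tibble(statistic = unname(tt$statistic),
                     p_value = tt$p.value,
                     method = "Welch two-sample t (supplementary)",
                     stars = significance_stars(tt$p.value),
                     quantity = "load_percent", scope = "per_animal")
    }
  )
  # exploratory per-cube comparison, flagged as such
  dens_cube <- lapply(groups, function(g) {
    per_cube$density_per_mm3[per_cube$group == g]
  })
  group_tests <- dplyr::bind_rows(
    group_tests,
    dplyr::mutate(tidy(mann_whitney_u(dens_cube[[1]], dens_cube[[2]])),
                  quantity = "density_per_mm3",
                  scope = "per_cube_exploratory")
  )
  within_group <- dplyr::bind_rows(lapply(groups, function(g) {
    d <- per_cube[per_cube$group == g, ]
    counts <- split(d$count, d$animal)
    dplyr::mutate(tidy(kruskal_wallis(counts)), group = g,
                  quantity = "count_across_animals")
  }))
  diam <- records |>
    dplyr::filter(.data$retained) |>
    dplyr::transmute(.data$animal, .data$group,
                     diameter_um = .data$equivalent_diameter_um)
  histograms <- lapply(stats::setNames(groups, groups), function(g) {
    size_histogram(diam$diameter_um[diam$group == g], qp$histogram_edges_um)
  })
  fractions <- compare_group_fractions(diam, qp$histogram_edges_um,
                                       group_order = groups)

  report <- list(
    seed = seed,
    generated = length(cohort$animals),
    per_cube = per_cube,
    per_animal = per_animal,
    group_tests = group_tests,
    within_group = within_group,
    histograms = lapply(histograms, function(h) as.data.frame(h)),
    fraction_comparison = fractions
  )
  validate_report(report)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_table(per_cube, file.path(out_dir, "per_cube.csv"))
    write_table(per_animal, file.path(out_dir, "per_animal.csv"))
    write_table(records |> dplyr::select(-dplyr::any_of(c("labels"))),
                file.path(out_dir, "plaques.csv"))
    write_table(group_tests, file.path(out_dir, "group_stats.csv"))
    write_table(fractions, file.path(out_dir, "fractions.csv"))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows",
                         pretty = TRUE)
  }
  log_stage("done in %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))
  if (is.null(out_dir)) report else invisible(report)
}

# minimal structural validation of the report bundle
validate_report <- function(report) {
  required <- c("seed", "per_cube", "per_animal", "group_tests",
                "histograms", "fraction_comparison")
  missing <- setdiff(required, names(report))
  if (length(missing) > 0) {
    stop("report is missing fields: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  cube_cols <- c("cube_id", "count", "density_per_mm3", "load_percent",
                 "animal", "group")
  if (!all(cube_cols %in% names(report$per_cube))) {
    stop("per_cube table lacks required columns", call. = FALSE)
  }
  invisible(TRUE)
}

#' Measure the off-waist plaque-merging artifact
#'
#' Where the Gaussian light sheet has thickened (several Rayleigh ranges from
#' its waist), close plaque pairs blur into single segmented objects, which
#' inflates the apparent fraction of very large plaques. This builds one
#' scene of sphere pairs separated by `gap_um` along the optical axis and
#' images it twice with identical optics: once with the sheet waist on the
#' scene and once with the scene `n_rayleigh` Rayleigh ranges off-waist;
#' both images are segmented identically.
#'
#' @param d_um sphere diameter of each pair member.
#' @param gap_um surface-to-surface gap along z.
#' @param n_pairs number of pairs in the scene.
#' @param n_rayleigh how many Rayleigh ranges off-waist the second image is.
#' @param sim optics template (waist, wavelength, PSF); noise is disabled.
#' @param threshold segmentation threshold; default halfway between
#'   background and amplitude.
#' @return Tibble with one row per imaging position (`waist`, `offwaist`):
#'   `n_objects`, `frac_gt50um` (fraction of segmented objects with
#'   equivalent diameter above 50 um), `sigma_z_um` (local sheet sigma).
#' @export
measure_offwaist_merging <- function(d_um = 40, gap_um = 6, n_pairs = 3,
                                     n_rayleigh = 3,
                                     sim = simulation_config(),
                                     threshold = NULL) {
  vs <- 2
  x_R <- pi * sim$sheet_waist_halfwidth_w0_um^2 / sim$wavelength_um
  pair_z <- c(-(d_um + gap_um) / 2, (d_um + gap_um) / 2)
  nz <- ceiling((d_um * 2 + gap_um + 60) / vs / 2) * 2
  ny <- ceiling((n_pairs * (d_um + 20) + 40) / vs)
  nx <- ceiling((d_um + 60) / vs)
  x_s <- nx * vs / 2
  plq <- dplyr::bind_rows(lapply(seq_len(n_pairs), function(i) {
    y <- 20 + (i - 0.5) * (d_um + 20)
    tibble::tibble(z_um = nz * vs / 2 + pair_z, y_um = y, x_um = x_s,
                   diameter_um = d_um)
  }))
  base <- simulation_config(
    grid_shape = c(nz, ny, nx), voxel_size_um = vs,
    background_level = sim$background_level,
    plaque_amplitude = sim$plaque_amplitude,
    lateral_fwhm_um = sim$lateral_fwhm_um,
    axial_fwhm_um = sim$axial_fwhm_um,
    sheet_waist_halfwidth_w0_um = sim$sheet_waist_halfwidth_w0_um,
    wavelength_um = sim$wavelength_um,
    noise_gaussian_sd = 0, noise_poisson = FALSE
  )
  thr <- threshold %||%
    (base$background_level +
       0.5 * (base$plaque_amplitude - base$background_level))
  raster <- rasterize_plaques(plq, base)
  sigma_z0 <- base$axial_fwhm_um / (2 * sqrt(2 * log(2)))
  out <- lapply(c(waist = 0, offwaist = n_rayleigh), function(k) {
    cfg <- base
    cfg$field_center_x_um <- x_s - k * x_R
    img <- apply_lightsheet_blur(raster, cfg)
    seg <- segment_plaques(img, segmentation_params(fixed_threshold = thr))
    rec <- seg$records
    tibble::tibble(
      n_objects = nrow(rec),
      frac_gt50um = mean(rec$equivalent_diameter_um > 50),
      sigma_z_um = sigma_z0 * sqrt(1 + k^2)
    )
  })
  dplyr::bind_rows(out, .id = "position")
}
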