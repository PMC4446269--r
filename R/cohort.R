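#' Define a cohort group
#'
#' @param name group label (e.g. `"young"`, `"adult"`).
#' @param n_animals animals in the group (the published design used 5).
#' @param size_dist a [size_dist_spec()] for plaque diameters.
#' @param density_per_mm3 plaque number density (density mode). The source
#'   study reports no density, so this is an explicit configuration choice.
#' @param total_in_cubes exact-totals mode: requested total planted plaque
#'   count summed over all of this group's sample-cube regions.
#' @return List of class `cohort_group`.
#' @export
cohort_group <- function(name, n_animals = 5L, size_dist,
                         density_per_mm3 = NULL, total_in_cubes = NULL) {
  stopifnot(inherits(size_dist, "size_dist_spec"))
  structure(
    list(name = name, n_animals = as.integer(n_animals),
         size_dist = size_dist, density_per_mm3 = density_per_mm3,
         total_in_cubes = total_in_cubes),
    class = "cohort_group"
  )
}

# deterministic stream of derived seeds, kept below 2^31
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + 104729 * k) %% 2147483629)
}

# pre-declared cube layout for exact-totals planting: cubes on a regular
# (z, y, x) grid with a margin between and around them
plan_cube_layout <- function(cube_layout, cube_edge_vox, margin_vox, vs) {
  pitch <- cube_edge_vox + margin_vox
  grid_shape <- cube_layout * pitch + margin_vox
  origins <- expand.grid(
    iz = seq_len(cube_layout[1]), iy = seq_len(cube_layout[2]),
    ix = seq_len(cube_layout[3])
  )
  tibble::tibble(
    cube_id = seq_len(nrow(origins)),
    z0 = margin_vox + (origins$iz - 1L) * pitch + 1L,
    y0 = margin_vox + (origins$iy - 1L) * pitch + 1L,
    x0 = margin_vox + (origins$ix - 1L) * pitch + 1L,
    ez = cube_edge_vox, ey = cube_edge_vox, ex = cube_edge_vox,
    vs_z = vs[1], vs_y = vs[2], vs_x = vs[3],
    origin_z_um = (margin_vox + (origins$iz - 1L) * pitch) * vs[1],
    origin_y_um = (margin_vox + (origins$iy - 1L) * pitch) * vs[2],
    origin_x_um = (margin_vox + (origins$ix - 1L) * pitch) * vs[3],
    edge_um = cube_edge_vox * vs[1],
    volume_mm3 = prod(cube_edge_vox * vs) / 1e9,
    hemisphere = "right"
  ) -> cubes
  list(cubes = cubes, grid_shape = as.integer(grid_shape))
}

# split an exact total over n_parts: floor share everywhere, remainder to the
# first cells in order (deterministic)
split_exact_total <- function(total, n_parts) {
  base <- total %/% n_parts
  rem <- total %% n_parts
  base + (seq_len(n_parts) <= rem)
}

#' Image a planted scene through the synthetic light-sheet model
#'
#' Applies, in order: Rayleigh-range axial blur + lateral blur, depth
#' attenuation, and camera noise + quantization, as configured.
#'
#' @param grid rasterized [voxel_grid()].
#' @param sim a [simulation_config()].
#' @param seed optional integer seed (noise).
#' @return Imaged integer [voxel_grid()].
#' @export
image_scene <- function(grid, sim, seed = NULL) {
  g <- apply_lightsheet_blur(grid, sim)
  g <- apply_attenuation(g, sim$attenuation_mu_per_mm, "y")
  add_noise_and_quantize(g, sim, seed = seed)
}

#' Generate a synthetic cohort of plaque-bearing brain volumes
#'
#' Stands in for cleared APPPS1 brains: for each animal a 3D volume is
#' generated with planted quasi-spherical plaques (group-specific size
#' distribution), optional vessel and stripe artifacts, light-sheet blur,
#' attenuation and camera noise, together with exact ground truth.
#'
#' Two planting modes. `"density"` draws
#' `round(density_per_mm3 x cortex volume)` plaques anywhere in the cortex
#' mask (the full grid). `"exact_totals"` plants plaques only inside a
#' pre-declared sample-cube layout so that the summed planted count across
#' all of a group's cube regions equals `total_in_cubes` exactly — the
#' configuration under which pipeline counts are directly comparable to
#' planted totals without edge ambiguity.
#'
#' @param groups list of [cohort_group()]s.
#' @param sim a [simulation_config()]; in exact-totals mode the grid shape
#'   is derived from the cube layout and the configured shape is ignored.
#' @param mode `"density"` or `"exact_totals"`.
#' @param cube_edge_vox,cube_layout,cube_margin_vox exact-totals cube
#'   geometry: cube edge in voxels, cubes per axis `(z, y, x)`, margin.
#' @param min_separation_um minimum sphere surface-to-surface gap.
#' @param n_vessels,n_stripes artifacts per animal.
#' @param seed integer master seed; all per-animal seeds derive from it.
#' @param out_dir optional directory: writes `<group>_<animal>.tif` (+ JSON
#'   sidecar), `cortex_<group>_<animal>.tif`, `truth.csv`, `cubes.csv` and
#'   `config.json`.
#' @param process optional `function(animal)` applied to each generated
#'   animal in turn; when given, volumes are not accumulated in memory and
#'   the callback's results are returned in `$processed` instead.
#' @return List with `truth` (tibble over all animals), `cubes`
#'   (exact-totals mode), and `animals` (list with per-animal `grid`,
#'   `cortex`, `truth`) or `processed`.
#' @export
generate_cohort <- function(groups, sim = simulation_config(),
                            mode = c("density", "exact_totals"),
                            cube_edge_vox = 120L,
                            cube_layout = c(1L, 2L, 3L),
                            cube_margin_vox = 8L,
                            min_separation_um = 10,
                            n_vessels = 0L, n_stripes = 0L,
                            seed = 1L, out_dir = NULL, process = NULL) {
  mode <- match.arg(mode)
  if (inherits(groups, "cohort_group")) groups <- list(groups)
  vs <- unname(sim$voxel_size_um)
  layout <- NULL
  if (mode == "exact_totals") {
    layout <- plan_cube_layout(as.integer(cube_layout),
                               as.integer(cube_edge_vox),
                               as.integer(cube_margin_vox), vs)
  }
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  truth_all <- list()
  cubes_all <- list()
  animals <- list()
  processed <- list()
  k <- 0L
  for (grp in groups) {
    n_cubes <- if (mode == "exact_totals") nrow(layout$cubes) else NA_integer_
    per_cube <- NULL
    if (mode == "exact_totals") {
      if (is.null(grp$total_in_cubes)) {
        stop("exact_totals mode needs total_in_cubes for group ", grp$name,
             call. = FALSE)
      }
      per_cube <- split_exact_total(grp$total_in_cubes,
                                    grp$n_animals * n_cubes)
    }
    for (a in seq_len(grp$n_animals)) {
      k <- k + 1L
      animal_id <- sprintf("%s_%d", grp$name, a)
      s_place <- derive_seed(seed, 4L * k)
      s_diam <- derive_seed(seed, 4L * k + 1L)
      s_noise <- derive_seed(seed, 4L * k + 2L)
      s_art <- derive_seed(seed, 4L * k + 3L)

      if (mode == "exact_totals") {
        grid_shape <- layout$grid_shape
        cubes <- layout$cubes
        plaques <- list()
        for (ci in seq_len(n_cubes)) {
          n_here <- per_cube[(a - 1L) * n_cubes + ci]
          if (n_here == 0L) next
          d <- sample_diameters(grp$size_dist, n_here,
                                seed = derive_seed(s_diam, ci))
          # place in a local cube-sized mask, then shift to the cube origin
          cube_mask <- array(TRUE, c(cubes$ez[ci], cubes$ey[ci],
                                     cubes$ex[ci]))
          plaques[[ci]] <- place_plaques(cube_mask, d, min_separation_um,
                                         seed = derive_seed(s_place, ci),
                                         voxel_size_um = vs) |>
            dplyr::mutate(z_um = .data$z_um + cubes$origin_z_um[ci],
                          y_um = .data$y_um + cubes$origin_y_um[ci],
                          x_um = .data$x_um + cubes$origin_x_um[ci],
                          cube_id = cubes$cube_id[ci])
        }
        plaques <- dplyr::bind_rows(plaques)
        cortex_mask <- NULL # cortex = bounding box of the cube layout
      } else {
        grid_shape <- unname(sim$grid_shape)
        cubes <- NULL
        cortex_mask <- array(TRUE, grid_shape)
        v_mm3 <- prod(grid_shape * vs) / 1e9
        n_plq <- as.integer(round(grp$density_per_mm3 * v_mm3))
        d <- sample_diameters(grp$size_dist, n_plq, seed = s_diam)
        plaques <- place_plaques(cortex_mask, d, min_separation_um,
                                 seed = s_place, voxel_size_um = vs)
      }

      sim_a <- sim
      sim_a$grid_shape <- stats::setNames(as.integer(grid_shape),
                                          c("z", "y", "x"))
      raster <- rasterize_plaques(plaques, sim_a)
      vessels <- add_vessels(raster, n_vessels, seed = s_art,
                             intensity = sim$plaque_amplitude)
      stripes <- add_stripes(vessels$grid, n_stripes,
                             seed = derive_seed(s_art, 1L),
                             intensity = sim$plaque_amplitude)
      grid <- image_scene(stripes$grid, sim_a, seed = s_noise)

      truth <- dplyr::bind_rows(
        plaques |>
          dplyr::mutate(animal = animal_id, group = grp$name,
                        object_type = "plaque"),
        if (nrow(vessels$vessels) > 0) {
          vessels$vessels |>
            dplyr::transmute(z_um = .data$z_um, y_um = .data$y_um,
                             x_um = .data$x_um, diameter_um = NA_real_,
                             animal = animal_id, group = grp$name,
                             object_type = "vessel")
        },
        if (nrow(stripes$stripes) > 0) {
          stripes$stripes |>
            dplyr::transmute(z_um = (.data$z_vox - 0.5) * vs[1],
                             y_um = (.data$y_vox - 0.5) * vs[2],
                             x_um = grid_shape[3] * vs[3] / 2,
                             diameter_um = NA_real_,
                             animal = animal_id, group = grp$name,
                             object_type = "stripe")
        }
      )
      truth_all[[k]] <- truth
      if (!is.null(cubes)) {
        cubes_all[[k]] <- dplyr::mutate(cubes, animal = animal_id,
                                        group = grp$name)
      }

      animal <- list(animal = animal_id, group = grp$name, grid = grid,
                     truth = truth, cubes = cubes,
                     artifact_voxels = list(vessel = vessels$voxel_idx,
                                            stripe = stripes$voxel_idx),
                     seed = c(place = s_place, diam = s_diam,
                              noise = s_noise, art = s_art))
      if (!is.null(out_dir)) {
        write_volume(grid, file.path(out_dir, paste0(animal_id, ".tif")),
                     provenance = list(seed = seed, animal = animal_id))
        cm <- if (is.null(cortex_mask)) array(1L, grid_shape) else
          cortex_mask + 0L
        write_volume(voxel_grid(cm, vs, 8L),
                     file.path(out_dir, paste0("cortex_", animal_id, ".tif")))
      }
      if (!is.null(process)) {
        processed[[k]] <- process(animal)
      } else {
        animals[[k]] <- animal
      }
    }
  }
  truth <- dplyr::bind_rows(truth_all)
  cubes <- if (length(cubes_all) > 0) dplyr::bind_rows(cubes_all) else NULL
  if (!is.null(out_dir)) {
    write_table(truth |>
                  dplyr::select(dplyr::all_of(c("animal", "group", "x_um",
                                                "y_um", "z_um", "diameter_um",
                                                "object_type"))),
                file.path(out_dir, "truth.csv"))
    if (!is.null(cubes)) write_table(cubes, file.path(out_dir, "cubes.csv"))
    write_config(list(sim = sim, mode = mode, seed = seed),
                 file.path(out_dir, "config.json"))
  }
  list(truth = truth, cubes = cubes,
       animals = if (is.null(process)) animals else NULL,
       processed = if (is.null(process)) NULL else processed)
}
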