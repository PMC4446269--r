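#' Write a volume as a multi-page TIFF with a JSON sidecar
#'
#' One TIFF page per z-slice, 16-bit little-endian container (12-bit data
#' fits losslessly). Voxel sizes are carried in a JSON sidecar
#' (`<path>.json`) because plain TIFF z-spacing tags are unreliable across
#' dialects; the sidecar also records the bit depth, axis order and optional
#' provenance (config hash, seed).
#'
#' @param grid an integer-valued [voxel_grid()].
#' @param path output TIFF path.
#' @param provenance optional named list stored in the sidecar.
#' @param compression `"none"` (default) or `"deflate"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(grid, path, provenance = NULL,
                         compression = c("none", "deflate")) {
  stopifnot(is_voxel_grid(grid))
  compression <- match.arg(compression)
  arr <- grid$data
  if (any(arr != round(arr)) || min(arr) < 0 || max(arr) > 65535) {
    stop("volume must hold integers in [0, 65535] to write losslessly",
         call. = FALSE)
  }
  pages <- lapply(seq_len(dim(arr)[1]), function(z) arr[z, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                  compression = compression)
  meta <- list(
    voxel_size_um = as.list(grid$voxel_size_um),
    bit_depth = grid$bit_depth,
    axis_order = "zyx",
    provenance = provenance
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a multi-page TIFF volume and its sidecar metadata
#'
#' @param path TIFF path written by [write_volume()] (sidecar
#'   `<path>.json` must exist).
#' @return A [voxel_grid()]; the sidecar metadata (including provenance) is
#'   attached as attribute `meta`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    stop("missing voxel-size metadata: expected sidecar config at ", sidecar,
         "; write one with voxel_size_um (z, y, x), bit_depth and axis_order",
         call. = FALSE)
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  shapes <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1])) {
    stop("inconsistent page shapes across the TIFF stack", call. = FALSE)
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (!identical(meta$axis_order, "zyx")) {
    stop("unsupported axis order tag: ", meta$axis_order, call. = FALSE)
  }
  nz <- length(pages)
  arr <- array(0, c(nz, shapes[1, 1], shapes[2, 1]))
  for (z in seq_len(nz)) arr[z, , ] <- pages[[z]]
  vs <- unlist(meta$voxel_size_um)[c("z", "y", "x")]
  g <- voxel_grid(arr, vs, as.integer(meta$bit_depth))
  attr(g, "meta") <- meta
  g
}

#' Write a data table as CSV with a type-preserving schema sidecar
#'
#' RFC 4180 CSV (header row, UTF-8, "." decimal) via readr, plus a small
#' `<path>.schema.json` recording column classes so that reads restore
#' integer/double/logical/character types exactly.
#'
#' @param df data frame or tibble.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  readr::write_csv(df, path, progress = FALSE)
  schema <- vapply(df, function(col) class(col)[1], character(1))
  jsonlite::write_json(as.list(schema), paste0(path, ".schema.json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' Read a CSV table written by [write_table()]
#'
#' When the schema sidecar is present, column types are restored from it and
#' columns in the file that the schema does not name raise a schema error.
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  schema_path <- paste0(path, ".schema.json")
  if (file.exists(schema_path)) {
    schema <- unlist(jsonlite::read_json(schema_path, simplifyVector = TRUE))
    header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
    unknown <- setdiff(header, names(schema))
    if (length(unknown) > 0) {
      stop("schema error: unknown columns ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    lookup <- c(integer = "i", numeric = "d", character = "c", logical = "l",
                factor = "c")
    types <- paste(unname(lookup[schema[header]]), collapse = "")
    readr::read_csv(path, col_types = types, progress = FALSE)
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
}

#' Load and validate a pipeline configuration file
#'
#' JSON or YAML by extension. Recognised sections are validated through the
#' package constructors: `simulation` -> [simulation_config()],
#' `segmentation` -> [segmentation_params()], `quantification` ->
#' [quant_params()], `size_distribution` -> [size_dist_spec()]; any other
#' top-level entries are kept as-is.
#'
#' @param path config path (`.json`, `.yaml` or `.yml`).
#' @return Named list with validated component configs.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop("unsupported config format: .", ext, call. = FALSE)
  )
  out <- raw
  if (!is.null(raw$simulation)) {
    out$simulation <- do.call(simulation_config, raw$simulation)
  }
  if (!is.null(raw$segmentation)) {
    out$segmentation <- do.call(segmentation_params, raw$segmentation)
  }
  if (!is.null(raw$quantification)) {
    out$quantification <- do.call(quant_params, raw$quantification)
  }
  if (!is.null(raw$size_distribution)) {
    out$size_distribution <- do.call(size_dist_spec, raw$size_distribution)
  }
  out
}

#' Echo a configuration object to JSON
#'
#' @param config a list or config object.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass_deep(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, unclass_deep)
  } else x
}
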