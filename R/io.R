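# Plain-text interchange: grids and cubes as CSV payloads with a JSON
# sidecar carrying variable, units, time axis, mask and geotransform.
# Registration between cubes and masks is checked, never resampled.

sidecar_path <- function(path) paste0(path, ".json")

#' Write a grid (matrix) with JSON sidecar
#'
#' Numeric or logical `rows x cols` matrix written as headerless CSV plus a
#' `<path>.json` sidecar with shape and geotransform.
#'
#' @param grid matrix.
#' @param path output CSV path.
#' @param geo optional geotransform list (`origin`, `px`, `crs`).
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path, geo = NULL) {
  stopifnot(is.matrix(grid))
  data.table::fwrite(data.table::as.data.table(`dimnames<-`(grid * 1, NULL)),
                     path, col.names = FALSE)
  meta <- list(kind = "grid", rows = nrow(grid), cols = ncol(grid),
               logical = is.logical(grid),
               geo = geo %||% list(origin = c(0, 0), px = c(1, -1),
                                   crs = "synthetic"))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a grid written by [write_grid()]
#'
#' @param path CSV path (its `.json` sidecar must exist).
#' @return Matrix with attribute `geo`.
#' @export
read_grid <- function(path) {
  if (!file.exists(path)) stop2("grid file not found: %s", path)
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  m <- as.matrix(data.table::fread(path, header = FALSE))
  dimnames(m) <- NULL
  if (!all(dim(m) == c(meta$rows, meta$cols)))
    stop2("grid %s does not match its sidecar shape", path)
  if (isTRUE(meta$logical)) m <- m > 0
  attr(m, "geo") <- meta$geo
  m
}

#' Write a climate cube with JSON sidecar
#'
#' The payload CSV holds the `time x pixel` matrix (pixels in column-major
#' grid order); the sidecar records dimensions, variable, units, start month,
#' processing flags, mask and geotransform.
#'
#' @param cube a [climate_cube()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path) {
  stopifnot(inherits(cube, "climate_cube"))
  m <- cube_matrix(cube)
  data.table::fwrite(data.table::as.data.table(m), path, col.names = FALSE)
  d <- dim(cube$data)
  meta <- list(kind = "cube", rows = d[1], cols = d[2], months = d[3],
               variable = cube$variable, units = cube$units,
               start = cube$start, flags = cube$flags,
               mask = as.integer(cube$mask), geo = cube$geo)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a cube written by [write_cube()]
#'
#' @param path CSV path (its `.json` sidecar must exist).
#' @return A [climate_cube()].
#' @export
read_cube <- function(path) {
  if (!file.exists(path)) stop2("cube file not found: %s", path)
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  if (!identical(meta$kind, "cube")) stop2("%s is not a cube payload", path)
  m <- as.matrix(data.table::fread(path, header = FALSE))
  dimnames(m) <- NULL
  if (!all(dim(m) == c(meta$months, meta$rows * meta$cols)))
    stop2("cube %s does not match its sidecar shape", path)
  mask <- matrix(meta$mask == 1L, meta$rows, meta$cols)
  climate_cube(array(t(m), dim = c(meta$rows, meta$cols, meta$months)),
               variable = meta$variable, units = meta$units,
               start = meta$start, mask = mask,
               geo = meta$geo, flags = as.list(meta$flags))
}

#' Write an index series as CSV
#'
#' Columns `year`, `month`, `value`; readable back with
#' [parse_index_csv()].
#'
#' @param series an [index_series()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_index_csv <- function(series, path) {
  stopifnot(inherits(series, "index_series"))
  mo <- month_seq(series$start, length(series))
  data.table::fwrite(data.frame(year = mo$year, month = mo$month,
                                value = series$values), path)
  invisible(path)
}

#' Write phase labels as CSV
#'
#' @param labels a [classify_phases()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_labels_csv <- function(labels, path) {
  stopifnot(inherits(labels, "phase_labels"))
  mo <- month_seq(labels$start, length(labels))
  data.table::fwrite(data.frame(year = mo$year, month = mo$month,
                                phase = as.character(labels$labels)), path)
  invisible(path)
}

#' Write a correlation map (r/p/n grids plus summary row)
#'
#' Three grid CSVs (`<prefix>_r.csv`, `_p.csv`, `_n.csv`) with sidecars, and
#' `<prefix>_summary.csv` with the [summarize_cmap()] row.
#'
#' @param cmap a [correlation_map()].
#' @param prefix output path prefix.
#' @return The prefix, invisibly.
#' @export
write_correlation_map <- function(cmap, prefix) {
  stopifnot(inherits(cmap, "correlation_map"))
  write_grid(cmap$r, paste0(prefix, "_r.csv"), geo = cmap$geo)
  write_grid(cmap$p, paste0(prefix, "_p.csv"), geo = cmap$geo)
  write_grid(cmap$n * 1, paste0(prefix, "_n.csv"), geo = cmap$geo)
  data.table::fwrite(summarize_cmap(cmap), paste0(prefix, "_summary.csv"))
  invisible(prefix)
}

#' Write a JSON run manifest
#'
#' Records the configuration, md5 hashes of the listed files, grid
#' conventions and package/R versions. Content is deterministic (no
#' timestamps), so identical runs produce identical manifests.
#'
#' @param config list echoed verbatim.
#' @param files character vector of produced files to hash.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, files, path) {
  files <- files[file.exists(files)]
  hashes <- as.list(tools::md5sum(files))
  names(hashes) <- basename(files)
  manifest <- list(
    config = config,
    conventions = list(
      grid = "north-up row order, pixel-centre registration",
      time = "half-open monthly intervals labelled by start month",
      lag = "positive lag: field responds after the index"),
    files = hashes,
    versions = list(ensotele = as.character(utils::packageVersion("ensotele")),
                    R = paste(R.version$major, R.version$minor, sep = ".")))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
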