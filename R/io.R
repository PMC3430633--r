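# Plain-text raster and table I/O.
#
# Rasters use the ESRI ASCII grid (.asc) format: a 6-line header
# (ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value) followed by rows
# of whitespace-separated values, top row first. The format is text-only
# and readable by every GIS.

#' Write / read a matrix as an ESRI ASCII grid
#'
#' @param m Numeric matrix (rows = grid rows, row 1 = northernmost).
#' @param path Output file path.
#' @param cell_size Cell edge in meters.
#' @param xll,yll Lower-left corner coordinates.
#' @param nodata NODATA sentinel (default -9999).
#' @return `write_ascii_grid`: the path, invisibly. `read_ascii_grid`: a
#'   list with `data` (matrix, `NA` for NODATA) and `cell_size`.
#' @export
write_ascii_grid <- function(m, path, cell_size = 231.7, xll = 0, yll = 0,
                             nodata = -9999) {
  m <- as.matrix(m)
  m[is.na(m)] <- nodata
  hdr <- c(
    paste("ncols", ncol(m)), paste("nrows", nrow(m)),
    paste("xllcorner", xll), paste("yllcorner", yll),
    paste("cellsize", cell_size), paste("NODATA_value", nodata)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(m, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6)
  val <- function(i) as.numeric(strsplit(hdr[i], "\\s+")[[1]][2])
  nc <- val(1); nr <- val(2); cs <- val(5); nd <- val(6)
  m <- as.matrix(utils::read.table(path, skip = 6))
  dimnames(m) <- NULL
  stopifnot(nrow(m) == nr, ncol(m) == nc)
  m[m == nd] <- NA
  list(data = m, cell_size = cs)
}

#' Export a synthetic scene to plain-text files
#'
#' Writes the partition (municipality ids) as a single ASCII grid, the
#' composite cube as one file per year and band
#' (`composites_<year>_<band>.asc` with 23 columns per pixel row is
#' impractical for grids, so each band-year is written as 23 grids
#' concatenated by composite index in a long CSV), and reference samples
#' as the standard sample CSV. In practice the CSV forms are what the
#' downstream CLI consumes.
#'
#' @param partition An `lulc_partition`.
#' @param cube Optional `lulc_cube`.
#' @param samples Optional `lulc_samples`.
#' @param out_dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
export_scene <- function(partition, cube = NULL, samples = NULL, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_ascii_grid(partition$municipality, file.path(out_dir, "municipality.asc"),
                   cell_size = partition$cell_size)
  write.csv(
    data.frame(municipality = seq_along(partition$biome_of),
               biome = partition$biome_of, ecoregion = partition$ecoregion_of),
    file.path(out_dir, "units.csv"), row.names = FALSE
  )
  if (!is.null(cube)) {
    for (b in names(cube$bands)) {
      df <- as.data.frame(cube$bands[[b]])
      names(df) <- paste0(b, "_", rep(cube$years, each = 23), "_",
                          rep(1:23, times = length(cube$years)))
      write.csv(df, file.path(out_dir, paste0("composites_", b, ".csv")),
                row.names = FALSE)
    }
    rel <- as.data.frame(cube$reliability)
    names(rel) <- paste0("rel_", rep(cube$years, each = 23), "_",
                         rep(1:23, times = length(cube$years)))
    write.csv(rel, file.path(out_dir, "reliability.csv"), row.names = FALSE)
  }
  if (!is.null(samples)) {
    write.csv(samples$interpretations, file.path(out_dir, "samples.csv"),
              row.names = FALSE)
    write.csv(samples$truth, file.path(out_dir, "samples_truth.csv"),
              row.names = FALSE)
  }
  invisible(out_dir)
}

#' Write annual five-class maps as ASCII grids
#'
#' One single-band integer grid per year (`map_<year>.asc`), coded
#' 0 = No Data, 1 = woody, 2 = mixed woody/plant, 3 = ag/herb,
#' 4 = bare/built, 5 = water.
#'
#' @param map_stack An `lulc_map_stack`.
#' @param out_dir Output directory.
#' @return The directory, invisibly.
#' @export
export_maps <- function(map_stack, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  part <- map_stack$partition
  for (y in seq_along(map_stack$years)) {
    write_ascii_grid(matrix(map_stack$labels5[, y], part$rows, part$cols),
                     file.path(out_dir, paste0("map_", map_stack$years[y], ".asc")),
                     cell_size = part$cell_size)
  }
  invisible(out_dir)
}

# key=value config reader for the CLI (lines starting with # ignored)
read_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- lapply(kv, function(x) {
    v <- trimws(x[2])
    suppressWarnings(n <- as.numeric(v))
    if (!is.na(n)) n else v
  })
  stats::setNames(vals, vapply(kv, function(x) trimws(x[1]), character(1)))
}
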