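#' Generate a synthetic landscape partition
#'
#' Tessellates a raster grid into municipalities by nearest-seed assignment
#' (Euclidean distance to seeded municipality centers, ties broken by the
#' lowest municipality id), then assigns every municipality to exactly one
#' biome and one ecoregion. The first `n_biomes` (`n_ecoregions`)
#' municipalities receive distinct units so that no unit is empty; the rest
#' are assigned at random. The partition is the spatial frame for all
#' downstream zonal statistics.
#'
#' @param rows,cols Grid dimensions in pixels.
#' @param n_municipalities Number of municipalities (`<= rows * cols`).
#' @param n_biomes,n_ecoregions Number of biome / ecoregion units
#'   (`<= n_municipalities`).
#' @param cell_size Pixel edge length in meters (default 231.7, the working
#'   resolution of the 250 m composite product).
#' @param seed Integer seed; identical seeds reproduce the partition
#'   bit-identically.
#' @return An object of class `lulc_partition`: a list with `rows`, `cols`,
#'   `cell_size`, `municipality` (integer matrix `rows x cols`), `biome_of`
#'   and `ecoregion_of` (integer vectors indexed by municipality id), and
#'   `pixel_counts` (pixels per municipality).
#' @examples
#' p <- generate_landscape(20, 20, n_municipalities = 4, seed = 1)
#' table(p$municipality)
#' @export
generate_landscape <- function(rows, cols, n_municipalities,
                               n_biomes = 1, n_ecoregions = 1,
                               cell_size = 231.7, seed = 1) {
  n_pix <- rows * cols
  if (rows < 1 || cols < 1) stop("grid dimensions must be >= 1")
  if (n_municipalities < 1 || n_municipalities > n_pix) {
    stop("n_municipalities must be between 1 and rows*cols (", n_pix, ")")
  }
  if (n_biomes < 1 || n_biomes > n_municipalities ||
      n_ecoregions < 1 || n_ecoregions > n_municipalities) {
    stop("n_biomes and n_ecoregions must be between 1 and n_municipalities")
  }

  set.seed(seed)
  seeds <- sample.int(n_pix, n_municipalities)
  seed_r <- (seeds - 1L) %% rows + 1L
  seed_c <- (seeds - 1L) %/% rows + 1L

  # nearest-seed tessellation, ties -> lowest municipality id
  pr <- rep(seq_len(rows), times = cols)
  pc <- rep(seq_len(cols), each = rows)
  d2 <- outer(pr, seed_r, function(a, b) (a - b)^2) +
    outer(pc, seed_c, function(a, b) (a - b)^2)
  muni <- max.col(-d2, ties.method = "first")

  assign_units <- function(n_units) {
    u <- integer(n_municipalities)
    u[seq_len(n_units)] <- seq_len(n_units)
    extra <- n_municipalities - n_units
    if (extra > 0) {
      u[(n_units + 1):n_municipalities] <-
        sample.int(n_units, extra, replace = TRUE)
    }
    u
  }
  biome_of <- assign_units(n_biomes)
  ecoregion_of <- assign_units(n_ecoregions)

  structure(
    list(
      rows = rows, cols = cols, cell_size = cell_size,
      municipality = matrix(muni, rows, cols),
      biome_of = biome_of, ecoregion_of = ecoregion_of,
      pixel_counts = tabulate(muni, nbins = n_municipalities)
    ),
    class = "lulc_partition"
  )
}

#' @export
print.lulc_partition <- function(x, ...) {
  cat("<lulc_partition> ", x$rows, "x", x$cols, " pixels (",
      x$cell_size, " m), ", length(x$pixel_counts), " municipalities, ",
      max(x$biome_of), " biome(s), ", max(x$ecoregion_of),
      " ecoregion(s)\n", sep = "")
  invisible(x)
}

#' Municipality area in square kilometers
#'
#' @param partition An `lulc_partition`.
#' @return Numeric vector of municipality areas (km^2), pixel count times
#'   squared cell size.
#' @export
municipality_areas_km2 <- function(partition) {
  partition$pixel_counts * cell_area_km2(partition$cell_size)
}

cell_area_km2 <- function(cell_size_m) (cell_size_m / 1000)^2
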