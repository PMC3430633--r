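#' Simulate a complete desk-scale scene
#'
#' Convenience wrapper chaining landscape generation, trajectory
#' realization, composite simulation and reference sampling with the
#' package defaults (60 x 60 pixels, 12 municipalities, 3 biomes, 4
#' ecoregions, 10 years) - a scene on which every stage runs in seconds.
#'
#' @param rows,cols,n_municipalities,n_biomes,n_ecoregions,years Scene
#'   dimensions.
#' @param trend_spec Optional `lulc_trend_spec`; by default municipalities
#'   get a woody/mixed/ag-herb mosaic with modest random woody trends.
#' @param phenology An `lulc_phenology` (defaults: noise 0.02, cloud 5%).
#' @param n_samples Reference footprints to place (default 100; the 1 km
#'   spacing rule caps feasible counts on a desk-scale grid).
#' @param seed Integer seed driving every stage.
#' @return List with `partition`, `cover`, `cube`, `samples`, `trend_spec`.
#' @export
simulate_scene <- function(rows = 60, cols = 60, n_municipalities = 12,
                           n_biomes = 3, n_ecoregions = 4, years = 10,
                           trend_spec = NULL, phenology = default_phenology(),
                           n_samples = 100, seed = 1) {
  part <- generate_landscape(rows, cols, n_municipalities, n_biomes,
                             n_ecoregions, seed = seed)
  if (is.null(trend_spec)) {
    trend_spec <- default_trend_spec(part, seed = seed + 1)
  }
  cover <- generate_trajectories(part, trend_spec, years = years,
                                 seed = seed + 2)
  cube <- simulate_composites(cover, phenology, seed = seed + 3)
  samples <- simulate_reference_samples(cover, n_samples, seed = seed + 4)
  list(partition = part, cover = cover, cube = cube, samples = samples,
       trend_spec = trend_spec)
}

#' Default mosaic trend specification
#'
#' Every municipality starts as a woody / mixed-woody / herb / ag / water
#' mosaic (55/15/15/10/5 percent) and receives a random woody trend drawn
#' from +-0.8 the municipality pixel-area per year, balanced against the
#' ag/herb classes; other classes are held flat. This emulates a landscape
#' where woody change trades against agriculture/herbaceous cover.
#'
#' @param partition An `lulc_partition`.
#' @param seed Integer seed for the municipality trend draws.
#' @return An `lulc_trend_spec`.
#' @export
default_trend_spec <- function(partition, seed = 1) {
  set.seed(seed)
  n_m <- length(partition$pixel_counts)
  px <- cell_area_km2(partition$cell_size)
  cls <- cover_classes8()
  P <- matrix(0, n_m, length(cls), dimnames = list(NULL, cls))
  P[, "woody"] <- 0.55
  P[, "mixed_woody"] <- 0.15
  P[, "herb"] <- 0.15
  P[, "ag"] <- 0.10
  P[, "water"] <- 0.05
  S <- matrix(0, n_m, length(cls), dimnames = list(NULL, cls))
  woody_px_per_yr <- runif(n_m, -0.8, 0.8) * partition$pixel_counts / 100
  S[, "woody"] <- woody_px_per_yr * px
  S[, "herb"] <- -0.6 * S[, "woody"]
  S[, "ag"] <- -0.4 * S[, "woody"]
  make_trend_spec(partition, P, S)
}

#' Run classification end-to-end on a simulated scene
#'
#' Labels the scene's reference samples (consensus + assignment rules,
#' expert resolutions from the simulator truth), extracts their features,
#' trains one classifier pair per biome, and builds the annual five-class
#' map stack.
#'
#' @param scene Output of [simulate_scene()].
#' @param config A [classifier_config()].
#' @param seed Integer seed for training.
#' @return List with `labeled`, `classifiers`, `maps`, `accuracy` (list of
#'   per-biome reports).
#' @export
run_classification <- function(scene, config = classifier_config(), seed = 1) {
  labeled <- label_samples(scene$samples$interpretations,
                           scene$samples$truth)
  labeled <- labeled[!is.na(labeled$class8), , drop = FALSE]
  sf <- sample_features(scene$cube, labeled)
  ok <- sf$tier == "full"
  muni <- as.vector(scene$partition$municipality)
  biome <- scene$partition$biome_of[muni[labeled$pixel]]

  classifiers <- vector("list", max(scene$partition$biome_of))
  for (b in sort(unique(scene$partition$biome_of))) {
    sel <- which(ok & biome == b)
    classifiers[[b]] <- train_biome_classifier(
      sf$features[sel, , drop = FALSE], labeled$class8[sel],
      config = config, seed = seed + b, biome = b
    )
  }
  maps <- build_annual_maps(scene$cube, scene$partition, classifiers)
  accuracy <- lapply(classifiers[!vapply(classifiers, is.null, logical(1))],
                     oob_accuracy)
  list(labeled = labeled, classifiers = classifiers, maps = maps,
       accuracy = accuracy)
}

#' Run the change-trend analysis on a map stack
#'
#' Zonal areas, the more-than-1 percent No-Data year rule, per-municipality
#' regressions, and rollups to ecoregion, biome and country scales.
#'
#' @param maps An `lulc_map_stack`.
#' @param partition The matching `lulc_partition`.
#' @param alpha Significance level (default 0.05).
#' @param nodata_threshold No-Data year-exclusion fraction (default 0.01).
#' @return List with `areas`, `fits`, `country`, `by_biome`, `by_ecoregion`.
#' @export
run_trends <- function(maps, partition = maps$partition, alpha = 0.05,
                       nodata_threshold = 0.01) {
  areas <- municipality_class_areas(maps, partition)
  areas <- filter_years(areas, nodata_threshold)
  fits <- classify_municipality(fit_all_trends(areas), alpha)
  list(
    areas = areas, fits = fits,
    country = rollup(fits, 1L, scale = "country"),
    by_biome = rollup(fits, partition$biome_of, scale = "biome"),
    by_ecoregion = rollup(fits, partition$ecoregion_of, scale = "ecoregion")
  )
}
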