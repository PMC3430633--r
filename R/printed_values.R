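#' Published Colombia 2001-2010 change statistics (inputs)
#'
#' The printed national-scale numbers from the published Colombia analysis
#' that this pipeline re-implements, bundled as input data for arithmetic
#' reproduction: regression-based country areas per class in 2001 and 2010,
#' the municipality gain/loss partition, the per-biome accuracy table, the
#' top-ten gain/loss hotspot columns, and the national woody and
#' woody-plus-mixed comparison columns. All areas are km^2 and accuracies
#' percent, exactly as printed.
#'
#' @return A list with components `country` (data frame: class, area2001,
#'   area2010), `municipal` (data frame: class, n_gain, n_loss, gain_km2,
#'   loss_km2), `n_municipalities`, `accuracy` (data frame: biome, n,
#'   overall, producer/user accuracy per five-class column),
#'   `hotspot_gain`, `hotspot_loss` (data frames: net, r, p, area_km2,
#'   pct_change), `national_comparison` (data frame: year, woody,
#'   woody_plus_mixed), `size_comparison` (list: mean gainer/loser areas,
#'   printed U and p).
#' @export
colombia_printed <- function() {
  list(
    country = data.frame(
      class = c("woody", "ag_herb", "mixed_woody_plant"),
      area2001 = c(580420, 383097, 151930),
      area2010 = c(597383, 397741, 122648)
    ),
    municipal = data.frame(
      class = c("woody", "ag_herb", "mixed_woody_plant"),
      n_gain = c(820, 587, 347),
      n_loss = c(264, 526, 762),
      gain_km2 = c(28092, 28345, 5199),
      loss_km2 = c(11129, 13701, 34481)
    ),
    n_municipalities = 1117,
    accuracy = data.frame(
      biome = c("moist_amazon", "moist_coastal", "dry", "grasslands"),
      n = c(5051, 2135, 1825, 1132),
      overall = c(92.2, 89.2, 82.0, 86.1),
      prod_ag_herb = c(86.5, 90.5, 87.3, 97.4),
      prod_bare_built = c(64.7, 91.4, 90.1, 67.6),
      prod_mixed_woody_plant = c(49.7, 33.3, 32.5, 29.7),
      prod_woody = c(100.0, 99.6, 92.4, 95.8),
      prod_water = c(99.9, 100.0, 100.0, 100.0),
      user_ag_herb = c(78.7, 83.5, 78.6, 83.9),
      user_bare_built = c(86.9, 89.5, 82.6, 89.3),
      user_mixed_woody_plant = c(73.6, 71.0, 68.7, 77.0),
      user_woody = c(97.7, 92.6, 81.6, 86.0),
      user_water = c(95.8, 99.0, 100.0, 98.1)
    ),
    hotspot_gain = data.frame(
      net = c(1065, 638, 589, 394, 344, 322, 211, 178, 164, 134),
      r = c(0.79, 0.87, 0.67, 0.66, 0.63, 0.74, 0.78, 0.64, 0.83, 0.62),
      p = c(0.005, 0.0008, 0.03, 0.03, 0.04, 0.05, 0.007, 0.04, 0.002, 0.05),
      area_km2 = c(65568, 2680, 7890, 1634, 1428, 802, 1454, 1284, 1520, 773),
      pct_change = c(3, 45, 2148, 62, 56, 108, 26, 40, 447, 52)
    ),
    hotspot_loss = data.frame(
      net = -c(712, 471, 409, 384, 359, 199, 126, 121, 104, 103),
      r = -c(0.62, 0.63, 0.74, 0.87, 0.75, 0.83, 0.84, 0.74, 0.61, 0.83),
      p = c(0.05, 0.04, 0.01, 0.001, 0.01, 0.002, 0.03, 0.01, 0.05, 0.002),
      area_km2 = c(10756, 3218, 5433, 2045, 12018, 17397, 1067, 2973, 3005, 1154),
      pct_change = -c(17, 29, 17, 27, 5, 10, 24, 26, 27, 10)
    ),
    national_comparison = data.frame(
      year = c(2001, 2005, 2008, 2010),
      woody = c(580420, 587953, 593611, 597383),
      woody_plus_mixed = c(732350, 726817, 722723, 720031)
    ),
    size_comparison = list(
      mean_gainer_km2 = 688, mean_loser_km2 = 3113,
      printed_U = 3.6, printed_p = 0.0003
    )
  )
}
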