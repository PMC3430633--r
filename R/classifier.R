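#' Default classifier configuration
#'
#' The ensemble configuration used throughout: 1999 trees, a minimum
#' terminal-node size of 5, and `floor(sqrt(p))` candidate predictors per
#' split. The outlier threshold of 10 governs proximity-based training-set
#' filtering.
#'
#' @param n_trees,nodesize,outlier_threshold Override individual values.
#' @return Named list.
#' @export
classifier_config <- function(n_trees = 1999, nodesize = 5,
                              outlier_threshold = 10) {
  list(n_trees = n_trees, nodesize = nodesize,
       outlier_threshold = outlier_threshold)
}

#' Train the tiered classifier pair for one biome
#'
#' Fits an initial forest on all 120 temporal features of the biome's
#' tier-`full` training samples, removes proximity outliers (standardized
#' score > threshold), then refits on the retained samples: the final
#' initial model on all 120 features and the secondary model on the 20
#' twelve-month features of the same filtered sample set. The secondary
#' model classifies pixel-years that have only valid annual statistics.
#'
#' @param features Numeric matrix of training features (columns named as in
#'   [feature_names()]); rows must be tier-`full` (no missing values).
#' @param class8 Character/factor vector of eight-scheme labels.
#' @param config From [classifier_config()].
#' @param seed Integer seed.
#' @param biome Identifier carried in the result.
#' @return Object of class `lulc_classifier_pair`: list with `initial`,
#'   `secondary` (both `lulc_rf`), `keep` (outlier filter), `outlier_scores`,
#'   `class8` (filtered labels), `config`, `biome`, `n_samples`.
#' @export
train_biome_classifier <- function(features, class8, config = classifier_config(),
                                   seed = 1, biome = NA) {
  features <- as.matrix(features)
  class8 <- as.character(class8)
  if (length(unique(class8)) < 2) {
    stop("biome ", biome, " has a single class among its samples; ",
         "cannot train a classifier")
  }
  if (anyNA(features)) {
    stop("training features contain missing values; train on tier 'full' samples")
  }
  cls_levels <- intersect(cover_classes8(), unique(class8))
  y <- factor(class8, levels = cls_levels)

  screen <- rf_fit(features, y, n_trees = config$n_trees,
                   nodesize = config$nodesize, seed = seed, proximity = TRUE)
  scores <- rf_outlier_scores(screen$proximity, y)
  keep <- scores <= config$outlier_threshold
  yk <- factor(as.character(y[keep]),
               levels = intersect(cover_classes8(), unique(as.character(y[keep]))))
  xk <- features[keep, , drop = FALSE]

  initial <- rf_fit(xk, yk, n_trees = config$n_trees,
                    nodesize = config$nodesize, seed = seed + 1,
                    proximity = FALSE)
  ann <- feature_names(annual_only = TRUE)
  secondary <- rf_fit(xk[, ann, drop = FALSE], yk, n_trees = config$n_trees,
                      nodesize = config$nodesize, seed = seed + 2,
                      proximity = FALSE)

  structure(
    list(initial = initial, secondary = secondary, keep = keep,
         outlier_scores = scores, class8 = as.character(yk),
         config = config, biome = biome, n_samples = sum(keep)),
    class = "lulc_classifier_pair"
  )
}

#' @export
print.lulc_classifier_pair <- function(x, ...) {
  cat("<lulc_classifier_pair> biome ", x$biome, ": ", x$n_samples,
      " training samples (", sum(!x$keep), " outliers removed), ",
      x$config$n_trees, " trees\n", sep = "")
  invisible(x)
}

#' Classify pixel-years through the tiered fallback
#'
#' Routes each feature vector by its tier: `full` -> initial model (all 120
#' features), `annual_only` -> secondary model (20 twelve-month features),
#' `none` -> No Data.
#'
#' @param features Matrix (rows = pixel-years) or single named vector.
#' @param tier Character vector of tiers aligned with rows.
#' @param classifier_pair An `lulc_classifier_pair`.
#' @return Character vector of eight-scheme labels, `NA` for No Data. The
#'   attribute `routed` counts rows per tier.
#' @export
classify_pixel_year <- function(features, tier, classifier_pair) {
  if (is.null(dim(features))) features <- matrix(features, 1,
                                                 dimnames = list(NULL, names(features)))
  out <- rep(NA_character_, nrow(features))
  full <- which(tier == "full")
  ann <- which(tier == "annual_only")
  if (length(full) > 0) {
    out[full] <- as.character(predict(classifier_pair$initial,
                                      features[full, , drop = FALSE]))
  }
  if (length(ann) > 0) {
    acols <- feature_names(annual_only = TRUE)
    out[ann] <- as.character(predict(classifier_pair$secondary,
                                     features[ann, acols, drop = FALSE]))
  }
  attr(out, "routed") <- c(full = length(full), annual_only = length(ann),
                           none = sum(tier == "none"))
  out
}

#' Build the annual five-class map stack
#'
#' Classifies every pixel-year with its biome's classifier pair (tiered
#' fallback), groups the eight-scheme predictions to the five-class scheme,
#' applies the multi-year exclusion rule - pixels with >= `max_nodata_years`
#' No-Data years over the series are set to No Data in all years - and
#' records each municipality's annual No-Data area fraction.
#'
#' @param cube An `lulc_cube`.
#' @param partition The matching `lulc_partition`.
#' @param classifiers List of `lulc_classifier_pair`, indexed by biome id.
#' @param max_nodata_years Exclusion threshold (default 4).
#' @return Object of class `lulc_map_stack`: list with `labels5` (integer
#'   matrix pixels x years, codes 0-5 with 0 = No Data), `nodata_frac`
#'   (municipalities x years), `years`, `partition`.
#' @export
build_annual_maps <- function(cube, partition, classifiers,
                              max_nodata_years = 4) {
  stopifnot(inherits(cube, "lulc_cube"), inherits(partition, "lulc_partition"))
  if (cube$n_pixels != partition$rows * partition$cols) {
    stop("cube and partition grids differ")
  }
  muni <- as.vector(partition$municipality)
  biome <- partition$biome_of[muni]
  need <- sort(unique(biome))
  have <- which(!vapply(classifiers, is.null, logical(1)))
  if (!all(need %in% have)) {
    stop("no trained classifier for biome(s): ",
         paste(setdiff(need, have), collapse = ", "))
  }

  n_years <- length(cube$years)
  labels5 <- matrix(0L, cube$n_pixels, n_years)
  for (y in seq_len(n_years)) {
    fm <- feature_matrix(cube, cube$years[y])
    for (b in need) {
      rows <- which(biome == b)
      cls8 <- classify_pixel_year(fm$features[rows, , drop = FALSE],
                                  fm$tier[rows], classifiers[[b]])
      lab <- rep(0L, length(rows))
      ok <- !is.na(cls8)
      lab[ok] <- class5_code(group_to_five(cls8[ok]))
      labels5[rows, y] <- lab
    }
  }

  # multi-year exclusion: chronically unreliable pixels dropped everywhere
  bad <- rowSums(labels5 == 0L) >= max_nodata_years
  labels5[bad, ] <- 0L

  n_m <- length(partition$pixel_counts)
  nodata_frac <- matrix(0, n_m, n_years,
                        dimnames = list(NULL, cube$years))
  for (y in seq_len(n_years)) {
    nd <- tapply(labels5[, y] == 0L, muni, sum)
    nodata_frac[as.integer(names(nd)), y] <-
      unname(nd) / partition$pixel_counts[as.integer(names(nd))]
  }

  structure(
    list(labels5 = labels5, nodata_frac = nodata_frac,
         years = cube$years, partition = partition),
    class = "lulc_map_stack"
  )
}

#' @export
print.lulc_map_stack <- function(x, ...) {
  cat("<lulc_map_stack> ", nrow(x$labels5), " pixels x ", length(x$years),
      " years; ", format(100 * mean(x$labels5 == 0L), digits = 3),
      "% No Data\n", sep = "")
  invisible(x)
}
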