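# Composite -> calendar-month mapping and the six statistics windows.
#
# Composite k (1..23) nominally starts on day-of-year 1 + 16*(k-1); it is
# assigned to the month containing that day (non-leap calendar). Windows are
# month sets: the full year, two six-month halves, three four-month thirds.
composite_months <- function() {
  doy <- 1 + 16 * (0:22)
  findInterval(doy, cumsum(c(0, 31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30)) + 1)
}

feature_windows <- function() {
  m <- composite_months()
  list(
    M12 = which(m >= 1),
    H1 = which(m <= 6), H2 = which(m >= 7),
    T1 = which(m <= 4), T2 = which(m >= 5 & m <= 8), T3 = which(m >= 9)
  )
}

feature_bands <- function() c("EVI", "red", "NIR", "MIR")
feature_stats <- function() c("mean", "sd", "min", "max", "range")

#' Names of the 120 temporal-statistics features
#'
#' `<band>_<window>_<stat>` for four bands (EVI, red, NIR, MIR), six windows
#' (M12 = 12-month; H1, H2 = six-month halves; T1, T2, T3 = four-month
#' thirds) and five statistics (mean, sd, min, max, range). The 20 `M12`
#' features are the predictor set of the secondary (annual-only) model.
#'
#' @param annual_only If `TRUE`, only the 20 twelve-month feature names.
#' @return Character vector of feature names.
#' @export
feature_names <- function(annual_only = FALSE) {
  wins <- if (annual_only) "M12" else names(feature_windows())
  unlist(lapply(feature_bands(), function(b) {
    lapply(wins, function(w) paste(b, w, feature_stats(), sep = "_"))
  }))
}

#' Five statistics of a reliability-filtered composite window
#'
#' Removes unreliable composites (reliability flag 3) and computes mean,
#' sample standard deviation (n-1 denominator), minimum, maximum and range
#' over the remainder. If fewer than three reliable composites remain the
#' window is invalid and all five statistics are `NA`.
#'
#' @param values Numeric vector, one entry per composite in the window.
#' @param reliability_flags Integer vector aligned with `values`; value 3
#'   marks an unreliable composite.
#' @return Named numeric vector `c(mean, sd, min, max, range)`, all `NA`
#'   when invalid.
#' @examples
#' window_statistics(c(0.2, 0.4, 0.6), c(0, 0, 0))
#' @export
window_statistics <- function(values, reliability_flags) {
  if (length(values) != length(reliability_flags)) {
    stop("values and reliability flags differ in length")
  }
  v <- values[reliability_flags != 3]
  if (length(v) < 3) {
    return(stats::setNames(rep(NA_real_, 5), feature_stats()))
  }
  c(mean = mean(v), sd = sd(v), min = min(v), max = max(v),
    range = max(v) - min(v))
}

#' Feature vector of one pixel-year
#'
#' Computes the 120 temporal statistics (5 statistics x 4 bands x 6
#' windows) from a year of 23 composites, with per-window validity (a
#' window is valid iff it holds >= 3 reliable composites) and the feature
#' tier that routes the pixel-year to a classifier: `"full"` when all six
#' windows are valid (initial model), `"annual_only"` when the 12-month
#' window is valid but some sub-annual window is not (secondary model),
#' `"none"` when the 12-month window itself is invalid (No Data).
#'
#' @param values 23 x 4 numeric matrix with columns EVI, red, NIR, MIR (a
#'   list of four length-23 vectors is also accepted).
#' @param reliability_flags Integer vector of 23 flags (3 = unreliable).
#' @return List with `features` (named length-120 vector, `NA` in invalid
#'   windows), `window_valid` (named logical, 6 windows), `tier`.
#' @export
build_feature_vector <- function(values, reliability_flags) {
  if (is.list(values)) values <- do.call(cbind, values[feature_bands()])
  values <- as.matrix(values)
  if (nrow(values) != 23 || ncol(values) != 4) {
    stop("expected 23 composites x 4 bands, got ",
         nrow(values), " x ", ncol(values))
  }
  if (length(reliability_flags) != 23) stop("expected 23 reliability flags")
  colnames(values) <- feature_bands()
  wins <- feature_windows()

  feats <- numeric(0)
  valid <- logical(length(wins))
  names(valid) <- names(wins)
  for (b in feature_bands()) {
    for (w in names(wins)) {
      s <- window_statistics(values[wins[[w]], b], reliability_flags[wins[[w]]])
      names(s) <- paste(b, w, names(s), sep = "_")
      feats <- c(feats, s)
    }
  }
  for (w in names(wins)) {
    valid[w] <- sum(reliability_flags[wins[[w]]] != 3) >= 3
  }
  tier <- if (!valid["M12"]) "none" else if (all(valid)) "full" else "annual_only"
  list(features = feats[feature_names()], window_valid = valid, tier = tier)
}

#' Feature matrix for all pixels of one cube year
#'
#' Vectorized equivalent of [build_feature_vector()] across every pixel of
#' an `lulc_cube` for one year: returns the pixels x 120 feature matrix and
#' the per-pixel tier. Agreement with the per-pixel path is exercised in
#' the test suite.
#'
#' @param cube An `lulc_cube`.
#' @param year Calendar year present in `cube$years`.
#' @return List with `features` (matrix, pixels x 120, named columns) and
#'   `tier` (character vector).
#' @export
feature_matrix <- function(cube, year) {
  yi <- match(year, cube$years)
  if (is.na(yi)) stop("year ", year, " not in cube")
  cols <- ((yi - 1) * 23 + 1):(yi * 23)
  rel <- cube$reliability[, cols, drop = FALSE]
  ok <- rel != 3
  wins <- feature_windows()
  n <- nrow(rel)

  out <- matrix(NA_real_, n, 120, dimnames = list(NULL, feature_names()))
  nvalid <- matrix(0L, n, length(wins), dimnames = list(NULL, names(wins)))
  for (w in names(wins)) {
    nvalid[, w] <- rowSums(ok[, wins[[w]], drop = FALSE])
  }

  for (b in feature_bands()) {
    V <- cube$bands[[b]][, cols, drop = FALSE]
    for (w in names(wins)) {
      idx <- wins[[w]]
      Vw <- V[, idx, drop = FALSE]
      Mw <- ok[, idx, drop = FALSE]
      nw <- nvalid[, w]
      good <- nw >= 3
      sums <- rowSums(Vw * Mw)
      mu <- ifelse(good, sums / nw, NA_real_)
      ss <- rowSums(Vw * Vw * Mw)
      var_ <- ifelse(good, pmax(ss - nw * mu^2, 0) / (nw - 1), NA_real_)
      Vinf <- Vw
      Vinf[!Mw] <- Inf
      mn <- do.call(pmin, as.data.frame(Vinf))
      Vninf <- Vw
      Vninf[!Mw] <- -Inf
      mx <- do.call(pmax, as.data.frame(Vninf))
      mn[!good] <- NA_real_
      mx[!good] <- NA_real_
      pre <- paste(b, w, sep = "_")
      out[, paste0(pre, "_mean")] <- mu
      out[, paste0(pre, "_sd")] <- sqrt(var_)
      out[, paste0(pre, "_min")] <- mn
      out[, paste0(pre, "_max")] <- mx
      out[, paste0(pre, "_range")] <- mx - mn
    }
  }
  annual_ok <- nvalid[, "M12"] >= 3
  all_ok <- rowSums(nvalid >= 3) == length(wins)
  tier <- ifelse(!annual_ok, "none", ifelse(all_ok, "full", "annual_only"))
  list(features = out, tier = tier)
}

#' Extract features for labeled reference samples
#'
#' Looks up each labeled sample's pixel and image year in the cube and
#' returns its feature vector and tier, ready for classifier training.
#'
#' @param cube An `lulc_cube`.
#' @param labeled Data frame from [label_samples()] with `pixel` and `year`.
#' @return List with `features` (matrix), `tier`, `labeled` (the input).
#' @export
sample_features <- function(cube, labeled) {
  feats <- matrix(NA_real_, nrow(labeled), 120,
                  dimnames = list(NULL, feature_names()))
  tier <- character(nrow(labeled))
  for (y in unique(labeled$year)) {
    fm <- feature_matrix(cube, y)
    sel <- which(labeled$year == y)
    feats[sel, ] <- fm$features[labeled$pixel[sel], , drop = FALSE]
    tier[sel] <- fm$tier[labeled$pixel[sel]]
  }
  list(features = feats, tier = tier, labeled = labeled)
}
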