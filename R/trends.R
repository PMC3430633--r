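#' Per-municipality annual class areas from a map stack
#'
#' Zonal statistics of the five-class annual maps: pixel counts per
#' municipality, class and year converted to km^2 with the squared cell
#' size, plus each municipality's total area and annual No-Data fraction.
#'
#' @param map_stack An `lulc_map_stack`.
#' @param partition The matching `lulc_partition` (defaults to the stack's).
#' @param cell_size Cell edge in meters (defaults to the partition's).
#' @return Object of class `lulc_area_table`: data frame with columns
#'   `municipality`, `class`, `year`, `area_km2`, `nodata_frac`, plus
#'   attributes `total_area_km2` (per municipality) and `years`.
#' @export
municipality_class_areas <- function(map_stack, partition = map_stack$partition,
                                     cell_size = partition$cell_size) {
  if (nrow(map_stack$labels5) != partition$rows * partition$cols) {
    stop("map stack and partition grids differ")
  }
  muni <- as.vector(partition$municipality)
  n_m <- length(partition$pixel_counts)
  px_area <- cell_area_km2(cell_size)
  cls <- cover_classes5()

  out <- vector("list", length(map_stack$years))
  for (y in seq_along(map_stack$years)) {
    counts <- table(factor(muni, levels = seq_len(n_m)),
                    factor(map_stack$labels5[, y], levels = seq_along(cls)))
    out[[y]] <- data.frame(
      municipality = rep(seq_len(n_m), times = length(cls)),
      class = rep(cls, each = n_m),
      year = map_stack$years[y],
      area_km2 = as.vector(counts) * px_area,
      nodata_frac = rep(map_stack$nodata_frac[, y], times = length(cls))
    )
  }
  res <- do.call(rbind, out)
  attr(res, "total_area_km2") <- partition$pixel_counts * px_area
  attr(res, "years") <- map_stack$years
  class(res) <- c("lulc_area_table", "data.frame")
  res
}

#' Drop years with excessive No Data from a municipality's record
#'
#' Removes municipality-years whose No-Data fraction exceeds the threshold
#' (strictly greater than; exactly at the threshold is retained) from all
#' classes of that municipality. Municipalities left with fewer than three
#' usable years are flagged: their trends are unestimable.
#'
#' @param area_table An `lulc_area_table`.
#' @param nodata_threshold Fraction of municipality area (default 0.01,
#'   i.e. the more-than-1 percent rule).
#' @return Filtered `lulc_area_table`; attribute `unestimable` lists
#'   municipality ids with < 3 remaining years.
#' @export
filter_years <- function(area_table, nodata_threshold = 0.01) {
  drop <- area_table$nodata_frac > nodata_threshold
  res <- area_table[!drop, , drop = FALSE]
  yrs <- tapply(res$year, res$municipality, function(y) length(unique(y)))
  unest <- as.integer(names(yrs)[yrs < 3])
  all_m <- unique(area_table$municipality)
  unest <- union(unest, setdiff(all_m, unique(res$municipality)))
  attr(res, "total_area_km2") <- attr(area_table, "total_area_km2")
  attr(res, "years") <- attr(area_table, "years")
  attr(res, "unestimable") <- sort(unest)
  class(res) <- class(area_table)
  res
}

#' Linear trend of class area against time
#'
#' Ordinary least squares of area on year index, Pearson correlation R, a
#' two-sided p-value from the exact t-transform of R with n-2 degrees of
#' freedom, fitted areas at the series endpoints (evaluated at the first
#' and last calendar years regardless of dropped interior years), and the
#' regression-based net change (fitted last minus fitted first). A
#' zero-variance area series takes the no-change convention: slope 0,
#' R = 0, p = 1.
#'
#' @param areas Annual class areas (km^2).
#' @param years Calendar years, same length (>= 3).
#' @param endpoint_years Length-2 vector of evaluation years (defaults to
#'   2001 and 2010).
#' @return List with `slope`, `intercept`, `r`, `p`, `n`, `fitted_first`,
#'   `fitted_last`, `net`, `significant`.
#' @export
fit_trend <- function(areas, years, endpoint_years = c(2001, 2010)) {
  if (length(areas) != length(years)) stop("areas and years differ in length")
  n <- length(areas)
  if (n < 3) stop("need at least 3 year-points to fit a trend")
  t_idx <- years - endpoint_years[1] + 1  # year index, 1 at first endpoint
  span <- endpoint_years[2] - endpoint_years[1]

  if (sd(areas) == 0) {
    a <- areas[1]
    return(list(slope = 0, intercept = a, r = 0, p = 1, n = n,
                fitted_first = a, fitted_last = a, net = 0,
                significant = FALSE))
  }
  mx <- mean(t_idx); my <- mean(areas)
  sxx <- sum((t_idx - mx)^2)
  sxy <- sum((t_idx - mx) * (areas - my))
  b <- sxy / sxx
  a <- my - b * mx
  r <- cor(t_idx, areas)
  tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tt), df = n - 2)
  f1 <- a + b * 1
  f2 <- a + b * (span + 1)
  list(slope = b, intercept = a, r = r, p = p, n = n,
       fitted_first = f1, fitted_last = f2, net = f2 - f1,
       significant = p <= 0.05)
}

#' Fit trends for every municipality and class
#'
#' Applies [fit_trend()] per municipality x class over the filtered area
#' table. Municipalities flagged unestimable (fewer than three usable
#' years) are returned with `NA` fits.
#'
#' @param area_table An `lulc_area_table`, normally after [filter_years()].
#' @param classes Classes to fit (default the three vegetation classes:
#'   woody, mixed woody/plant, ag/herb).
#' @param endpoint_years Passed to [fit_trend()].
#' @return Data frame of class `lulc_trend_fits`: `municipality`, `class`,
#'   `slope`, `intercept`, `r`, `p`, `n`, `fitted2001`, `fitted2010`,
#'   `net`, `significant`, `estimable`.
#' @export
fit_all_trends <- function(area_table,
                           classes = c("woody", "mixed_woody_plant", "ag_herb"),
                           endpoint_years = NULL) {
  yrs <- attr(area_table, "years")
  if (is.null(endpoint_years)) {
    endpoint_years <- if (is.null(yrs)) c(2001, 2010) else range(yrs)
  }
  unest <- attr(area_table, "unestimable")
  munis <- sort(unique(c(area_table$municipality, unest)))
  grid <- expand.grid(municipality = munis, class = classes,
                      stringsAsFactors = FALSE)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    m <- grid$municipality[i]; cl <- grid$class[i]
    sub <- area_table[area_table$municipality == m & area_table$class == cl, ]
    if (m %in% unest || nrow(sub) < 3) {
      rows[[i]] <- data.frame(
        municipality = m, class = cl, slope = NA_real_, intercept = NA_real_,
        r = NA_real_, p = NA_real_, n = nrow(sub), fitted2001 = NA_real_,
        fitted2010 = NA_real_, net = NA_real_, significant = NA,
        estimable = FALSE
      )
    } else {
      f <- fit_trend(sub$area_km2, sub$year, endpoint_years)
      rows[[i]] <- data.frame(
        municipality = m, class = cl, slope = f$slope, intercept = f$intercept,
        r = f$r, p = f$p, n = f$n, fitted2001 = f$fitted_first,
        fitted2010 = f$fitted_last, net = f$net, significant = f$significant,
        estimable = TRUE
      )
    }
  }
  res <- do.call(rbind, rows)
  class(res) <- c("lulc_trend_fits", "data.frame")
  res
}

#' Gain/loss/no-change label for municipality trends
#'
#' Direction is the sign of the regression-based net change; the
#' significant variant additionally requires `p <= alpha` (inclusive).
#'
#' @param trend_fits An `lulc_trend_fits` data frame (or any frame with
#'   `net`, `p`, `estimable`).
#' @param alpha Significance level (default 0.05).
#' @return The input with `direction` (`"gain"`, `"loss"`, `"none"`,
#'   `"unestimable"`) and `significant` recomputed at `alpha`.
#' @export
classify_municipality <- function(trend_fits, alpha = 0.05) {
  dir <- ifelse(!trend_fits$estimable, "unestimable",
                ifelse(trend_fits$net > 0, "gain",
                       ifelse(trend_fits$net < 0, "loss", "none")))
  trend_fits$direction <- dir
  trend_fits$significant <- ifelse(trend_fits$estimable,
                                   trend_fits$p <= alpha, NA)
  trend_fits
}
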