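#' Build a per-municipality cover trend specification
#'
#' A trend specification states, for every municipality, the initial
#' proportion of each eight-scheme cover class and a prescribed linear
#' trend (km^2 per year) for that class. [generate_trajectories()] realizes
#' it as annual pixel-label maps whose zonal class areas track the
#' prescribed lines to within one pixel.
#'
#' @param partition An `lulc_partition`.
#' @param init_props Either a named numeric vector of initial class
#'   proportions (recycled to every municipality) or a matrix with one row
#'   per municipality and columns named by classes. Proportions must be
#'   nonnegative and sum to 1 per municipality.
#' @param slopes_km2_yr Same shape as `init_props`: prescribed trend of
#'   each class area in km^2/yr. Defaults to all zero.
#' @return A data frame of class `lulc_trend_spec` with columns
#'   `municipality`, `class8`, `init_prop`, `slope_km2_yr`.
#' @export
make_trend_spec <- function(partition, init_props, slopes_km2_yr = NULL) {
  n_m <- length(partition$pixel_counts)
  cls <- cover_classes8()
  as_mat <- function(x, what) {
    if (is.null(dim(x))) {
      if (is.null(names(x)) || !all(names(x) %in% cls)) {
        stop(what, " must be named by cover classes")
      }
      full <- stats::setNames(numeric(length(cls)), cls)
      full[names(x)] <- x
      matrix(full, n_m, length(cls), byrow = TRUE, dimnames = list(NULL, cls))
    } else {
      m <- matrix(0, n_m, length(cls), dimnames = list(NULL, cls))
      m[, colnames(x)] <- x
      m
    }
  }
  P <- as_mat(init_props, "init_props")
  if (any(P < 0)) stop("initial proportions must be nonnegative")
  if (any(abs(rowSums(P) - 1) > 1e-8)) {
    stop("initial class proportions must sum to 1 in every municipality")
  }
  S <- if (is.null(slopes_km2_yr)) {
    matrix(0, n_m, length(cls), dimnames = list(NULL, cls))
  } else {
    as_mat(slopes_km2_yr, "slopes_km2_yr")
  }
  out <- data.frame(
    municipality = rep(seq_len(n_m), each = length(cls)),
    class8 = rep(cls, times = n_m),
    init_prop = as.vector(t(P)),
    slope_km2_yr = as.vector(t(S))
  )
  class(out) <- c("lulc_trend_spec", "data.frame")
  out
}

#' Realize true cover trajectories on a landscape
#'
#' For each municipality the prescribed class-area lines are converted to
#' per-year pixel-count targets (largest-remainder rounding so counts sum
#' exactly to the municipality's pixel count), and pixel labels are flipped
#' year-to-year at municipality-random locations so the realized areas track
#' the targets. Trends that would drive a class area negative are clipped
#' at zero (with a warning); the discrepancy is absorbed by the largest
#' remaining class.
#'
#' @param partition An `lulc_partition`.
#' @param trend_spec From [make_trend_spec()].
#' @param years Number of annual maps (default 10).
#' @param start_year First calendar year (default 2001).
#' @param seed Integer seed; output is deterministic given the seed.
#' @return An object of class `lulc_cover_series`: list with `labels`
#'   (integer matrix, pixels x years, codes into [cover_classes8()]),
#'   `years` (calendar years), `partition`, and `trend_spec`.
#' @export
generate_trajectories <- function(partition, trend_spec, years = 10,
                                  start_year = 2001, seed = 1) {
  stopifnot(inherits(partition, "lulc_partition"))
  n_m <- length(partition$pixel_counts)
  cls <- cover_classes8()
  K <- length(cls)
  set.seed(seed)

  muni <- as.vector(partition$municipality)
  n_pix <- length(muni)
  labels <- matrix(NA_integer_, n_pix, years)
  px_area <- cell_area_km2(partition$cell_size)
  clipped <- FALSE

  for (m in seq_len(n_m)) {
    pix <- which(muni == m)
    N <- length(pix)
    if (N == 0L) next
    sp <- trend_spec[trend_spec$municipality == m, ]
    p0 <- sp$init_prop[match(cls, sp$class8)]
    slope_px <- sp$slope_km2_yr[match(cls, sp$class8)] / px_area

    # integer class targets per year (largest-remainder, ties -> low class)
    targets <- matrix(0L, years, K)
    for (y in seq_len(years)) {
      tgt <- N * p0 + slope_px * (y - 1)
      if (any(tgt < -1e-9)) clipped <- TRUE
      tgt <- pmax(tgt, 0)
      excess <- sum(tgt) - N
      if (abs(excess) > 1e-9) tgt[which.max(tgt)] <- tgt[which.max(tgt)] - excess
      fl <- floor(tgt + 1e-9)
      rem <- N - sum(fl)
      if (rem > 0) {
        frac <- tgt - fl
        add <- order(-frac, seq_len(K))[seq_len(rem)]
        fl[add] <- fl[add] + 1
      }
      targets[y, ] <- as.integer(fl)
    }

    # year 1: random spatial arrangement of the initial composition
    lab <- rep.int(seq_len(K), targets[1, ])
    lab <- lab[sample.int(N)]
    labels[pix, 1] <- lab

    for (y in 2:max(2, years)) {
      if (years < 2) break
      delta <- targets[y, ] - targets[y - 1, ]
      pool <- integer(0)
      for (k in which(delta < 0)) {
        holders <- which(lab == k)
        give <- holders[sample.int(length(holders), -delta[k])]
        pool <- c(pool, give)
      }
      if (length(pool) > 1) pool <- pool[sample.int(length(pool))]
      off <- 0L
      for (k in which(delta > 0)) {
        take <- pool[(off + 1):(off + delta[k])]
        lab[take] <- k
        off <- off + delta[k]
      }
      labels[pix, y] <- lab
    }
  }
  if (clipped) {
    warning("some prescribed trends would drive a class area negative; ",
            "targets were clipped at zero")
  }

  structure(
    list(
      labels = labels, years = start_year + seq_len(years) - 1L,
      partition = partition, trend_spec = trend_spec
    ),
    class = "lulc_cover_series"
  )
}

#' Realized class areas of a true-cover series
#'
#' Zonal class areas (km^2) of the ground-truth labels, per municipality,
#' class and year. Useful as the perfect-classifier oracle in tests.
#'
#' @param cover An `lulc_cover_series`.
#' @param scheme `"class8"` or `"class5"` (grouped).
#' @return Data frame with `municipality`, `class`, `year`, `area_km2`.
#' @export
true_class_areas <- function(cover, scheme = c("class8", "class5")) {
  scheme <- match.arg(scheme)
  part <- cover$partition
  muni <- as.vector(part$municipality)
  px_area <- cell_area_km2(part$cell_size)
  cls <- if (scheme == "class8") cover_classes8() else cover_classes5()
  n_m <- length(part$pixel_counts)

  out <- vector("list", length(cover$years))
  for (y in seq_along(cover$years)) {
    lab <- cover$labels[, y]
    if (scheme == "class5") {
      lab <- class5_code(group_to_five(cover_classes8()[lab]))
    }
    counts <- table(factor(muni, levels = seq_len(n_m)),
                    factor(lab, levels = seq_along(cls)))
    out[[y]] <- data.frame(
      municipality = rep(seq_len(n_m), times = length(cls)),
      class = rep(cls, each = n_m),
      year = cover$years[y],
      area_km2 = as.vector(counts) * px_area
    )
  }
  do.call(rbind, out)
}

#' @export
print.lulc_cover_series <- function(x, ...) {
  cat("<lulc_cover_series> ", nrow(x$labels), " pixels x ",
      length(x$years), " years (", min(x$years), "-", max(x$years), ")\n",
      sep = "")
  invisible(x)
}
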