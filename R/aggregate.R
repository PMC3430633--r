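#' Assign a municipality to the unit of greatest overlap
#'
#' Municipalities straddling several biomes or ecoregions belong to the
#' unit with the greatest overlap area; ties go to the lowest unit id.
#'
#' @param municipality_overlap_areas Named (or indexed) nonnegative numeric
#'   vector of overlap areas, at least one positive.
#' @return The winning unit id (name if named, index otherwise).
#' @examples
#' assign_unit(c(A = 60, B = 40))  # "A"
#' @export
assign_unit <- function(municipality_overlap_areas) {
  a <- municipality_overlap_areas
  if (any(a < 0)) stop("overlap areas must be nonnegative")
  if (all(a == 0)) stop("municipality has zero overlap with every unit")
  i <- which.max(a)  # which.max takes the first (lowest id) on ties
  if (!is.null(names(a))) names(a)[i] else i
}

#' Roll municipality trends up to a coarser scale
#'
#' Sums regression-fitted first-year areas, last-year areas and net changes
#' of ALL estimable municipalities (not only significant ones) within each
#' unit of the requested scale, and counts gaining/losing municipalities.
#' The invariant `net = area_last - area_first = gain - loss` holds exactly
#' per unit and class.
#'
#' @param trend_fits An `lulc_trend_fits` data frame.
#' @param unit_assignment Integer/character vector mapping municipality id
#'   to unit id (e.g. `partition$biome_of`), or a single unit id for the
#'   country scale.
#' @param scale Label stored in the output (e.g. `"biome"`).
#' @return Data frame with `scale`, `unit`, `class`, `area_first`,
#'   `area_last`, `net`, `n_gain`, `n_loss`, `gain_total`, `loss_total`.
#' @export
rollup <- function(trend_fits, unit_assignment, scale = "unit") {
  tf <- trend_fits[trend_fits$estimable, , drop = FALSE]
  if (length(unit_assignment) == 1) {
    unit <- rep(unit_assignment, nrow(tf))
  } else {
    if (any(is.na(unit_assignment[tf$municipality]))) {
      stop("some municipalities lack a unit assignment at scale ", scale)
    }
    unit <- unit_assignment[tf$municipality]
  }
  d <- data.frame(
    unit = unit, class = tf$class,
    area_first = tf$fitted2001, area_last = tf$fitted2010, net = tf$net,
    n_gain = as.numeric(tf$net > 0), n_loss = as.numeric(tf$net < 0),
    gain_total = pmax(tf$net, 0), loss_total = pmax(-tf$net, 0)
  )
  res <- stats::aggregate(d[, -(1:2)], by = d[, 1:2, drop = FALSE], FUN = sum)
  cbind(scale = scale, res)
}

#' Gain/loss partition of municipalities for one class
#'
#' Counts municipalities gaining (net > 0) and losing (net < 0) the class,
#' sums their absolute net changes, and reports integer-rounded
#' percentages of the total municipality count. The national net equals
#' total gain minus total loss exactly.
#'
#' @param trend_fits An `lulc_trend_fits` data frame.
#' @param class Class to partition on (default `"woody"`).
#' @param significant_only Restrict to `p <= alpha` municipalities.
#' @param alpha Significance level for the restriction (default 0.05).
#' @return List with `n_total`, `n_gain`, `n_loss`, `n_none`, `pct_gain`,
#'   `pct_loss`, `gain_total`, `loss_total` (both positive km^2), `net`.
#' @export
gain_loss_partition <- function(trend_fits, class = "woody",
                                significant_only = FALSE, alpha = 0.05) {
  tf <- trend_fits[trend_fits$class == class & trend_fits$estimable, ]
  n_total <- length(unique(trend_fits$municipality))
  if (significant_only) tf <- tf[tf$p <= alpha, ]
  gain <- tf$net > 0
  loss <- tf$net < 0
  list(
    n_total = n_total,
    n_gain = sum(gain), n_loss = sum(loss),
    n_none = n_total - sum(gain) - sum(loss),
    pct_gain = round_half_up(100 * sum(gain) / n_total),
    pct_loss = round_half_up(100 * sum(loss) / n_total),
    gain_total = sum(tf$net[gain]),
    loss_total = sum(-tf$net[loss]),  # avoids sprintf's "-0.0" on empty sets
    net = sum(tf$net)
  )
}

#' Share of a national total captured by top-ranked net changes
#'
#' @param top_nets Net changes (km^2) of the selected municipalities.
#' @param national_total Total |net| in the same direction (km^2).
#' @return Integer-rounded percentage.
#' @export
hotspot_share <- function(top_nets, national_total) {
  round_half_up(100 * sum(abs(top_nets)) / national_total)
}

#' Hotspot table: top-k municipalities by absolute net change
#'
#' Ranks municipalities with net change in the requested direction by
#' |net change| (ties by municipality id) and reports the top k together
#' with their share of the national total in that direction,
#' integer-rounded. Optionally restricted to significant trends.
#'
#' @param trend_fits An `lulc_trend_fits` data frame.
#' @param k Number of municipalities (default 10).
#' @param direction `"gain"` or `"loss"`.
#' @param class Class of interest (default `"woody"`).
#' @param significant_only Restrict ranking AND the national denominator to
#'   significant municipalities.
#' @param alpha Significance level (default 0.05).
#' @return Object of class `lulc_hotspots`: data frame of the top rows
#'   (`municipality`, `net`, `r`, `p`, `pct_change`) with attributes
#'   `share` (percent of national total) and `direction`.
#' @export
hotspots <- function(trend_fits, k = 10, direction = c("gain", "loss"),
                     class = "woody", significant_only = FALSE, alpha = 0.05) {
  direction <- match.arg(direction)
  stopifnot(k >= 1)
  tf <- trend_fits[trend_fits$class == class & trend_fits$estimable, ]
  if (significant_only) tf <- tf[tf$p <= alpha, ]
  tf <- if (direction == "gain") tf[tf$net > 0, ] else tf[tf$net < 0, ]
  total <- sum(abs(tf$net))
  ord <- order(-abs(tf$net), tf$municipality)
  if (k > nrow(tf)) {
    message("only ", nrow(tf), " municipalities available for top-", k,
            " ", direction, " table; truncating")
    k <- nrow(tf)
  }
  top <- tf[ord[seq_len(k)], ]
  pc <- vapply(seq_len(nrow(top)), function(i) {
    percent_change(top$net[i], top$fitted2001[i])
  }, numeric(1))
  out <- data.frame(
    municipality = top$municipality, net = top$net, r = top$r, p = top$p,
    pct_change = pc, row.names = NULL
  )
  attr(out, "share") <- hotspot_share(top$net, total)
  attr(out, "direction") <- direction
  class(out) <- c("lulc_hotspots", "data.frame")
  out
}

#' Percent change relative to the fitted first-year baseline
#'
#' @param net Net change (km^2).
#' @param baseline Fitted first-year area (km^2); must be positive for a
#'   defined result.
#' @return Percentage, or `NA` (with a `"undefined"` attribute) when the
#'   baseline is zero or negative.
#' @export
percent_change <- function(net, baseline) {
  if (is.na(baseline) || baseline <= 0) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  100 * net / baseline
}

#' Rank-sum comparison of gaining vs losing municipality sizes
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test of the municipality
#' areas of significant gainers against significant losers: exact p by
#' complete enumeration for combined n <= 12 (midranks under ties), and
#' the normal approximation with tie correction otherwise. Reports both
#' the U statistic (for the first group) and the normal deviate z.
#'
#' @param gainers_areas,losers_areas Positive municipality areas (km^2),
#'   both nonempty.
#' @return Object of class `lulc_size_comparison`: list with `n`, `means`,
#'   `U` (first group), `z`, `p`, `method`.
#' @export
compare_sizes <- function(gainers_areas, losers_areas) {
  x <- gainers_areas; y <- losers_areas
  if (length(x) == 0 || length(y) == 0) stop("both groups must be nonempty")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  rk <- rank(c(x, y))
  R1 <- sum(rk[seq_len(n1)])
  U1 <- R1 - n1 * (n1 + 1) / 2
  U <- U1

  if (N <= 12) {
    method <- "exact enumeration"
    combs <- combn(N, n1)
    stats <- apply(combs, 2, function(ix) sum(rk[ix])) - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    p <- mean(abs(stats - mu) >= abs(U1 - mu) - 1e-12)
    z <- (U1 - mu) / max(sd(stats), .Machine$double.eps)
  } else {
    method <- "normal approximation with tie correction"
    mu <- n1 * n2 / 2
    ties <- table(rk)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    z <- (U1 - mu) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
    p <- min(p, 1)
  }
  structure(
    list(n = c(gainers = n1, losers = n2),
         means = c(gainers = mean(x), losers = mean(y)),
         U = U, z = z, p = p, method = method),
    class = "lulc_size_comparison"
  )
}

#' @export
print.lulc_size_comparison <- function(x, ...) {
  cat("<lulc_size_comparison> mean areas ",
      format(x$means[1], digits = 4), " vs ", format(x$means[2], digits = 4),
      " km^2; U=", format(x$U, digits = 4), ", z=", format(x$z, digits = 3),
      ", p=", format(x$p, digits = 3), " (", x$method, ")\n", sep = "")
  invisible(x)
}
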