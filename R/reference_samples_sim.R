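# Canonical footprint compositions used by the simulator. A footprint of a
# given true class gets this percent-cover vector over the seven interpreted
# categories; the derived mixed_woody class is represented by intermediate
# woody cover (20-80% rule).
class_composition <- function(class8) {
  comp <- list(
    woody       = c(woody = 90, herb = 10),
    mixed_woody = c(woody = 50, herb = 30, ag = 20),
    plant       = c(plant = 85, woody = 15),
    herb        = c(herb = 90, woody = 10),
    ag          = c(ag = 90, herb = 10),
    built       = c(built = 85, bare = 15),
    bare        = c(bare = 90, herb = 10),
    water       = c(water = 95, herb = 5)
  )
  full <- stats::setNames(numeric(7), pct_categories())
  v <- comp[[class8]]
  full[names(v)] <- v
  full
}

#' Simulate paired-interpreter reference samples
#'
#' Places reference footprints on the landscape honoring a minimum spacing
#' between sample centers, then generates two interpreters' percent-cover
#' estimates per sample. Each footprint's true composition is the canonical
#' percent-cover vector of its true class in a randomly chosen image year;
#' interpreter estimates add truncated Gaussian noise (renormalized to
#' 100%), and, at the disagreement rate, the second interpreter's two
#' largest categories are swapped so the majority cover differs. Half the
#' samples (by default) are placed by class-stratified sampling, the rest
#' purely at random.
#'
#' @param true_cover An `lulc_cover_series`.
#' @param n_samples Number of footprints.
#' @param min_spacing_m Minimum distance between sample centers in meters
#'   (default 1000).
#' @param interpreter_noise Sd of percent-cover noise (percent points,
#'   default 5).
#' @param disagreement_rate Probability that interpreters disagree on the
#'   majority cover (default 0.1).
#' @param stratified_fraction Fraction of samples placed by class-stratified
#'   sampling (default 0.5; the balance is purely random).
#' @param seed Integer seed.
#' @param max_attempts Placement attempts before declaring the spacing
#'   constraint infeasible.
#' @return Object of class `lulc_samples`: list with `interpretations`
#'   (data frame, two rows per sample: `sample_id`, `x`, `y`, `pixel`,
#'   `year`, `interpreter`, `pct_*` columns) and `truth` (data frame with
#'   `sample_id`, `pixel`, `year`, `class8`, true `pct_*` columns).
#' @export
simulate_reference_samples <- function(true_cover, n_samples,
                                       min_spacing_m = 1000,
                                       interpreter_noise = 5,
                                       disagreement_rate = 0.1,
                                       stratified_fraction = 0.5,
                                       seed = 1, max_attempts = 200L) {
  stopifnot(inherits(true_cover, "lulc_cover_series"))
  part <- true_cover$partition
  set.seed(seed)
  cats <- pct_categories()
  empty <- function(n) {
    df <- as.data.frame(matrix(numeric(0), 0, 6 + length(cats)))
    names(df) <- c("sample_id", "x", "y", "pixel", "year", "interpreter",
                   paste0("pct_", cats))
    df
  }
  if (n_samples == 0) {
    return(structure(list(interpretations = empty(0),
                          truth = empty(0)[, -6]), class = "lulc_samples"))
  }

  n_pix <- nrow(true_cover$labels)
  px_r <- (seq_len(n_pix) - 1L) %% part$rows + 1L
  px_c <- (seq_len(n_pix) - 1L) %/% part$rows + 1L
  # pixel-center coordinates in meters (grid origin at 0,0)
  cx <- (px_c - 0.5) * part$cell_size
  cy <- (px_r - 0.5) * part$cell_size
  min_d2 <- min_spacing_m^2

  n_strat <- round(n_samples * stratified_fraction)
  year1_class <- true_cover$labels[, 1]
  # candidate order: stratified picks cycle through classes present
  strat_pool <- split(seq_len(n_pix), year1_class)
  chosen <- integer(0)
  far_enough <- function(p) {
    length(chosen) == 0 ||
      all((cx[chosen] - cx[p])^2 + (cy[chosen] - cy[p])^2 >= min_d2)
  }
  attempts <- 0L
  k <- 0L
  while (length(chosen) < n_samples) {
    k <- k + 1L
    stratified <- length(chosen) < n_strat
    cand <- if (stratified) {
      pool <- strat_pool[[1 + (k - 1) %% length(strat_pool)]]
      pool[sample.int(length(pool), 1)]
    } else {
      sample.int(n_pix, 1)
    }
    if (far_enough(cand)) {
      chosen <- c(chosen, cand)
      attempts <- 0L
    } else {
      attempts <- attempts + 1L
      if (attempts >= max_attempts) {
        # rejection sampling has saturated: scan the full feasible set
        feas <- which(vapply(seq_len(n_pix), far_enough, logical(1)))
        if (length(feas) == 0) {
          stop("cannot place ", n_samples, " samples at >= ", min_spacing_m,
               " m spacing (placed ", length(chosen),
               "; no feasible pixel remains)")
        }
        chosen <- c(chosen, feas[sample.int(length(feas), 1)])
        attempts <- 0L
      }
    }
  }

  years <- true_cover$years
  yr_idx <- sample.int(length(years), n_samples, replace = TRUE)
  true_cls <- cover_classes8()[true_cover$labels[cbind(chosen, yr_idx)]]
  truth_p <- t(vapply(true_cls, class_composition, numeric(7)))

  jitter_pct <- function(p) {
    if (interpreter_noise <= 0) return(p)
    q <- pmax(p + rnorm(length(p), 0, interpreter_noise) * (p > 0), 0)
    100 * q / sum(q)
  }
  rows <- vector("list", 2L * n_samples)
  for (i in seq_len(n_samples)) {
    a <- jitter_pct(truth_p[i, ])
    b <- jitter_pct(truth_p[i, ])
    if (disagreement_rate > 0 && runif(1) < disagreement_rate) {
      o <- order(-b, seq_along(b))
      b[o[1:2]] <- b[o[2:1]]  # swap top two -> different majority
    }
    for (j in 1:2) {
      v <- if (j == 1) a else b
      rows[[2 * (i - 1) + j]] <- data.frame(
        sample_id = i, x = cx[chosen[i]], y = cy[chosen[i]],
        pixel = chosen[i], year = years[yr_idx[i]], interpreter = j,
        t(stats::setNames(v, paste0("pct_", cats)))
      )
    }
  }
  truth <- data.frame(
    sample_id = seq_len(n_samples), pixel = chosen,
    year = years[yr_idx], class8 = true_cls,
    stats::setNames(as.data.frame(truth_p), paste0("pct_", cats)),
    row.names = NULL
  )
  structure(list(interpretations = do.call(rbind, rows), truth = truth),
            class = "lulc_samples")
}

#' @export
print.lulc_samples <- function(x, ...) {
  cat("<lulc_samples> ", nrow(x$truth), " footprints, ",
      nrow(x$interpretations), " interpretations\n", sep = "")
  invisible(x)
}
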