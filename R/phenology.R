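#' Class phenology specification
#'
#' Defines, for every eight-scheme cover class, a seasonal mean curve over
#' the 23 sixteen-day composite slots of a year in each of the four bands
#' (EVI, red, NIR, MIR), a Gaussian observation-noise scale, and the
#' probability that a composite is cloud-contaminated (reliability flag 3).
#' The default curves are stylized but physically plausible tropical
#' signatures: evergreen woody cover is green (high EVI) and aseasonal,
#' herbaceous cover has a strong annual cycle, agriculture a double-peaked
#' cropping cycle, plantations high and mildly seasonal, built/bare low EVI
#' with bright red/MIR, and water dark in all bands. EVI is bounded to
#' \[-0.2, 1\] and reflectances to \[0, 1\] after noise.
#'
#' @param noise_sd Observation noise standard deviation (band units,
#'   default 0.02).
#' @param cloud_prob Per-composite probability of an unreliable (flag 3)
#'   observation, default 0.05.
#' @return Object of class `lulc_phenology`: list with `curves` (list per
#'   class of 23 x 4 matrices), `noise_sd`, `cloud_prob`.
#' @export
default_phenology <- function(noise_sd = 0.02, cloud_prob = 0.05) {
  t <- seq_len(23)
  s1 <- sin(2 * pi * (t - 1) / 23)        # annual cycle
  s2 <- sin(4 * pi * (t - 1) / 23)        # semi-annual (double cropping)
  curve <- function(evi, red, nir, mir) {
    m <- cbind(EVI = evi, red = red, NIR = nir, MIR = mir)
    rownames(m) <- NULL
    m
  }
  curves <- list(
    woody       = curve(0.55 + 0.03 * s1, 0.05 + 0 * t, 0.35 + 0.02 * s1, 0.12 + 0 * t),
    mixed_woody = curve(0.45 + 0.08 * s1, 0.07 + 0 * t, 0.32 + 0.03 * s1, 0.16 + 0 * t),
    plant       = curve(0.50 + 0.05 * s1, 0.06 + 0 * t, 0.38 + 0.02 * s1, 0.14 + 0 * t),
    herb        = curve(0.33 + 0.12 * s1, 0.09 + 0.02 * s1, 0.30 + 0.05 * s1, 0.20 + 0 * t),
    ag          = curve(0.30 + 0.13 * s2, 0.10 + 0.02 * s2, 0.28 + 0.04 * s2, 0.22 + 0 * t),
    built       = curve(0.15 + 0 * t, 0.18 + 0 * t, 0.22 + 0 * t, 0.25 + 0 * t),
    bare        = curve(0.10 + 0 * t, 0.25 + 0 * t, 0.30 + 0 * t, 0.35 + 0 * t),
    water       = curve(0.00 + 0 * t, 0.03 + 0 * t, 0.02 + 0 * t, 0.01 + 0 * t)
  )
  structure(list(curves = curves, noise_sd = noise_sd, cloud_prob = cloud_prob),
            class = "lulc_phenology")
}

#' Simulate a composite image cube from true cover
#'
#' Emulates a 16-day composite vegetation-index product: per pixel, 23
#' composites per year in four bands (EVI, red, NIR, MIR) plus a pixel
#' reliability flag, where 0 = good and 3 = unreliable (cloud). Band values
#' are the class seasonal curve plus Gaussian noise, clamped to physical
#' ranges; reliability flags are i.i.d. Bernoulli(`cloud_prob`).
#'
#' @param true_cover An `lulc_cover_series`.
#' @param phenology An `lulc_phenology`; must define every class present.
#' @param seed Integer seed.
#' @return Object of class `lulc_cube`: list with `bands` (list of four
#'   pixel x (23*years) matrices), `reliability` (same shape, values 0/3),
#'   `years`, `n_pixels`.
#' @export
simulate_composites <- function(true_cover, phenology = default_phenology(),
                                seed = 1) {
  stopifnot(inherits(true_cover, "lulc_cover_series"))
  labels <- true_cover$labels
  present <- cover_classes8()[sort(unique(as.vector(labels)))]
  missing <- setdiff(present, names(phenology$curves))
  if (length(missing) > 0) {
    stop("phenology spec missing class(es): ", paste(missing, collapse = ", "))
  }
  set.seed(seed)
  n_pix <- nrow(labels)
  n_years <- ncol(labels)
  n_comp <- 23L
  band_names <- c("EVI", "red", "NIR", "MIR")
  lims <- list(EVI = c(-0.2, 1), red = c(0, 1), NIR = c(0, 1), MIR = c(0, 1))

  # per-class curve lookup matrices: class x composite, one per band
  cls <- cover_classes8()
  curve_by_band <- lapply(band_names, function(b) {
    t(vapply(cls, function(cl) {
      if (cl %in% names(phenology$curves)) phenology$curves[[cl]][, b] else rep(NA_real_, n_comp)
    }, numeric(n_comp)))
  })
  names(curve_by_band) <- band_names

  bands <- lapply(band_names, function(b) matrix(0, n_pix, n_comp * n_years))
  names(bands) <- band_names
  reliability <- matrix(0L, n_pix, n_comp * n_years)

  for (y in seq_len(n_years)) {
    colr <- ((y - 1) * n_comp + 1):(y * n_comp)
    lab <- labels[, y]
    for (b in band_names) {
      v <- curve_by_band[[b]][lab, , drop = FALSE]
      if (phenology$noise_sd > 0) {
        v <- v + matrix(rnorm(n_pix * n_comp, 0, phenology$noise_sd), n_pix, n_comp)
      }
      v[v < lims[[b]][1]] <- lims[[b]][1]
      v[v > lims[[b]][2]] <- lims[[b]][2]
      bands[[b]][, colr] <- v
    }
    if (phenology$cloud_prob > 0) {
      reliability[, colr] <- 3L * matrix(
        rbinom(n_pix * n_comp, 1, phenology$cloud_prob), n_pix, n_comp)
    }
  }

  structure(
    list(bands = bands, reliability = reliability,
         years = true_cover$years, n_pixels = n_pix),
    class = "lulc_cube"
  )
}

#' @export
print.lulc_cube <- function(x, ...) {
  cat("<lulc_cube> ", x$n_pixels, " pixels x ", length(x$years),
      " years x 23 composites x 4 bands; ",
      format(100 * mean(x$reliability == 3L), digits = 3),
      "% unreliable\n", sep = "")
  invisible(x)
}
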