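#' Cover-class schemes
#'
#' The pipeline labels reference samples and map pixels in an eight-category
#' scheme and reports maps and change statistics in a grouped five-class
#' scheme: \emph{ag} and \emph{herb} merge to \code{ag_herb},
#' \emph{mixed woody} and \emph{plant} (plantations) to
#' \code{mixed_woody_plant}, \emph{built} and \emph{bare} to
#' \code{bare_built}; \emph{woody} and \emph{water} pass through. Integer
#' codes follow the map-export convention 0 = No Data, 1 = woody,
#' 2 = mixed woody/plant, 3 = ag/herb, 4 = bare/built, 5 = water.
#'
#' @return Character vector of class names, in canonical (code) order.
#' @export
cover_classes8 <- function() {
  c("woody", "mixed_woody", "plant", "herb", "ag", "built", "bare", "water")
}

#' @rdname cover_classes8
#' @export
cover_classes5 <- function() {
  c("woody", "mixed_woody_plant", "ag_herb", "bare_built", "water")
}

#' Percent-cover categories interpreted on reference footprints
#'
#' Seven categories are visually estimated per footprint; the eighth map
#' class (\code{mixed_woody}) is derived from them by [assign_class()]. The
#' order is also the fixed tie-break order for "majority cover".
#'
#' @return Character vector of the seven category names.
#' @export
pct_categories <- function() {
  c("woody", "herb", "ag", "plant", "built", "bare", "water")
}

#' Group an eight-category class label into the five-class scheme
#'
#' @param class8 Character vector of 8-scheme labels (see [cover_classes8()]).
#' @return Character vector of 5-scheme labels.
#' @examples
#' group_to_five(c("plant", "water", "built"))
#' @export
group_to_five <- function(class8) {
  map <- c(
    woody = "woody", mixed_woody = "mixed_woody_plant",
    plant = "mixed_woody_plant", herb = "ag_herb", ag = "ag_herb",
    built = "bare_built", bare = "bare_built", water = "water"
  )
  bad <- is.na(class8) | !class8 %in% names(map)
  if (any(bad)) {
    stop("group_to_five() applies to labeled samples only; got: ",
         paste(unique(class8[bad]), collapse = ", "))
  }
  unname(map[class8])
}

#' @rdname group_to_five
#' @param class5 Character vector of 5-scheme labels.
#' @return `class5_code`: integer codes (1-5) of 5-scheme labels.
#' @export
class5_code <- function(class5) {
  match(class5, cover_classes5())
}

# integer codes for the 8-scheme (internal)
class8_code <- function(class8) match(class8, cover_classes8())

# round half away from zero, the convention of printed percentages
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
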