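#' Accuracy statistics from a confusion matrix
#'
#' Overall accuracy is the trace over the total; producer's accuracy per
#' class is the diagonal over the row (reference) total, user's accuracy
#' the diagonal over the column (prediction) total, all in percent. Rows
#' are reference, columns predicted.
#'
#' @param confusion Square numeric matrix (rows = reference).
#' @return List with `confusion`, `overall`, `producers`, `users`, `n`.
#' @examples
#' accuracy_from_matrix(matrix(c(8, 3, 2, 7), 2))  # overall 75%
#' @export
accuracy_from_matrix <- function(confusion) {
  confusion <- as.matrix(confusion)
  stopifnot(nrow(confusion) == ncol(confusion))
  n <- sum(confusion)
  dg <- diag(confusion)
  list(
    confusion = confusion,
    overall = 100 * sum(dg) / n,
    producers = 100 * dg / rowSums(confusion),
    users = 100 * dg / colSums(confusion),
    n = n
  )
}

#' Out-of-bag accuracy report of a biome classifier
#'
#' Grouped five-class accuracy from the initial model's out-of-bag
#' predictions: both OOB predictions and reference labels are mapped from
#' the eight-scheme to the five-class scheme before the confusion matrix is
#' built (the grouping reduces inter-class confusion, and map reporting is
#' in five classes). The sample count is the post-outlier-filter training
#' size.
#'
#' @param classifier_pair An `lulc_classifier_pair`.
#' @return Object of class `lulc_accuracy`: the [accuracy_from_matrix()]
#'   fields plus `biome` and `classes`.
#' @export
oob_accuracy <- function(classifier_pair) {
  ref8 <- classifier_pair$class8
  pred8 <- as.character(classifier_pair$initial$oob_pred)
  usable <- !is.na(pred8)
  ref5 <- factor(group_to_five(ref8[usable]), levels = cover_classes5())
  pred5 <- factor(group_to_five(pred8[usable]), levels = cover_classes5())
  rep <- accuracy_from_matrix(unclass(table(ref5, pred5)))
  rep$biome <- classifier_pair$biome
  rep$classes <- cover_classes5()
  rep$n <- classifier_pair$n_samples
  class(rep) <- "lulc_accuracy"
  rep
}

#' @export
print.lulc_accuracy <- function(x, ...) {
  cat("<lulc_accuracy> biome ", x$biome, ": overall ",
      format(x$overall, digits = 4), "% (n=", x$n, ")\n", sep = "")
  invisible(x)
}

#' Cross-biome accuracy summary
#'
#' Unweighted mean and sample standard deviation (n-1) of the per-biome
#' overall accuracies, and unweighted per-class means of producer's and
#' user's accuracies. Note this is the plain biome mean, not the
#' sample-weighted mean.
#'
#' @param reports List of `lulc_accuracy` reports (>= 2), or a data frame
#'   with an `overall` column plus optional `producers`/`users` matrices.
#' @return List with `mean_overall`, `sd_overall`, `mean_producers`,
#'   `mean_users`, `n_total`, `per_biome`.
#' @export
summarize_accuracy <- function(reports) {
  if (is.data.frame(reports)) {
    overall <- reports$overall
    producers <- users <- NULL
    n_total <- if ("n" %in% names(reports)) sum(reports$n) else NA
  } else {
    stopifnot(length(reports) >= 2)
    overall <- vapply(reports, function(r) r$overall, numeric(1))
    producers <- do.call(rbind, lapply(reports, function(r) r$producers))
    users <- do.call(rbind, lapply(reports, function(r) r$users))
    n_total <- sum(vapply(reports, function(r) r$n, numeric(1)))
  }
  list(
    mean_overall = mean(overall),
    sd_overall = sd(overall),
    mean_producers = if (!is.null(producers)) colMeans(producers, na.rm = TRUE),
    mean_users = if (!is.null(users)) colMeans(users, na.rm = TRUE),
    n_total = n_total,
    per_biome = overall
  )
}
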