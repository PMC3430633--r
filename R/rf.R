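#' Fit a seeded classification random forest
#'
#' Bagged CART trees with Gini splits, `mtry` candidate predictors per
#' split and a minimum terminal-node size, grown by the package's compiled
#' backend (no tree/forest package is assumed present at run time).
#' Out-of-bag votes and, optionally, the case-proximity matrix (fraction of
#' trees in which two cases land in the same terminal node) are returned.
#' Identical seeds reproduce the forest bit-identically.
#'
#' @param x Numeric predictor matrix (no missing values).
#' @param y Factor (or character) response.
#' @param n_trees Number of trees (default 1999).
#' @param nodesize Minimum terminal-node size (default 5): nodes at or
#'   below this size are not split further.
#' @param mtry Candidate predictors per split; default `floor(sqrt(p))`.
#' @param seed Integer seed.
#' @param proximity Compute the n x n proximity matrix (default `TRUE`).
#' @return Object of class `lulc_rf`: list with `trees`, `classes`,
#'   `oob_votes`, `oob_pred`, `proximity`, `config`.
#' @export
rf_fit <- function(x, y, n_trees = 1999, nodesize = 5,
                   mtry = NULL, seed = 1, proximity = TRUE) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("predictor matrix contains missing values")
  y <- factor(y)
  if (nlevels(y) < 2) stop("need at least two classes to train")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  fit <- rf_build(x, as.integer(y) - 1L, nlevels(y), as.integer(n_trees),
                  as.integer(mtry), as.integer(nodesize), as.double(seed),
                  isTRUE(proximity))
  votes <- fit$oob_votes
  colnames(votes) <- levels(y)
  # majority OOB vote, ties -> first (lowest) class in level order
  oob_pred <- factor(levels(y)[max.col(votes, ties.method = "first")],
                     levels = levels(y))
  oob_pred[fit$oob_count == 0] <- NA
  structure(
    list(trees = fit$trees, classes = levels(y), y = y,
         oob_votes = votes, oob_pred = oob_pred,
         oob_count = fit$oob_count, proximity = fit$proximity,
         config = list(n_trees = n_trees, nodesize = nodesize,
                       mtry = mtry, seed = seed),
         n_features = ncol(x), feature_names = colnames(x)),
    class = "lulc_rf"
  )
}

#' @export
print.lulc_rf <- function(x, ...) {
  cat("<lulc_rf> ", length(x$trees), " trees, ", length(x$classes),
      " classes, mtry=", x$config$mtry, ", nodesize=", x$config$nodesize,
      "\n", sep = "")
  invisible(x)
}

#' Predict classes with a fitted forest
#'
#' Majority vote over all trees; ties broken by the fixed class (level)
#' order.
#'
#' @param object An `lulc_rf`.
#' @param newdata Numeric matrix with the training feature columns.
#' @param ... Unused.
#' @return Factor of predicted classes.
#' @export
predict.lulc_rf <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(object$feature_names) && !is.null(colnames(newdata))) {
    newdata <- newdata[, object$feature_names, drop = FALSE]
  }
  if (ncol(newdata) != object$n_features) {
    stop("newdata has ", ncol(newdata), " features; model expects ",
         object$n_features)
  }
  votes <- rf_votes(object$trees, newdata, length(object$classes))
  factor(object$classes[max.col(votes, ties.method = "first")],
         levels = object$classes)
}

#' Proximity-based outlier scores
#'
#' The classic forest outlier measure: for case i of class c the raw score
#' is `n_c / sum_j prox(i,j)^2` over classmates j, standardized within the
#' class by subtracting the class median and dividing by the class mean
#' absolute deviation from the median. Classes with fewer than two members
#' get score 0 (retained).
#'
#' @param proximity n x n proximity matrix.
#' @param y Class vector aligned with its rows.
#' @return Numeric vector of standardized outlier scores.
#' @export
rf_outlier_scores <- function(proximity, y) {
  y <- as.character(y)
  n <- length(y)
  raw <- numeric(n)
  for (cl in unique(y)) {
    mem <- which(y == cl)
    if (length(mem) < 2) {
      raw[mem] <- NA  # undefined; standardized to 0 below
      next
    }
    for (i in mem) {
      p2 <- proximity[i, setdiff(mem, i)]^2
      raw[i] <- length(mem) / max(sum(p2), .Machine$double.eps)
    }
  }
  score <- numeric(n)
  for (cl in unique(y)) {
    mem <- which(y == cl)
    r <- raw[mem]
    if (anyNA(r) || length(mem) < 2) next
    med <- median(r)
    madm <- mean(abs(r - med))
    score[mem] <- if (madm <= .Machine$double.eps) 0 else (r - med) / madm
  }
  score
}

#' Remove proximity outliers from a training set
#'
#' Drops samples whose standardized outlier score exceeds `threshold`
#' (default 10, the conventional cutoff).
#'
#' @param samples Anything indexable by row/position (data frame or index
#'   vector); returned filtered.
#' @param proximity Proximity matrix from an initial forest fit on all
#'   samples.
#' @param y Class vector.
#' @param threshold Score cutoff (default 10).
#' @return List with `samples` (filtered), `keep` (logical), `scores`.
#' @export
remove_outliers <- function(samples, proximity, y, threshold = 10) {
  scores <- rf_outlier_scores(proximity, y)
  keep <- scores <= threshold
  filtered <- if (is.data.frame(samples) || is.matrix(samples)) {
    samples[keep, , drop = FALSE]
  } else {
    samples[keep]
  }
  list(samples = filtered, keep = keep, scores = scores)
}
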