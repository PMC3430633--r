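#' Majority cover category of a percent-cover vector
#'
#' The category with the largest percent; ties are broken by the fixed
#' category order of [pct_categories()]. Used to decide whether two
#' interpreters "agree on the majority cover".
#'
#' @param pct Named numeric vector over the seven categories (names may be
#'   bare category names or `pct_`-prefixed).
#' @return Category name.
#' @export
majority_cover <- function(pct) {
  pct <- normalize_pct(pct)
  ord <- pct_categories()
  ord[which.max(pct[ord])]
}

# accept pct_woody-style or bare names; return vector named by categories
normalize_pct <- function(pct) {
  nm <- names(pct)
  if (is.null(nm)) stop("percent-cover vector must be named")
  nm <- sub("^pct_", "", nm)
  keep <- nm %in% pct_categories()
  v <- stats::setNames(numeric(7), pct_categories())
  v[nm[keep]] <- as.numeric(pct[keep])
  if (any(v < 0)) stop("percent covers must be nonnegative")
  if (abs(sum(v) - 100) > 0.5) {
    stop("percent covers must sum to 100 (got ", round(sum(v), 2), ")")
  }
  v
}

#' Consensus of two interpreters' percent-cover estimates
#'
#' If the interpreters agree on the majority cover category and on the
#' image year, their percent estimates are averaged element-wise
#' (provenance `"averaged"`). Otherwise the supplied expert resolution is
#' adopted verbatim (provenance `"expert"`); with no expert resolution the
#' sample is flagged unresolved and excluded from labelling. A tie for
#' majority counts as agreement only if both interpreters tie identically.
#'
#' @param interpretation_a,interpretation_b Lists/rows with `sample_id`,
#'   `year` and percent-cover entries (`pct_*` columns accepted).
#' @param expert_resolution Optional list with `year` and percent covers,
#'   adopted on disagreement.
#' @return Object of class `lulc_consensus`: list with `sample_id`, `pct`
#'   (named vector), `year`, `provenance` (`"averaged"`, `"expert"` or
#'   `"unresolved"`).
#' @export
consensus <- function(interpretation_a, interpretation_b,
                      expert_resolution = NULL) {
  ia <- interpretation_a
  ib <- interpretation_b
  if (!identical(as.integer(ia$sample_id), as.integer(ib$sample_id))) {
    stop("interpretations refer to different samples (",
         ia$sample_id, " vs ", ib$sample_id, ")")
  }
  pa <- normalize_pct(unlist(ia[grep("^pct_", names(ia))]))
  pb <- normalize_pct(unlist(ib[grep("^pct_", names(ib))]))

  tie_set <- function(p) {
    m <- max(p)
    names(p)[p == m]
  }
  agree_major <- identical(tie_set(pa), tie_set(pb))
  agree_year <- identical(as.integer(ia$year), as.integer(ib$year))

  if (agree_major && agree_year) {
    out <- list(sample_id = ia$sample_id, pct = (pa + pb) / 2,
                year = as.integer(ia$year), provenance = "averaged")
  } else if (!is.null(expert_resolution)) {
    keep <- sub("^pct_", "", names(expert_resolution)) %in% pct_categories()
    pe <- normalize_pct(unlist(expert_resolution[keep]))
    out <- list(sample_id = ia$sample_id, pct = pe,
                year = as.integer(expert_resolution$year),
                provenance = "expert")
  } else {
    out <- list(sample_id = ia$sample_id, pct = NULL, year = NA_integer_,
                provenance = "unresolved")
  }
  structure(out, class = "lulc_consensus")
}

#' Assign an eight-scheme class from final percent covers
#'
#' A sample is assigned to a class if that category's cover is >= 80%;
#' otherwise, samples with 20-80% woody cover whose bare, herb and ag
#' components are each < 80% become `mixed_woody`. All other compositions
#' are unassigned (`NA`). The >= 80% single-category rule takes precedence;
#' the 20-80% woody interval is closed on both ends.
#'
#' @param final_percents Named percent-cover vector (sums to 100 +- 0.5).
#' @return Class name from [cover_classes8()], or `NA_character_`.
#' @examples
#' assign_class(c(woody = 85, herb = 15))           # "woody"
#' assign_class(c(woody = 50, herb = 30, ag = 20))  # "mixed_woody"
#' assign_class(c(ag = 79, herb = 21))              # NA (unassigned)
#' @export
assign_class <- function(final_percents) {
  p <- normalize_pct(final_percents)
  dominant <- names(p)[p >= 80]
  if (length(dominant) > 0) {
    # precedence by fixed category order if (implausibly) several qualify
    return(pct_categories()[min(match(dominant, pct_categories()))])
  }
  if (p["woody"] >= 20 && p["woody"] <= 80 &&
      p["bare"] < 80 && p["herb"] < 80 && p["ag"] < 80) {
    return("mixed_woody")
  }
  NA_character_
}

#' Label a table of paired interpretations
#'
#' Applies [consensus()] and [assign_class()] to every sample in an
#' interpretation table (two rows per sample), then groups assigned labels
#' to the five-class scheme. Disagreements are resolved from
#' `expert_resolutions` when available (matched by `sample_id`); samples
#' left unresolved or unassigned get `NA` labels.
#'
#' @param interpretations Data frame as produced by
#'   [simulate_reference_samples()] (or read from its CSV).
#' @param expert_resolutions Optional data frame with `sample_id`, `year`
#'   and `pct_*` columns (the simulator's `truth` table works).
#' @return Data frame with one row per sample: `sample_id`, `pixel` (if
#'   present), `year`, final `pct_*` columns, `provenance`, `class8`,
#'   `class5`.
#' @export
label_samples <- function(interpretations, expert_resolutions = NULL) {
  ids <- sort(unique(interpretations$sample_id))
  pct_cols <- grep("^pct_", names(interpretations), value = TRUE)
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    rows <- interpretations[interpretations$sample_id == ids[i], ]
    if (nrow(rows) != 2) {
      stop("sample ", ids[i], " must have exactly two interpretations")
    }
    expert <- NULL
    if (!is.null(expert_resolutions)) {
      er <- expert_resolutions[expert_resolutions$sample_id == ids[i], ]
      if (nrow(er) == 1) expert <- as.list(er)
    }
    cs <- consensus(as.list(rows[1, ]), as.list(rows[2, ]), expert)
    cls8 <- if (cs$provenance == "unresolved") NA_character_ else assign_class(cs$pct)
    pct <- if (is.null(cs$pct)) rep(NA_real_, 7) else unname(cs$pct)
    out[[i]] <- data.frame(
      sample_id = ids[i],
      pixel = if ("pixel" %in% names(rows)) rows$pixel[1] else NA_integer_,
      year = cs$year,
      t(stats::setNames(pct, paste0("pct_", pct_categories()))),
      provenance = cs$provenance,
      class8 = cls8,
      class5 = if (is.na(cls8)) NA_character_ else group_to_five(cls8)
    )
  }
  do.call(rbind, out)
}
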