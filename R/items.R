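# Item reduction and scale scoring.

#' Retain the top-loading items of each subconstruct
#'
#' Keeps, within every first-order subconstruct, the \code{k} items with
#' the largest standardized loadings; ties are broken by questionnaire
#' order (earlier item wins) and recorded. Loadings are compared at full
#' floating precision.
#'
#' @param loadings named per-item loadings, or a fitted
#'   \code{"igdc_cfa"} object (its \code{lambda} is used).
#' @param factor_map named list of item labels per subconstruct; taken
#'   from the fit when \code{loadings} is an \code{"igdc_cfa"}.
#' @param k items to retain per subconstruct (default 3).
#' @return object of class \code{"scale_definition"}: list with
#'   \code{factor_map} (retained items by subconstruct), \code{items},
#'   \code{dropped}, \code{score_range}, \code{ties} (labels where the
#'   tie rule fired).
#' @export
select_top_items <- function(loadings, factor_map = NULL, k = 3L) {
  if (inherits(loadings, "igdc_cfa")) {
    if (!loadings$converged) stop("cannot reduce items from a non-converged fit")
    factor_map <- loadings$spec$factor_map
    loadings <- loadings$lambda
  }
  if (is.null(factor_map)) stop("factor_map required with a plain loading vector")
  if (any(lengths(factor_map) < k)) {
    short <- names(factor_map)[lengths(factor_map) < k]
    stop("subconstruct(s) with fewer than k items: ", paste(short, collapse = ", "))
  }
  kept <- lapply(factor_map, function(items) {
    lam <- loadings[items]
    if (anyNA(lam)) stop("loading missing for: ",
                         paste(items[is.na(lam)], collapse = ", "))
    # stable sort: ties resolved by questionnaire (input) order
    items[order(-lam)[seq_len(k)]]
  })
  kept <- lapply(kept, function(it) it[order(match(it, unlist(factor_map)))])
  ties <- names(factor_map)[vapply(factor_map, function(items) {
    anyDuplicated(loadings[items]) > 0L
  }, logical(1))]
  items <- unlist(kept, use.names = FALSE)
  structure(list(factor_map = kept, items = items,
                 dropped = setdiff(unlist(factor_map, use.names = FALSE), items),
                 score_range = c(0L, 2L * length(items)), ties = ties),
            class = "scale_definition")
}

#' @export
print.scale_definition <- function(x, ...) {
  cat("Scale definition:", length(x$items), "items across",
      length(x$factor_map), "subconstructs; score range",
      x$score_range[1], "-", x$score_range[2], "\n")
  if (length(x$dropped)) cat("Dropped:", paste(x$dropped, collapse = ", "), "\n")
  if (length(x$ties)) cat("Tie rule applied in:", paste(x$ties, collapse = ", "), "\n")
  invisible(x)
}

#' Sum score over a scale definition
#'
#' @param responses person x item matrix of codes.
#' @param scale a \code{"scale_definition"}, or a character vector of
#'   item labels.
#' @return per-person integer sum score.
#' @export
sum_score <- function(responses, scale) {
  items <- if (inherits(scale, "scale_definition")) scale$items else scale
  missing <- setdiff(items, colnames(responses))
  if (length(missing)) stop("unknown item label(s): ", paste(missing, collapse = ", "))
  X <- responses[, items, drop = FALSE]
  if (anyNA(X)) stop("missing responses on scale items; drop incomplete rows first")
  as.integer(rowSums(X))
}
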