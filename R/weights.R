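#' Rank-based method weights
#'
#' The two selectors are ranked: the better-performing method receives
#' weight 2, the other weight 1. Only the two assignments `{1, 2}` and
#' `{2, 1}` exist; a run enumerates both.
#'
#' @param w_lasso,w_mrmr integer weights; must be `{1, 2}` in some order.
#' @return object of class `method_weights`.
#' @export
method_weights <- function(w_lasso, w_mrmr) {
  w_lasso <- as.integer(w_lasso)
  w_mrmr <- as.integer(w_mrmr)
  if (!setequal(c(w_lasso, w_mrmr), c(1L, 2L)))
    stop("method weights must be {1, 2} in some order", call. = FALSE)
  structure(list(w_lasso = w_lasso, w_mrmr = w_mrmr),
            class = "method_weights")
}

#' Accumulate per-fold selections into feature weights
#'
#' Each feature's weight is the sum, over folds, of the method weight of
#' every selector that picked it:
#' `weight(f) = sum_folds [ w_lasso * (f in lasso set) + w_mrmr * (f in mrmr set) ]`.
#' With 5 folds and weights `{1, 2}` the theoretical maximum is 15.
#' Features never selected are not stored.
#'
#' @param per_fold list of length `n_folds`; each element a list with
#'   character elements `lasso` and `mrmr` (either may be empty).
#' @param mw a [method_weights].
#' @param n_folds expected number of folds (defaults to
#'   `length(per_fold)`).
#' @return object of class `weight_table`: list with `weights` (named
#'   integer vector, decreasing weight then feature ID), `n_folds`,
#'   `method_weights`.
#' @export
accumulate_weights <- function(per_fold, mw, n_folds = length(per_fold)) {
  stopifnot(inherits(mw, "method_weights"))
  if (length(per_fold) != n_folds)
    stop("per_fold must have length n_folds", call. = FALSE)
  tally <- integer(0)
  bump <- function(tally, ids, w) {
    if (!length(ids)) return(tally)
    ids <- unique(as.character(ids))
    new <- setdiff(ids, names(tally))
    if (length(new)) tally[new] <- 0L
    tally[ids] <- tally[ids] + w
    tally
  }
  for (fold in per_fold) {
    tally <- bump(tally, fold$lasso, mw$w_lasso)
    tally <- bump(tally, fold$mrmr, mw$w_mrmr)
  }
  tally <- tally[order(-tally, names(tally))]
  structure(list(weights = tally, n_folds = as.integer(n_folds),
                 method_weights = mw),
            class = "weight_table")
}

#' @method print weight_table
#' @export
print.weight_table <- function(x, ...) {
  cat(sprintf("<weight_table> %d features over %d folds (w_lasso=%d, w_mrmr=%d); max weight %s\n",
              length(x$weights), x$n_folds, x$method_weights$w_lasso,
              x$method_weights$w_mrmr,
              if (length(x$weights)) max(x$weights) else "-"))
  invisible(x)
}

#' Candidate subset at a minimum-weight threshold
#'
#' Returns every feature with accumulated weight at least `k`; thresholds
#' above the maximum observed weight give the empty set, and the subsets
#' are nested: `subset(k + 1)` is contained in `subset(k)`.
#'
#' @param wt a [weight_table].
#' @param k minimum weight, `k >= 1`.
#' @return character vector of feature IDs (sorted by decreasing weight,
#'   then ID).
#' @export
subset_at_threshold <- function(wt, k) {
  stopifnot(inherits(wt, "weight_table"), k >= 1)
  names(wt$weights)[wt$weights >= k]
}
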