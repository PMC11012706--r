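#' Plan (stratified) cross-validation folds
#'
#' Binary targets get stratified folds: within each class, samples are
#' shuffled and dealt round-robin, so per-fold class counts deviate from
#' the proportional share by at most one sample. Continuous targets (or
#' binary targets containing unknowns, as in an all-status regression) get
#' plain shuffled folds, unless a separate binary `strata` vector is
#' supplied to stratify on (e.g. methylation status accompanying an
#' expression regression).
#'
#' @param target a [target_vector] (or plain vector) over the samples.
#' @param n_folds number of folds (default 5).
#' @param seed RNG seed for the shuffle (default 0).
#' @param strata optional factor-like vector to stratify on instead of the
#'   target itself.
#' @return an object of class `fold_plan`: list with `n_folds`,
#'   `assignments` (fold index per sample), `stratified`, `seed`.
#' @export
make_folds <- function(target, n_folds = 5L, seed = 0L, strata = NULL) {
  n_folds <- as.integer(n_folds)
  stopifnot(n_folds >= 2L)
  n <- if (inherits(target, "target_vector")) length(target) else length(target)

  strat_var <- NULL
  if (!is.null(strata)) {
    strat_var <- as.character(strata)
    stopifnot(length(strat_var) == n)
  } else if (inherits(target, "target_vector")) {
    if (target$kind == "binary" && !any(target$unknown_mask))
      strat_var <- target$values
  } else if (is.factor(target) || is.character(target)) {
    strat_var <- as.character(target)
  }

  assignments <- integer(n)
  if (is.null(strat_var)) {
    with_seed(seed, {
      assignments[sample.int(n)] <- rep_len(seq_len(n_folds), n)
    })
    stratified <- FALSE
  } else {
    classes <- sort(unique(strat_var))
    sizes <- table(strat_var)
    small <- names(sizes)[sizes < n_folds]
    if (length(small))
      stop("class(es) smaller than n_folds: ",
           paste(small, collapse = ", "), call. = FALSE)
    with_seed(seed, {
      offset <- 0L
      for (cl in classes) {
        idx <- which(strat_var == cl)
        idx <- idx[sample.int(length(idx))]
        # rotate the starting fold between classes so fold sizes stay even
        folds <- ((seq_along(idx) - 1L + offset) %% n_folds) + 1L
        assignments[idx] <- folds
        offset <- (offset + length(idx)) %% n_folds
      }
    })
    stratified <- TRUE
  }
  structure(list(n_folds = n_folds, assignments = assignments,
                 stratified = stratified, seed = as.integer(seed)),
            class = "fold_plan")
}

#' @method print fold_plan
#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> %d folds over %d samples (%s, seed %d)\n",
              x$n_folds, length(x$assignments),
              if (x$stratified) "stratified" else "shuffled", x$seed))
  invisible(x)
}

# indices of training / test rows for fold i
fold_train <- function(plan, i) which(plan$assignments != i)
fold_test <- function(plan, i) which(plan$assignments == i)
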