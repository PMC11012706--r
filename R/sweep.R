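#' Sweep the minimum-weight threshold over a weight table
#'
#' Evaluates the candidate subset `{f : weight(f) >= k}` for every k from 1
#' to the maximum observed weight, producing one row per k with the subset
#' size and every model's mean cross-validated score. Consecutive k values
#' often share the same subset; each distinct subset is evaluated once and
#' its scores reused, so identical subsets yield identical score rows.
#' Empty subsets (only possible above the maximum weight, hence never in
#' range) would be recorded with size 0 and no scores.
#'
#' @param wt a [weight_table].
#' @param evaluator function(character subset) -> named numeric vector of
#'   per-model scores (e.g. a closure over [evaluate_subset()]).
#' @param task `"classification"` (higher score is better) or
#'   `"regression"` (lower is better) — stored for [select_best()].
#' @return object of class `sweep_result`: list with `table` (data.frame:
#'   `k`, `n_features`, one column per model), `subsets` (list of feature
#'   vectors indexed by k), `task`.
#' @export
sweep_thresholds <- function(wt, evaluator,
                             task = c("classification", "regression")) {
  stopifnot(inherits(wt, "weight_table"), is.function(evaluator))
  task <- match.arg(task)
  if (!length(wt$weights))
    stop("weight table is empty: no feature was ever selected", call. = FALSE)
  kmax <- max(wt$weights)
  cache <- new.env(parent = emptyenv())
  rows <- vector("list", kmax)
  subsets <- vector("list", kmax)
  for (k in seq_len(kmax)) {
    subset <- subset_at_threshold(wt, k)
    subsets[[k]] <- subset
    if (!length(subset)) {
      rows[[k]] <- list(k = k, n_features = 0L, scores = NULL)
      next
    }
    key <- paste(sort(subset), collapse = "\r")
    if (is.null(cache[[key]])) {
      cache[[key]] <- tryCatch(evaluator(subset), error = function(e) {
        stop(sprintf("evaluation failed at threshold k=%d: %s", k,
                     conditionMessage(e)), call. = FALSE)
      })
    }
    rows[[k]] <- list(k = k, n_features = length(subset),
                      scores = cache[[key]])
  }
  model_names <- names(rows[[1L]]$scores)
  tab <- data.frame(k = seq_len(kmax),
                    n_features = vapply(rows, function(r) r$n_features, 0L))
  for (mn in model_names)
    tab[[mn]] <- vapply(rows, function(r)
      if (is.null(r$scores)) NA_real_ else unname(r$scores[[mn]]), 0)
  structure(list(table = tab, subsets = subsets, task = task),
            class = "sweep_result")
}

#' @method print sweep_result
#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %s, k = 1..%d\n", x$task, nrow(x$table)))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Pick the best (threshold, model) cell of a sweep
#'
#' Scans every scored cell of the sweep table and returns the best score —
#' maximum accuracy for classification, minimum MSE for regression. Ties on
#' the score are broken by fewer features, then by smaller k, then by the
#' fixed model order of the table columns. The result is invariant to the
#' row order of the table.
#'
#' @param sr a [sweep_result].
#' @return list with `k`, `subset`, `model`, `score`, `n_features`.
#' @export
select_best <- function(sr) {
  stopifnot(inherits(sr, "sweep_result"))
  tab <- sr$table
  model_names <- setdiff(colnames(tab), c("k", "n_features"))
  maximize <- sr$task == "classification"
  best <- NULL
  # evaluate cells in the canonical tie-break order so the first strict
  # improvement wins: k ascending within model after sorting on the keys
  cells <- expand.grid(row = seq_len(nrow(tab)),
                       mi = seq_along(model_names))
  for (idx in seq_len(nrow(cells))) {
    r <- cells$row[idx]; mn <- model_names[cells$mi[idx]]
    s <- tab[[mn]][r]
    if (is.na(s)) next
    cand <- list(k = tab$k[r], n_features = tab$n_features[r],
                 model = mn, score = s)
    if (is.null(best) || better_cell(cand, best, maximize)) best <- cand
  }
  if (is.null(best))
    stop("no evaluated (non-empty) row in the sweep", call. = FALSE)
  best$subset <- sr$subsets[[best$k]]
  best[c("k", "subset", "model", "score", "n_features")]
}

# strict ordering: better score, then fewer features, then smaller k, then
# earlier model in the fixed order (earlier == already-held best wins ties)
better_cell <- function(cand, best, maximize) {
  if (cand$score != best$score)
    return(if (maximize) cand$score > best$score else cand$score < best$score)
  if (cand$n_features != best$n_features)
    return(cand$n_features < best$n_features)
  if (cand$k != best$k) return(cand$k < best$k)
  FALSE
}
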