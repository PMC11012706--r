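#' Cross-validated evaluation of a feature subset
#'
#' For each model in the zoo, trains on each fold's training rows restricted
#' to the subset and scores the held-out rows — accuracy for classification,
#' mean squared error for regression — returning the unweighted mean over
#' folds. Features are standardized per fold on the training rows only
#' (fit on train, apply to test) so no test information leaks into scaling.
#'
#' @param m an [expr_matrix] (already preprocessed).
#' @param target a [target_vector]; binary targets must have no unknowns.
#' @param subset non-empty character vector of feature IDs, all present in
#'   `m`.
#' @param models a [model_config] matching the target kind.
#' @param plan a [fold_plan] over the samples of `m`.
#' @param per_fold if `TRUE`, also return the per-model per-fold score
#'   matrix as attribute `"folds"` for audit.
#' @return named numeric vector of mean scores, one per model.
#' @export
evaluate_subset <- function(m, target, subset, models, plan,
                            per_fold = FALSE) {
  stopifnot(inherits(m, "expr_matrix"), inherits(target, "target_vector"),
            inherits(models, "model_config"), inherits(plan, "fold_plan"))
  if (!length(subset)) stop("subset is empty", call. = FALSE)
  miss <- setdiff(subset, feature_ids(m))
  if (length(miss))
    stop("subset features absent from the matrix: ",
         paste(utils::head(miss, 5L), collapse = ", "), call. = FALSE)
  classification <- models$task == "classification"
  if (classification) {
    if (target$kind != "binary" || any(target$unknown_mask))
      stop("classification evaluation needs a binary target without unknowns",
           call. = FALSE)
    yfac <- target_factor(target)
  } else {
    if (target$kind != "continuous")
      stop("regression evaluation needs a continuous target", call. = FALSE)
  }

  V <- m$values[, subset, drop = FALSE]
  scores <- matrix(NA_real_, plan$n_folds, length(models$models),
                   dimnames = list(NULL, models$models))
  for (i in seq_len(plan$n_folds)) {
    tr <- fold_train(plan, i)
    te <- fold_test(plan, i)
    Xtr <- V[tr, , drop = FALSE]
    ctr <- colMeans(Xtr)
    str_ <- apply(Xtr, 2L, stats::sd)
    str_[str_ == 0 | !is.finite(str_)] <- 1
    Xtr <- scale(Xtr, center = ctr, scale = str_)
    Xte <- scale(V[te, , drop = FALSE], center = ctr, scale = str_)
    for (mod in models$models) {
      res <- tryCatch({
        if (classification) {
          pred <- fit_predict(mod, Xtr, yfac[tr], Xte, models$random_state)
          cc <- confusion_counts(yfac[te], pred,
                                 positive = target$positive_label)
          accuracy(cc)
        } else {
          pred <- fit_predict(mod, Xtr, target$values[tr], Xte,
                              models$random_state)
          mean_squared_error(target$values[te], pred)
        }
      }, error = function(e) {
        stop(sprintf("model %s failed on fold %d: %s", mod, i,
                     conditionMessage(e)), call. = FALSE)
      })
      scores[i, mod] <- res
    }
  }
  out <- colMeans(scores)
  if (per_fold) attr(out, "folds") <- scores
  out
}

#' Class-mean alteration analysis
#'
#' For every feature, computes the mean over positive-class samples, the
#' mean over negative-class samples, and their difference; features whose
#' absolute difference exceeds `band` are flagged as altered (the
#' conventional band on log2-scale serum data is 0.3). Output is sorted by
#' decreasing absolute difference with rank numbers.
#'
#' @param m an [expr_matrix] (typically log2-transformed).
#' @param target a binary [target_vector] without unknowns.
#' @param band non-negative half-width of the "unaltered" band (default 0.3).
#' @return data.frame with columns `feature_id`, `gene_symbol`, `mean_pos`,
#'   `mean_neg`, `diff`, `flagged`, `rank`.
#' @export
alteration_analysis <- function(m, target, band = 0.3) {
  stopifnot(inherits(m, "expr_matrix"), inherits(target, "target_vector"))
  if (target$kind != "binary" || any(target$unknown_mask))
    stop("alteration analysis needs a binary target without unknowns",
         call. = FALSE)
  pos <- target$values == target$positive_label
  if (!any(pos) || all(pos))
    stop("both classes must have at least one sample", call. = FALSE)
  mean_pos <- colMeans(m$values[pos, , drop = FALSE])
  mean_neg <- colMeans(m$values[!pos, , drop = FALSE])
  d <- mean_pos - mean_neg
  gs <- m$gene_symbols
  out <- data.frame(
    feature_id = feature_ids(m),
    gene_symbol = if (is.null(gs)) NA_character_
                  else unname(gs[feature_ids(m)]),
    mean_pos = unname(mean_pos),
    mean_neg = unname(mean_neg),
    diff = unname(d),
    flagged = unname(abs(d) > band),
    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$diff), out$feature_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
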