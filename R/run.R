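#' Run configuration for the full selection pipeline
#'
#' @param task `"classification"` or `"regression"`.
#' @param n_folds folds for the stratified CV (default 5).
#' @param seed seed for the fold plan and all stochastic components
#'   (default 0).
#' @param mrmr an [mrmr_config].
#' @param lasso a [lasso_config]; defaults to the logistic objective for
#'   classification and the linear objective (penalty 0.1) for regression.
#' @param models a [model_config]; defaults to the task's fixed zoo.
#' @param nested_evaluation if `TRUE`, candidate subsets are scored on a
#'   fresh fold split (seed + 1) instead of reusing the selection folds.
#'   The default (`FALSE`) reuses the selection folds, reproducing the
#'   published single-CV protocol; scores are then optimistically biased
#'   as generalization estimates.
#' @return object of class `run_config`.
#' @export
run_config <- function(task = c("classification", "regression"),
                       n_folds = 5L, seed = 0L,
                       mrmr = mrmr_config(),
                       lasso = NULL, models = NULL,
                       nested_evaluation = FALSE) {
  task <- match.arg(task)
  if (is.null(lasso))
    lasso <- if (task == "classification")
      lasso_config(objective = "logistic")
    else lasso_config(objective = "linear")
  if (is.null(models)) models <- model_config(task)
  stopifnot(inherits(mrmr, "mrmr_config"), inherits(lasso, "lasso_config"),
            inherits(models, "model_config"), models$task == task)
  structure(list(task = task, n_folds = as.integer(n_folds),
                 seed = as.integer(seed), mrmr = mrmr, lasso = lasso,
                 models = models, nested_evaluation = isTRUE(nested_evaluation)),
            class = "run_config")
}

#' Full hybrid feature-selection run
#'
#' Executes the whole pipeline on a preprocessed matrix: per-fold LASSO and
#' mRMR selection inside a stratified CV, weight accumulation under both
#' rank-based method-weight assignments (`lasso=1/mrmr=2` and
#' `lasso=2/mrmr=1`), a minimum-weight threshold sweep scoring every
#' candidate subset with the fixed model zoo, a best cell per assignment,
#' and the overall winner across assignments (ties: better score, fewer
#' features, smaller k, model order, then assignment order).
#'
#' For classification, samples with unknown status are dropped before fold
#' planning. For regression with a `strata` vector containing unknowns,
#' folds fall back to plain shuffling.
#'
#' @param m an [expr_matrix] (already preprocessed; see
#'   [preprocess_matrix()]).
#' @param target a [target_vector] aligned to `m`.
#' @param config a [run_config].
#' @param strata optional stratification labels for regression folds.
#' @return object of class `profwise_result`; see [write_report()] and the
#'   print method.
#' @export
run_profwise <- function(m, target, config = run_config(), strata = NULL) {
  stopifnot(inherits(m, "expr_matrix"), inherits(target, "target_vector"),
            inherits(config, "run_config"))
  if (length(target) != nrow(m$values))
    stop("matrix and target have different numbers of samples", call. = FALSE)
  classification <- config$task == "classification"
  if (classification) {
    if (target$kind != "binary")
      stop("classification requires a binary target", call. = FALSE)
    if (any(target$unknown_mask)) {
      keep <- which(!target$unknown_mask)
      m <- subset_matrix(m, samples = keep)
      target <- subset_target(target, keep)
    }
  } else if (target$kind != "continuous") {
    stop("regression requires a continuous target", call. = FALSE)
  }

  t0 <- proc.time()[["elapsed"]]
  stage <- function(msg) message(sprintf("[profwise %7.1fs] %s",
                                         proc.time()[["elapsed"]] - t0, msg))

  plan <- make_folds(target, config$n_folds, config$seed, strata = strata)
  stage(sprintf("fold plan: %d folds over %d samples%s", plan$n_folds,
                length(plan$assignments),
                if (plan$stratified) " (stratified)" else ""))

  per_fold <- vector("list", plan$n_folds)
  for (i in seq_len(plan$n_folds)) {
    tr <- fold_train(plan, i)
    Xtr <- m$values[tr, , drop = FALSE]
    ytr <- subset_target(target, tr)
    per_fold[[i]] <- list(lasso = lasso_select(Xtr, ytr, config$lasso),
                          mrmr = mrmr_rank(Xtr, ytr, config$mrmr))
    stage(sprintf("fold %d: LASSO %d features, mRMR %d features", i,
                  length(per_fold[[i]]$lasso), length(per_fold[[i]]$mrmr)))
  }

  eval_plan <- if (config$nested_evaluation)
    make_folds(target, config$n_folds, config$seed + 1L, strata = strata)
  else plan
  # memoized across both weight assignments: identical candidate subsets
  # (e.g. the k = 1 union) are scored once
  score_cache <- new.env(parent = emptyenv())
  evaluator <- function(subset) {
    key <- paste(sort(subset), collapse = "\r")
    if (is.null(score_cache[[key]]))
      score_cache[[key]] <- evaluate_subset(m, target, subset,
                                            config$models, eval_plan)
    score_cache[[key]]
  }

  assignments <- list(lasso1_mrmr2 = method_weights(1L, 2L),
                      lasso2_mrmr1 = method_weights(2L, 1L))
  weight_tables <- list()
  sweeps <- list()
  bests <- list()
  for (nm in names(assignments)) {
    wt <- accumulate_weights(per_fold, assignments[[nm]], plan$n_folds)
    weight_tables[[nm]] <- wt
    sweeps[[nm]] <- sweep_thresholds(wt, evaluator, task = config$task)
    bests[[nm]] <- select_best(sweeps[[nm]])
    stage(sprintf("%s: swept k=1..%d, best %s %s=%.4g with %d features at k=%d",
                  nm, nrow(sweeps[[nm]]$table), bests[[nm]]$model,
                  if (classification) "ACC" else "MSE",
                  bests[[nm]]$score, bests[[nm]]$n_features, bests[[nm]]$k))
  }

  winner_assignment <- names(bests)[1L]
  for (nm in names(bests)[-1L]) {
    if (better_cell(bests[[nm]], bests[[winner_assignment]],
                    maximize = classification))
      winner_assignment <- nm
  }
  winner <- bests[[winner_assignment]]
  winner$assignment <- winner_assignment
  gs <- m$gene_symbols
  winner$gene_symbols <- if (is.null(gs)) rep(NA_character_,
                                              length(winner$subset))
                         else unname(gs[winner$subset])
  stage(sprintf("winner: %s / %s, %d features (%.1f%% of %d)",
                winner_assignment, winner$model, winner$n_features,
                100 * winner$n_features / ncol(m$values), ncol(m$values)))

  structure(list(task = config$task, config = config, fold_plan = plan,
                 evaluation_plan = eval_plan, per_fold = per_fold,
                 weight_tables = weight_tables, sweeps = sweeps,
                 bests = bests, winner = winner,
                 n_input_features = ncol(m$values),
                 sample_ids = sample_ids(m)),
            class = "profwise_result")
}

#' @method print profwise_result
#' @export
print.profwise_result <- function(x, ...) {
  metric <- if (x$task == "classification") "ACC" else "MSE"
  cat(sprintf("<profwise_result> %s over %d samples x %d features\n",
              x$task, length(x$sample_ids), x$n_input_features))
  for (nm in names(x$bests)) {
    b <- x$bests[[nm]]
    cat(sprintf("  %s: best %s %s = %.4g, %d features (k = %d)\n",
                nm, b$model, metric, b$score, b$n_features, b$k))
  }
  w <- x$winner
  cat(sprintf("  winner: %s, %s %s = %.4g with %d features (%.1f%% reduction)\n",
              w$assignment, w$model, metric, w$score, w$n_features,
              100 * (1 - w$n_features / x$n_input_features)))
  invisible(x)
}

#' Write a full run report to a directory
#'
#' Emits, deterministically (no timestamps), everything needed to re-derive
#' any table cell: per-assignment sweep tables and weight tables (TSV), the
#' fold assignments and per-fold selector outputs (TSV), a winner summary
#' (JSON) and a package-version manifest (JSON).
#'
#' @param result a `profwise_result` from [run_profwise()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(result, dir) {
  stopifnot(inherits(result, "profwise_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, file)
    utils::write.table(df, file.path(dir, file), sep = "\t", quote = FALSE,
                       row.names = FALSE)

  for (nm in names(result$sweeps)) {
    tab <- result$sweeps[[nm]]$table
    num <- setdiff(colnames(tab), c("k", "n_features"))
    tab[num] <- lapply(tab[num], format_num)
    tsv(tab, sprintf("sweep_%s.tsv", nm))
    wt <- result$weight_tables[[nm]]
    tsv(data.frame(feature_id = names(wt$weights),
                   weight = unname(wt$weights)),
        sprintf("weights_%s.tsv", nm))
  }
  tsv(data.frame(sample_id = result$sample_ids,
                 fold = result$fold_plan$assignments),
      "fold_assignments.tsv")
  sel <- do.call(rbind, lapply(seq_along(result$per_fold), function(i) {
    pf <- result$per_fold[[i]]
    data.frame(fold = i,
               method = rep(c("lasso", "mrmr"),
                            c(length(pf$lasso), length(pf$mrmr))),
               feature_id = c(pf$lasso, pf$mrmr))
  }))
  tsv(sel, "fold_selections.tsv")

  w <- result$winner
  jsonlite::write_json(
    list(task = result$task,
         assignment = w$assignment,
         model = w$model,
         metric = if (result$task == "classification") "ACC" else "MSE",
         score = w$score,
         k = w$k,
         n_features = w$n_features,
         n_input_features = result$n_input_features,
         reduction_pct = 100 * (1 - w$n_features / result$n_input_features),
         features = as.list(w$subset),
         gene_symbols = as.list(w$gene_symbols),
         seed = result$config$seed,
         n_folds = result$config$n_folds),
    file.path(dir, "winner.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE, null = "null", na = "null")

  deps <- c("profwise", "glmnet", "e1071", "randomForest", "rpart", "class")
  vers <- vapply(deps, function(p)
    as.character(utils::packageVersion(p)), "")
  jsonlite::write_json(list(r_version = paste(R.version$major,
                                              R.version$minor, sep = "."),
                            packages = as.list(vers)),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(dir)
}
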