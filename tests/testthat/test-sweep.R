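# cheap synthetic evaluator: deterministic hash-like scores per subset
toy_evaluator <- function(models = c("SVM", "LR")) {
  function(subset) {
    h <- sum(utils::head(utf8ToInt(paste(sort(subset), collapse = "")), 50))
    stats::setNames(((h * seq_along(models)) %% 97) / 97, models)
  }
}

toy_weight_table <- function(weights) {
  per_fold <- list(list(lasso = names(weights), mrmr = character(0)))
  wt <- accumulate_weights(per_fold, method_weights(1, 2), 1)
  wt$weights <- sort(as.integer(weights), decreasing = TRUE)
  names(wt$weights) <- names(sort(weights, decreasing = TRUE))
  wt
}

test_that("the sweep emits one row per k up to the maximum weight", {
  wt <- toy_weight_table(c(a = 8L, b = 5L, c = 5L, d = 1L))
  sr <- sweep_thresholds(wt, toy_evaluator(), task = "classification")
  expect_identical(nrow(sr$table), 8L)
  expect_identical(sr$table$k, 1:8)
  expect_identical(sr$table$n_features, c(4L, 3L, 3L, 3L, 3L, 1L, 1L, 1L))

  # identical subsets at consecutive k give identical score rows
  expect_identical(sr$table$SVM[2:5], rep(sr$table$SVM[2L], 4L))
  expect_identical(sr$table$SVM[6:8], rep(sr$table$SVM[6L], 3L))

  # every row's subset equals an independent recomputation
  for (k in 1:8)
    expect_setequal(sr$subsets[[k]], names(wt$weights)[wt$weights >= k])
})

test_that("select_best agrees with a brute-force scan over random sweeps", {
  set.seed(51)
  models <- c("SVM", "LR", "KNN", "RF", "AdaBoost")
  for (case in 1:30) {
    kmax <- sample(3:12, 1)
    sizes <- sort(sample.int(60, kmax), decreasing = TRUE)
    # force duplicated score rows sometimes, and exact ties
    tab <- data.frame(k = seq_len(kmax), n_features = sizes)
    for (mn in models)
      tab[[mn]] <- round(runif(kmax), sample(1:2, 1))
    task <- if (case %% 2) "classification" else "regression"
    sr <- structure(list(table = tab,
                         subsets = lapply(sizes, function(s)
                           sprintf("f%02d", seq_len(s))),
                         task = task),
                    class = "sweep_result")
    got <- select_best(sr)
    want <- oracle_best_cell(tab, models, maximize = task == "classification")
    expect_identical(got[c("k", "model", "score", "n_features")],
                     want[c("k", "model", "score", "n_features")])

    # invariance to row order
    shuf <- sr
    ord <- sample.int(kmax)
    shuf$table <- tab[ord, , drop = FALSE]
    got2 <- select_best(shuf)
    expect_identical(got2[c("k", "model", "score", "n_features")],
                     got[c("k", "model", "score", "n_features")])
  }
})

test_that("score ties resolve to fewer features, then smaller k", {
  tab <- data.frame(k = 1:3, n_features = c(30L, 19L, 19L),
                    SVR = c(0.2, 0.173, 0.173), RF = c(0.3, 0.25, 0.21))
  sr <- structure(list(table = tab,
                       subsets = list(sprintf("f%02d", 1:30),
                                      sprintf("f%02d", 1:19),
                                      sprintf("f%02d", 1:19)),
                       task = "regression"),
                  class = "sweep_result")
  best <- select_best(sr)
  expect_identical(best$n_features, 19L)
  expect_identical(best$k, 2L)
  expect_identical(best$model, "SVR")
  expect_identical(best$score, 0.173)
})

test_that("evaluator failures surface with the threshold annotated", {
  wt <- toy_weight_table(c(a = 3L, b = 1L))
  bomb <- function(subset) if (length(subset) < 2) stop("boom") else
    c(SVM = 0.5)
  expect_error(sweep_thresholds(wt, bomb, task = "classification"),
               "k=2.*boom")
})
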