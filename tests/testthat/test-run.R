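# one small end-to-end classification run shared by several blocks
small_cls_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- generate_synthetic(synthetic_spec(
        n_samples = 50, n_features = 80, n_informative = 4,
        n_redundant_per_informative = 1, effect_size = 2, seed = 17))
      cfg <- run_config("classification", seed = 0,
                        mrmr = mrmr_config(n_select = 12))
      res <- suppressMessages(run_profwise(ds$matrix, ds$target, cfg))
      cache <<- list(ds = ds, cfg = cfg, res = res)
    }
    cache
  }
})

test_that("an end-to-end run recovers planted groups and is internally consistent", {
  st <- small_cls_run()
  res <- st$res

  rec <- group_recovery(res$winner$subset, st$ds$truth)
  expect_gte(rec$recovered, 3L)

  # both rank-based weight assignments present
  expect_identical(names(res$weight_tables), c("lasso1_mrmr2", "lasso2_mrmr1"))
  expect_identical(res$weight_tables$lasso1_mrmr2$method_weights$w_mrmr, 2L)

  # every sweep row's subset matches an independent recomputation, and
  # recorded scores are reproducible from the evaluation module
  for (nm in names(res$sweeps)) {
    sr <- res$sweeps[[nm]]
    wt <- res$weight_tables[[nm]]
    for (k in seq_len(nrow(sr$table)))
      expect_setequal(sr$subsets[[k]], subset_at_threshold(wt, k))
    spot <- sr$table[nrow(sr$table), ]   # re-derive one row per assignment
    rescored <- evaluate_subset(st$ds$matrix, st$ds$target,
                                sr$subsets[[spot$k]],
                                st$cfg$models, res$evaluation_plan)
    for (mod in names(rescored))
      expect_equal(spot[[mod]], unname(rescored[mod]))
  }

  # the winner is one of the per-assignment bests
  expect_identical(res$winner$score,
                   res$bests[[res$winner$assignment]]$score)
  # winner gene symbols line up with the matrix map
  gs <- st$ds$matrix$gene_symbols
  expect_identical(res$winner$gene_symbols,
                   unname(gs[res$winner$subset]))
})

test_that("unknown-status samples are dropped before classification", {
  ds <- generate_synthetic(synthetic_spec(
    n_samples = 50, n_features = 40, n_informative = 3, effect_size = 2,
    unknown_fraction = 0.2, seed = 18))
  expect_identical(sum(ds$target$unknown_mask), 10L)
  cfg <- run_config("classification", seed = 0,
                    mrmr = mrmr_config(n_select = 8))
  res <- suppressMessages(run_profwise(ds$matrix, ds$target, cfg))
  expect_length(res$sample_ids, 40L)
  expect_length(res$fold_plan$assignments, 40L)
})

test_that("report writing is deterministic and re-loadable", {
  st <- small_cls_run()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_report(st$res, d1)
  res2 <- suppressMessages(run_profwise(st$ds$matrix, st$ds$target, st$cfg))
  write_report(res2, d2)
  files <- sort(list.files(d1))
  expect_identical(sort(list.files(d2)), files)
  expect_true("winner.json" %in% files)
  for (f in files)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     info = f)

  w <- jsonlite::read_json(file.path(d1, "winner.json"),
                           simplifyVector = TRUE)
  expect_identical(sort(unlist(w$features)), sort(st$res$winner$subset))
  expect_equal(w$score, st$res$winner$score)
})

test_that("a regression run selects the planted predictors", {
  ds <- generate_synthetic(synthetic_spec(
    n_samples = 60, n_features = 60, n_informative = 3,
    n_redundant_per_informative = 1, task = "regression", seed = 19))
  cfg <- run_config("regression", seed = 0, mrmr = mrmr_config(n_select = 10))
  res <- suppressMessages(run_profwise(ds$matrix, ds$target, cfg))
  expect_identical(res$config$lasso$objective, "linear")
  expect_identical(sort(names(res$sweeps$lasso1_mrmr2$table)),
                   sort(c("k", "n_features", "SVR", "RF")))
  rec <- group_recovery(res$winner$subset, ds$truth)
  expect_gte(rec$recovered, 2L)
  # regression best minimizes MSE
  tabs <- res$sweeps[[res$winner$assignment]]$table
  expect_lte(res$winner$score, min(tabs$SVR, na.rm = TRUE))
})

test_that("nested evaluation uses a different fold plan", {
  ds <- generate_synthetic(synthetic_spec(
    n_samples = 40, n_features = 30, n_informative = 2, effect_size = 2,
    seed = 20))
  cfg <- run_config("classification", seed = 0,
                    mrmr = mrmr_config(n_select = 5),
                    nested_evaluation = TRUE)
  res <- suppressMessages(run_profwise(ds$matrix, ds$target, cfg))
  expect_false(identical(res$fold_plan$assignments,
                         res$evaluation_plan$assignments))
})
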