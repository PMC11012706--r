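test_that("stratified folds keep class proportions within one sample", {
  # the 27 methylated : 38 unmethylated composition, plus random imbalances
  set.seed(61)
  compositions <- list(c(27L, 38L))
  for (i in 1:8)
    compositions[[i + 1L]] <- c(sample(10:40, 1), sample(10:60, 1))
  for (comp in compositions) {
    lab <- c(rep("methylated", comp[1]), rep("unmethylated", comp[2]))
    tv <- target_vector(sample(lab))
    plan <- make_folds(tv, 5, seed = 0)
    for (cl in c("methylated", "unmethylated")) {
      n_cl <- sum(tv$values == cl)
      per_fold <- tabulate(plan$assignments[tv$values == cl], 5)
      expect_true(all(abs(per_fold - n_cl / 5) <= 1),
                  info = paste(comp, collapse = ":"))
    }
    # folds partition the samples
    expect_identical(sort(unlist(lapply(1:5, function(i)
      which(plan$assignments == i)))), seq_along(lab))
  }

  # 27:38 with 5 folds: 5-6 positives and 7-8 negatives per fold
  lab <- c(rep("methylated", 27), rep("unmethylated", 38))
  plan <- make_folds(target_vector(lab), 5, seed = 3)
  pos <- tabulate(plan$assignments[1:27], 5)
  neg <- tabulate(plan$assignments[28:65], 5)
  expect_true(all(pos %in% 5:6))
  expect_true(all(neg %in% 7:8))
})

test_that("fold plans are deterministic in the seed and reject tiny classes", {
  tv <- target_vector(rep(c("methylated", "unmethylated"), c(12, 20)))
  p1 <- make_folds(tv, 4, seed = 7)
  p2 <- make_folds(tv, 4, seed = 7)
  p3 <- make_folds(tv, 4, seed = 8)
  expect_identical(p1$assignments, p2$assignments)
  expect_false(identical(p1$assignments, p3$assignments))

  tiny <- target_vector(rep(c("methylated", "unmethylated"), c(3, 20)))
  expect_error(make_folds(tiny, 5), "smaller than n_folds")

  # continuous targets get plain shuffled folds unless strata are given
  cont <- target_vector(rnorm(30))
  expect_false(make_folds(cont, 5)$stratified)
  strat <- make_folds(cont, 5, strata = rep(c("a", "b"), 15))
  expect_true(strat$stratified)
})

test_that("accuracy and MSE match hand-computed values", {
  cases <- list(
    list(c(TP = 27, TN = 38, FP = 0, FN = 0), 1.0),
    list(c(TP = 1, TN = 1, FP = 1, FN = 1), 0.5),
    list(c(TP = 0, TN = 0, FP = 2, FN = 3), 0.0),
    list(c(TP = 50, TN = 30, FP = 10, FN = 10), 0.8),
    list(c(TP = 3, TN = 4, FP = 2, FN = 1), 0.7))
  for (cs in cases) {
    cc <- as.list(cs[[1]])
    expect_identical(accuracy(cc), cs[[2]])
  }
  expect_error(accuracy(list(TP = 0, TN = 0, FP = 0, FN = 0)), "zero")

  expect_identical(mean_squared_error(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_identical(mean_squared_error(c(0, 0), c(1, 1)), 1)
  expect_equal(mean_squared_error(c(1, 2, 3), c(2, 2, 2)), 2 / 3)
  expect_equal(mean_squared_error(c(-1, 1), c(1, -1)), 4)
  expect_equal(mean_squared_error(5, 2.5), 6.25)
  expect_error(mean_squared_error(1:3, 1:2), "lengths differ")

  # counts from labels
  cc <- confusion_counts(c("m", "m", "u", "u"), c("m", "u", "u", "m"),
                         positive = "m")
  expect_identical(cc[c("TP", "FN", "TN", "FP")],
                   list(TP = 1L, FN = 1L, TN = 1L, FP = 1L))
})

test_that("a constant predictor scores at the majority rate of each fold", {
  lab <- rep(c("methylated", "unmethylated"), c(16, 24))
  tv <- target_vector(lab)
  m <- make_em(matrix(3.7, 40, 1))
  plan <- make_folds(tv, 5, seed = 1)
  scores <- evaluate_subset(m, tv, "f01", model_config("classification"),
                            plan)
  expected <- mean(vapply(1:5, function(i) {
    tr <- which(plan$assignments != i)
    te <- which(plan$assignments == i)
    maj <- names(which.max(table(tv$values[tr])))
    mean(tv$values[te] == maj)
  }, 0))
  expect_equal(unname(scores), rep(expected, 5), tolerance = 1e-12)
})

test_that("a separating feature is learned perfectly and deterministically", {
  set.seed(62)
  lab <- rep(c("methylated", "unmethylated"), each = 20)
  v <- rnorm(40, sd = 0.2) + ifelse(lab == "methylated", 5, 0)
  m <- make_em(cbind(sig = v, noise = rnorm(40)))
  tv <- target_vector(lab)
  plan <- make_folds(tv, 5, seed = 0)
  s1 <- evaluate_subset(m, tv, c("sig", "noise"),
                        model_config("classification"), plan)
  expect_identical(unname(s1[c("SVM", "LR")]), c(1, 1))
  s2 <- evaluate_subset(m, tv, c("noise", "sig"),
                        model_config("classification"), plan)
  expect_identical(sort(names(s1)), sort(names(s2)))
  expect_equal(s1[names(s2)], s2)   # feature order within subset irrelevant
})

test_that("mean-of-folds accuracy equals pooled accuracy with equal folds", {
  set.seed(63)
  lab <- rep(c("methylated", "unmethylated"), each = 20)
  tv <- target_vector(lab)
  plan <- make_folds(tv, 4, seed = 0)   # 10 per fold exactly
  m <- make_em(cbind(a = rnorm(40) + 0.8 * (lab == "methylated"),
                     b = rnorm(40)))
  sc <- evaluate_subset(m, tv, c("a", "b"),
                        model_config("classification"), plan,
                        per_fold = TRUE)
  folds <- attr(sc, "folds")
  sizes <- tabulate(plan$assignments, 4)
  expect_true(all(sizes == sizes[1]))
  pooled <- colSums(folds * sizes) / sum(sizes)
  expect_equal(unname(colMeans(folds)), unname(pooled))
})

test_that("alteration analysis flags shifted features and is antisymmetric", {
  set.seed(64)
  lab <- rep(c("methylated", "unmethylated"), each = 15)
  V <- matrix(rnorm(30 * 4, sd = 0.01), 30, 4)
  V[lab == "methylated", 2] <- V[lab == "methylated", 2] + 1.0   # planted
  m <- make_em(V, symbols = c(f02 = "GENE2"))
  tv <- target_vector(lab)
  alt <- alteration_analysis(m, tv, band = 0.3)
  expect_identical(alt$feature_id[1L], "f02")
  expect_identical(alt$rank, 1:4)
  expect_true(alt$flagged[1L])
  expect_false(any(alt$flagged[-1L]))
  expect_identical(alt$gene_symbol[1L], "GENE2")
  expect_equal(alt$diff[1L], alt$mean_pos[1L] - alt$mean_neg[1L])

  # swapping the class convention negates every difference
  tv_neg <- target_vector(lab, positive_label = "unmethylated")
  alt2 <- alteration_analysis(m, tv_neg, band = 0.3)
  alt2 <- alt2[match(alt$feature_id, alt2$feature_id), ]
  expect_equal(alt2$diff, -alt$diff)

  # identical class means: zero diff, not flagged
  flat <- make_em(matrix(rep(c(1, 2), 15 * 2), 30, 2, byrow = FALSE))
  flat$values[, 1] <- 1
  flat$values[, 2] <- rep(c(0, 1), 15)
  altf <- alteration_analysis(flat, tv, band = 0.3)
  expect_equal(altf$diff[altf$feature_id == "f01"], 0)
  expect_false(altf$flagged[altf$feature_id == "f01"])
})
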