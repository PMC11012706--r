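test_that("generation is reproducible and matches the requested shape", {
  spec <- synthetic_spec(n_samples = 40, n_features = 60, n_informative = 4,
                         n_redundant_per_informative = 2, seed = 9)
  a <- generate_synthetic(spec)
  b <- generate_synthetic(spec)
  expect_identical(a$matrix$values, b$matrix$values)
  expect_identical(a$target$values, b$target$values)
  expect_identical(dim(a$matrix), c(40L, 60L))
  expect_length(a$truth$informative, 4L)
  expect_true(all(lengths(a$truth$groups) == 3L))

  # positive fraction within 1/n of the requested ratio
  frac <- mean(a$target$values == "methylated")
  expect_lte(abs(frac - 27 / 65), 1 / 40)

  # copies share their group's gene symbol
  gs <- a$matrix$gene_symbols
  for (g in a$truth$groups)
    expect_length(unique(gs[g]), 1L)

  c_ <- generate_synthetic(synthetic_spec(n_samples = 40, n_features = 60,
                                          seed = 10, n_informative = 4))
  expect_false(identical(a$matrix$values, c_$matrix$values))
})

test_that("redundant copies are correlated at the requested level", {
  spec <- synthetic_spec(n_samples = 400, n_features = 30, n_informative = 3,
                         n_redundant_per_informative = 2,
                         redundancy_rho = 0.8, seed = 5)
  ds <- generate_synthetic(spec)
  for (inf in ds$truth$informative) {
    grp <- ds$truth$groups[[inf]]
    copies <- setdiff(grp, inf)
    for (cp in copies) {
      r <- cor(ds$matrix$values[, inf], ds$matrix$values[, cp])
      expect_gt(r, 0.7)
      expect_lt(r, 0.9)
    }
  }
})

test_that("informative features carry the planted class shift", {
  spec <- synthetic_spec(n_samples = 300, n_features = 50, n_informative = 5,
                         n_redundant_per_informative = 0, effect_size = 1.5,
                         seed = 6)
  ds <- generate_synthetic(spec)
  pos <- ds$target$values == "methylated"
  shifts <- vapply(ds$truth$informative, function(f)
    mean(ds$matrix$values[pos, f]) - mean(ds$matrix$values[!pos, f]), 0)
  expect_true(all(shifts > 1.0))
  noise <- setdiff(feature_ids(ds$matrix), ds$truth$informative)
  nshift <- vapply(noise, function(f)
    mean(ds$matrix$values[pos, f]) - mean(ds$matrix$values[!pos, f]), 0)
  expect_true(all(abs(nshift) < 0.6))
})

test_that("regression targets reflect the planted slopes", {
  spec <- synthetic_spec(n_samples = 200, n_features = 40, n_informative = 3,
                         n_redundant_per_informative = 1, effect_size = 1.5,
                         task = "regression", seed = 7)
  ds <- generate_synthetic(spec)
  expect_identical(ds$target$kind, "continuous")
  fit <- lm(ds$target$values ~ ds$matrix$values[, ds$truth$informative])
  expect_equal(unname(coef(fit)[-1]), rep(1.5, 3), tolerance = 0.15)

  # unknown-status regression carries an auxiliary status vector
  spec2 <- synthetic_spec(n_samples = 60, n_features = 20, n_informative = 2,
                          task = "regression", unknown_fraction = 0.4,
                          seed = 8)
  ds2 <- generate_synthetic(spec2)
  expect_false(is.null(ds2$status))
  expect_identical(sum(ds2$status$unknown_mask), 24L)
})

test_that("rfu_like produces positive intensities inverted by log2", {
  set.seed(12)
  m <- make_em(matrix(rnorm(30), 5, 6))
  r <- rfu_like(m)
  expect_true(all(r$values > 0))
  back <- log2_transform(r)
  expect_equal(back$values, m$values + 10, tolerance = 1e-12)

  # monotone in the input
  ord <- order(m$values)
  expect_identical(order(r$values), ord)
})

test_that("invalid generator specs are rejected", {
  expect_error(synthetic_spec(n_features = 10, n_informative = 5,
                              n_redundant_per_informative = 2),
               "exceed")
  expect_error(synthetic_spec(redundancy_rho = 1.2), "redundancy_rho")
  expect_error(synthetic_spec(class_ratio = 0), "class_ratio")
})
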