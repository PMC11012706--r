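# Independent reference implementations used to cross-check the package.
# These deliberately take the slow literal route (per-pair loops, table()
# contingency counts) and share no code with the package internals.

# equal-frequency bins from average ranks (the estimator's definition)
oracle_bins <- function(x, bins) {
  b <- as.integer(ceiling(bins * rank(x, ties.method = "average") / length(x)))
  b[b < 1L] <- 1L
  b[b > bins] <- bins
  b
}

# mutual information (nats) of two binned vectors via a contingency table
oracle_mi <- function(a, b, la, lb) {
  n <- length(a)
  tab <- table(factor(a, levels = seq_len(la)), factor(b, levels = seq_len(lb)))
  total <- 0
  for (i in seq_len(la)) {
    for (j in seq_len(lb)) {
      pij <- tab[i, j] / n
      if (pij > 0) {
        pi_ <- sum(tab[i, ]) / n
        p_j <- sum(tab[, j]) / n
        total <- total + pij * log(pij / (pi_ * p_j))
      }
    }
  }
  # the estimator's declared tie policy: scores live at 12 significant
  # digits so mathematically equal scores are exactly equal
  signif(max(total, 0), 12L)
}

oracle_f_stat <- function(x, y, continuous) {
  n <- length(x)
  if (continuous) {
    r <- suppressWarnings(stats::cor(x, y))
    if (!is.finite(r)) return(0)
    (n - 2) * r^2 / max(1 - r^2, .Machine$double.eps)
  } else {
    x1 <- x[y == 1]; x0 <- x[y == 0]
    sw <- (sum((x1 - mean(x1))^2) + sum((x0 - mean(x0))^2)) / (n - 2)
    num <- (mean(x1) - mean(x0))^2
    if (sw == 0 && num == 0) return(0)
    num / max(sw * (1 / length(x1) + 1 / length(x0)), .Machine$double.eps)
  }
}

oracle_score_round <- function(x) signif(x, 12L)

# literal greedy mRMR: scans every remaining candidate at every step,
# recomputing relevance and all pairwise redundancies from scratch
oracle_mrmr <- function(X, y, n_select,
                        estimator = c("mutual_information", "f_statistic"),
                        bins = 10L) {
  estimator <- match.arg(estimator)
  ids <- colnames(X)
  p <- ncol(X)
  continuous <- !(length(unique(y)) == 2L && all(y %in% c(0, 1)))
  if (estimator == "mutual_information") {
    yb <- if (continuous) oracle_bins(y, bins) else as.integer(y) + 1L
    ylev <- if (continuous) bins else 2L
    xb <- lapply(seq_len(p), function(j) oracle_bins(X[, j], bins))
    rel <- vapply(seq_len(p), function(j) oracle_mi(yb, xb[[j]], ylev, bins), 0)
    red <- function(a, b) oracle_mi(xb[[a]], xb[[b]], bins, bins)
  } else {
    rel <- oracle_score_round(
      vapply(seq_len(p), function(j) oracle_f_stat(X[, j], y, continuous), 0))
    red <- function(a, b) {
      r <- suppressWarnings(abs(stats::cor(X[, a], X[, b])))
      oracle_score_round(if (!is.finite(r)) 0 else r)
    }
  }
  chosen <- integer(0)
  for (step in seq_len(n_select)) {
    best_j <- NA_integer_
    best_score <- -Inf
    for (j in setdiff(seq_len(p), chosen)) {
      score <- rel[j]
      if (length(chosen)) {
        acc <- 0
        for (s in chosen) acc <- acc + red(s, j)
        score <- score - acc / length(chosen)
      }
      if (score > best_score ||
          (score == best_score && ids[j] < ids[best_j])) {
        best_score <- score
        best_j <- j
      }
    }
    chosen <- c(chosen, best_j)
  }
  ids[chosen]
}

# brute-force best cell of a sweep table: enumerate all (k, model) cells
# and sort on the full tie-break key
oracle_best_cell <- function(tab, model_names, maximize) {
  cell_key <- function(score, n_features, k, model)
    c(if (maximize) -score else score, n_features, k,
      match(model, model_names))
  lex_less <- function(a, b) {
    d <- which(a != b)
    length(d) > 0L && a[d[1L]] < b[d[1L]]
  }
  best <- NULL
  for (mn in model_names) {
    for (r in seq_len(nrow(tab))) {
      s <- tab[[mn]][r]
      if (is.na(s)) next
      cand <- list(k = tab$k[r], n_features = tab$n_features[r],
                   model = mn, score = s)
      if (is.null(best) ||
          lex_less(cell_key(s, cand$n_features, cand$k, mn),
                   cell_key(best$score, best$n_features, best$k,
                            best$model)))
        best <- cand
    }
  }
  best
}

# small labelled expression matrix from a plain matrix
make_em <- function(V, symbols = NULL) {
  if (is.null(rownames(V))) rownames(V) <- sprintf("s%02d", seq_len(nrow(V)))
  if (is.null(colnames(V))) colnames(V) <- sprintf("f%02d", seq_len(ncol(V)))
  expr_matrix(V, symbols)
}

# random per-fold selection lists over a feature universe
random_per_fold <- function(n_folds, universe, max_pick) {
  lapply(seq_len(n_folds), function(i)
    list(lasso = sample(universe, sample.int(max_pick, 1L)),
         mrmr = sample(universe, sample.int(max_pick, 1L))))
}
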