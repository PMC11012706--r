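#' mRMR selector configuration
#'
#' @param n_select number of features to rank per fold (default 50).
#' @param relevance_estimator `"mutual_information"` (default): relevance and
#'   redundancy are mutual information, with continuous variables
#'   discretized into `mi_bins` equal-frequency bins (a binary target is
#'   used as-is); or `"f_statistic"`: relevance is the one-way ANOVA F
#'   statistic (binary target) / univariate regression F (continuous
#'   target), redundancy the absolute Pearson correlation — faster, and the
#'   classic "FCD"-style variant.
#' @param mi_bins bins for equal-frequency discretization (default 10).
#' @return an object of class `mrmr_config`.
#' @export
mrmr_config <- function(n_select = 50L,
                        relevance_estimator = c("mutual_information",
                                                "f_statistic"),
                        mi_bins = 10L) {
  relevance_estimator <- match.arg(relevance_estimator)
  n_select <- as.integer(n_select)
  mi_bins <- as.integer(mi_bins)
  stopifnot(n_select >= 1L, mi_bins >= 2L)
  structure(list(n_select = n_select,
                 relevance_estimator = relevance_estimator,
                 mi_bins = mi_bins),
            class = "mrmr_config")
}

# Equal-frequency discretization into B bins via average ranks; a constant
# vector collapses to a single bin (so its MI with anything is exactly 0).
discretize_ef <- function(x, bins) {
  n <- length(x)
  b <- ceiling(bins * rank(x, ties.method = "average") / n)
  pmin(pmax(as.integer(b), 1L), bins)
}

# Scores are rounded to 12 significant digits: mathematically equal scores
# (e.g. two features with identical contingency tables) must compare equal
# regardless of floating-point summation order, so that the lexicographic
# tie rule — not last-bit noise — decides ties.
score_round <- function(x) signif(x, 12L)

# Mutual information (nats) between one binned vector and every column of a
# binned matrix, via one-hot cross products: joint counts N[br, bc] per
# column, MI = sum p * log(p / (pr * pc)).
mi_vs_all <- function(ref_bins, bin_mat, ref_levels, col_levels) {
  n <- length(ref_bins)
  stopifnot(nrow(bin_mat) == n)
  ind_ref <- matrix(0, n, ref_levels)
  ind_ref[cbind(seq_len(n), ref_bins)] <- 1
  pr <- colSums(ind_ref) / n
  mi <- numeric(ncol(bin_mat))
  for (bc in seq_len(col_levels)) {
    v <- bin_mat == bc
    pc <- colSums(v) / n                       # per-column marginal of bin bc
    nj <- crossprod(ind_ref, v) / n            # ref_levels x p joint probs
    ratio <- nj / outer(pr, pc)
    term <- nj * log(ratio)
    term[nj == 0] <- 0
    mi <- mi + colSums(term)
  }
  score_round(pmax(mi, 0))
}

# F statistic of each column against y: one-way ANOVA for a binary 0/1 y,
# univariate regression F for continuous y. Zero-variance columns get 0.
f_stat_relevance <- function(X, y01, continuous) {
  n <- nrow(X)
  if (continuous) {
    r <- suppressWarnings(stats::cor(X, y01))
    r[!is.finite(r)] <- 0
    f <- (n - 2) * r^2 / pmax(1 - r^2, .Machine$double.eps)
  } else {
    n1 <- sum(y01 == 1); n0 <- sum(y01 == 0)
    m1 <- colMeans(X[y01 == 1, , drop = FALSE])
    m0 <- colMeans(X[y01 == 0, , drop = FALSE])
    ss1 <- colSums(scale(X[y01 == 1, , drop = FALSE], center = m1,
                         scale = FALSE)^2)
    ss0 <- colSums(scale(X[y01 == 0, , drop = FALSE], center = m0,
                         scale = FALSE)^2)
    sw <- (ss1 + ss0) / (n - 2)
    f <- (m1 - m0)^2 / pmax(sw * (1 / n1 + 1 / n0), .Machine$double.eps)
    f[sw == 0 & (m1 - m0) == 0] <- 0
  }
  score_round(as.numeric(f))
}

#' Greedy minimum-redundancy maximum-relevance feature ranking
#'
#' Ranks features by the mRMR criterion: the first pick maximizes relevance
#' to the target; each subsequent pick maximizes
#' \deqn{I(Y, X_i) - \frac{1}{|S|} \sum_{X_s \in S} I(X_s, X_i)}
#' over features \eqn{X_i} not yet in the selected set \eqn{S}. Ties in the
#' score are broken by ascending feature-ID lexicographic order, so the
#' ranking is deterministic. Zero-variance features have zero relevance and
#' are never an error.
#'
#' @param X numeric matrix (training rows only) with feature IDs as
#'   colnames, or an [expr_matrix].
#' @param y a [target_vector] without unknowns among the supplied rows, or a
#'   plain numeric/factor vector.
#' @param cfg an [mrmr_config].
#' @return character vector of exactly `n_select` feature IDs in selection
#'   order.
#' @export
mrmr_rank <- function(X, y, cfg = mrmr_config()) {
  if (inherits(X, "expr_matrix")) X <- X$values
  stopifnot(is.matrix(X), !is.null(colnames(X)))
  ids <- colnames(X)
  p <- ncol(X)
  if (cfg$n_select > p)
    stop(sprintf("n_select (%d) exceeds the number of features (%d)",
                 cfg$n_select, p), call. = FALSE)
  yb <- coerce_selector_target(y, nrow(X))
  continuous <- yb$continuous

  if (cfg$relevance_estimator == "mutual_information") {
    B <- cfg$mi_bins
    D <- apply(X, 2L, discretize_ef, bins = B)
    if (continuous) {
      ybins <- discretize_ef(yb$y, B); ylev <- B
    } else {
      ybins <- yb$y + 1L; ylev <- 2L
    }
    relevance <- mi_vs_all(ybins, D, ylev, B)
    redundancy_vs_all <- function(j) mi_vs_all(D[, j], D, B, B)
  } else {
    relevance <- f_stat_relevance(X, yb$y, continuous)
    redundancy_vs_all <- function(j) {
      r <- suppressWarnings(abs(stats::cor(X, X[, j])))
      r[!is.finite(r)] <- 0
      score_round(as.numeric(r))
    }
  }

  selected <- integer(0)
  cum_red <- numeric(p)
  available <- rep(TRUE, p)
  for (step in seq_len(cfg$n_select)) {
    score <- if (length(selected)) relevance - cum_red / length(selected)
             else relevance
    score[!available] <- -Inf
    best <- which(score == max(score))
    if (length(best) > 1L) best <- best[order(ids[best])][1L]
    selected <- c(selected, best)
    available[best] <- FALSE
    if (step < cfg$n_select) cum_red <- cum_red + redundancy_vs_all(best)
  }
  ids[selected]
}

# Accepts a target_vector, factor, character or numeric vector and returns
# list(y = 0/1 integer or numeric, continuous = flag).
coerce_selector_target <- function(y, n) {
  if (inherits(y, "target_vector")) {
    if (length(y) != n)
      stop("target length does not match the number of rows", call. = FALSE)
    if (y$kind == "binary") {
      if (any(y$unknown_mask))
        stop("selector targets must not contain unknown labels", call. = FALSE)
      return(list(y = target_binary01(y), continuous = FALSE))
    }
    return(list(y = y$values, continuous = TRUE))
  }
  if (is.factor(y) || is.character(y)) {
    f <- factor(y)
    if (nlevels(f) != 2L)
      stop("factor target must have exactly 2 levels", call. = FALSE)
    return(list(y = as.integer(f) - 1L, continuous = FALSE))
  }
  stopifnot(is.numeric(y), length(y) == n)
  if (length(unique(y)) == 2L && all(y %in% c(0, 1)))
    return(list(y = as.integer(y), continuous = FALSE))
  list(y = y, continuous = TRUE)
}
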