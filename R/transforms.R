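#' Log2-transform positive expression values
#'
#' Raw aptamer intensities (relative fluorescence units) arrive normalized
#' but with high variance; a base-2 logarithm stabilizes them before feature
#' selection. All values must be strictly positive.
#'
#' @param m an [expr_matrix] of strictly positive values.
#' @return an [expr_matrix] of the same shape with `log2` applied cell-wise.
#' @export
log2_transform <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  bad <- which(m$values <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("log2_transform requires strictly positive values; first offender at sample '%s', feature '%s' (value %g)",
                 sample_ids(m)[bad[1L, 1L]], feature_ids(m)[bad[1L, 2L]],
                 m$values[bad[1L, , drop = FALSE]]), call. = FALSE)
  }
  out <- m
  out$values <- log2(m$values)
  out
}

#' Z-score normalize each feature
#'
#' Centers and scales every feature to mean 0 and sample standard deviation
#' 1 (denominator n-1), the usual preprocessing for already-summarized
#' tissue proteomics. Constant features cannot be scaled and are dropped
#' with a warning; mRMR and LASSO would treat them as uninformative anyway.
#'
#' @param m an [expr_matrix].
#' @return an [expr_matrix], possibly with fewer features.
#' @export
zscore_normalize <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  sds <- apply(m$values, 2L, stats::sd)
  const <- sds == 0 | !is.finite(sds)
  v <- m$values
  if (any(const)) {
    warning(sprintf("dropping %d constant feature(s): %s", sum(const),
                    paste(utils::head(feature_ids(m)[const], 5L),
                          collapse = ", ")), call. = FALSE)
    v <- v[, !const, drop = FALSE]
    sds <- sds[!const]
  }
  if (!ncol(v)) stop("all features are constant", call. = FALSE)
  v <- scale(v, center = TRUE, scale = sds)
  attr(v, "scaled:center") <- NULL
  attr(v, "scaled:scale") <- NULL
  gs <- m$gene_symbols
  if (!is.null(gs)) gs <- gs[names(gs) %in% colnames(v)]
  if (!is.null(gs) && !length(gs)) gs <- NULL
  expr_matrix(v, gs)
}

#' Remove the predicted protein from the predictor set
#'
#' When regressing a protein's own expression on the panel, that marker
#' must not sit among the predictors (e.g. 7289 panel features become 7288
#' predictors when one marker is the regression target).
#'
#' @param m an [expr_matrix].
#' @param feature_id marker to remove; must be present.
#' @return an [expr_matrix] with `n_features` reduced by one.
#' @export
exclude_target_feature <- function(m, feature_id) {
  stopifnot(inherits(m, "expr_matrix"), is.character(feature_id),
            length(feature_id) == 1L)
  if (!feature_id %in% feature_ids(m))
    stop("feature '", feature_id, "' not present in the matrix", call. = FALSE)
  keep <- setdiff(feature_ids(m), feature_id)
  subset_matrix(m, features = keep)
}

#' Apply a named preprocessing preset
#'
#' `"log2_rfu"` log2-transforms positive RFU-like intensities (serum panel
#' regime); `"zscore"` z-scores each feature (tissue/CPTAC regime); `"none"`
#' passes the matrix through.
#'
#' @param m an [expr_matrix].
#' @param preset one of `"log2_rfu"`, `"zscore"`, `"none"`.
#' @return an [expr_matrix].
#' @export
preprocess_matrix <- function(m, preset = c("none", "log2_rfu", "zscore")) {
  preset <- match.arg(preset)
  switch(preset,
         none = m,
         log2_rfu = log2_transform(m),
         zscore = zscore_normalize(m))
}
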