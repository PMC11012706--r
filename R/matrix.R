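#' Expression matrix container
#'
#' A thin validated wrapper around a samples x features numeric matrix, as
#' produced by large proteomic panels (e.g. aptamer-based serum assays):
#' rows are patients, columns are protein markers identified by a marker ID
#' (SeqId-like), optionally mapped to Entrez-style gene symbols.
#'
#' @param values numeric matrix, `n_samples x n_features`, with unique
#'   rownames (sample IDs) and unique colnames (feature/marker IDs). All
#'   values must be finite.
#' @param gene_symbols optional named character vector mapping feature IDs to
#'   gene symbols. The map may cover only a subset of features and need not
#'   be injective (several aptamers can target the same protein).
#' @return An object of class `expr_matrix`.
#' @examples
#' m <- expr_matrix(matrix(1:6, 3, 2,
#'   dimnames = list(c("s1", "s2", "s3"), c("f1", "f2"))))
#' dim(m)
#' @export
expr_matrix <- function(values, gene_symbols = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  sid <- rownames(values)
  fid <- colnames(values)
  if (is.null(sid) || is.null(fid))
    stop("'values' must carry sample IDs as rownames and feature IDs as colnames",
         call. = FALSE)
  dup <- unique(sid[duplicated(sid)])
  if (length(dup))
    stop("duplicated sample IDs: ", paste(dup, collapse = ", "), call. = FALSE)
  dup <- unique(fid[duplicated(fid)])
  if (length(dup))
    stop("duplicated feature IDs: ", paste(dup, collapse = ", "), call. = FALSE)
  if (anyNA(values) || any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite value at sample '%s', feature '%s'",
                 sid[bad[1L]], fid[bad[2L]]), call. = FALSE)
  }
  if (!is.null(gene_symbols)) {
    if (is.null(names(gene_symbols)) || !is.character(gene_symbols))
      stop("'gene_symbols' must be a named character vector", call. = FALSE)
    unknown <- setdiff(names(gene_symbols), fid)
    if (length(unknown))
      stop("gene_symbols maps unknown feature IDs: ",
           paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
  }
  structure(list(values = values, gene_symbols = gene_symbols),
            class = "expr_matrix")
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Sample and feature IDs of an expression matrix
#' @param m an `expr_matrix`
#' @return character vector of IDs.
#' @export
sample_ids <- function(m) rownames(m$values)

#' @rdname sample_ids
#' @export
feature_ids <- function(m) colnames(m$values)

#' @method print expr_matrix
#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d samples x %d features\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$gene_symbols))
    cat(sprintf("  gene symbols for %d features\n", length(x$gene_symbols)))
  invisible(x)
}

#' Restrict an expression matrix to a subset of samples and/or features
#'
#' @param m an `expr_matrix`
#' @param samples sample IDs or indices (default: all)
#' @param features feature IDs or indices (default: all)
#' @return An `expr_matrix` with the requested rows/columns, gene-symbol map
#'   trimmed accordingly.
#' @export
subset_matrix <- function(m, samples = NULL, features = NULL) {
  stopifnot(inherits(m, "expr_matrix"))
  v <- m$values
  if (!is.null(samples)) {
    if (is.character(samples)) {
      miss <- setdiff(samples, rownames(v))
      if (length(miss))
        stop("unknown sample IDs: ", paste(miss, collapse = ", "), call. = FALSE)
    }
    v <- v[samples, , drop = FALSE]
  }
  if (!is.null(features)) {
    if (is.character(features)) {
      miss <- setdiff(features, colnames(v))
      if (length(miss))
        stop("unknown feature IDs: ", paste(miss, collapse = ", "), call. = FALSE)
    }
    v <- v[, features, drop = FALSE]
  }
  gs <- m$gene_symbols
  if (!is.null(gs)) gs <- gs[names(gs) %in% colnames(v)]
  if (!is.null(gs) && !length(gs)) gs <- NULL
  expr_matrix(v, gs)
}

#' Target vector paired with an expression matrix
#'
#' Binary targets hold a class label per sample (e.g. MGMT promoter
#' methylation: "methylated"/"unmethylated") with an `unknown_mask` for
#' samples of unknown status; continuous targets hold a real value per
#' sample (e.g. MGMT protein expression).
#'
#' @param values character/factor vector (binary) or numeric vector
#'   (continuous); `NA`, empty strings and the literal "unknown"
#'   (case-insensitive) mark unknown status for binary targets.
#' @param kind `"binary"`, `"continuous"`, or `"auto"` (binary when `values`
#'   is non-numeric with at most 3 distinct levels including unknowns).
#' @param positive_label class treated as positive; default `"methylated"`.
#'   Matched case-insensitively; if absent from the levels, the
#'   lexicographically first level is used as positive with a warning.
#' @return An object of class `target_vector` with fields `kind`, `values`,
#'   `positive_label`, `negative_label` (binary only) and `unknown_mask`.
#' @export
target_vector <- function(values, kind = c("auto", "binary", "continuous"),
                          positive_label = "methylated") {
  kind <- match.arg(kind)
  if (kind == "auto")
    kind <- if (is.numeric(values)) "continuous" else {
      lv <- tolower(trimws(as.character(values)))
      unk <- is.na(lv) | lv == "" | lv == "unknown"
      # binary when at most 3 distinct levels including the unknown marker
      if (length(unique(lv[!unk])) + any(unk) <= 3L) "binary"
      else "continuous"
    }
  if (kind == "continuous") {
    vals <- suppressWarnings(as.numeric(values))
    if (anyNA(vals) && !anyNA(values))
      stop("target is neither binary (at most 2 levels plus unknown) ",
           "nor numeric", call. = FALSE)
    if (any(!is.finite(vals[!is.na(vals)])))
      stop("continuous target contains non-finite values", call. = FALSE)
    if (anyNA(vals))
      stop("continuous target contains missing values", call. = FALSE)
    out <- list(kind = "continuous", values = vals,
                positive_label = NULL, negative_label = NULL,
                unknown_mask = rep(FALSE, length(vals)))
  } else {
    raw <- trimws(as.character(values))
    unk <- is.na(raw) | raw == "" | tolower(raw) == "unknown"
    lab <- tolower(raw)
    lab[unk] <- NA_character_
    levels <- sort(unique(lab[!unk]))
    if (length(levels) != 2L)
      stop(sprintf("binary target must have exactly 2 non-unknown levels, got %d (%s)",
                   length(levels), paste(levels, collapse = ", ")), call. = FALSE)
    pos <- tolower(positive_label)
    if (!pos %in% levels) {
      pos <- levels[1L]
      warning(sprintf("positive label '%s' not found; using '%s' as positive class",
                      positive_label, pos), call. = FALSE)
    }
    out <- list(kind = "binary", values = lab,
                positive_label = pos,
                negative_label = setdiff(levels, pos),
                unknown_mask = unk)
  }
  structure(out, class = "target_vector")
}

#' @export
length.target_vector <- function(x) length(x$values)

#' @method print target_vector
#' @export
print.target_vector <- function(x, ...) {
  if (x$kind == "binary") {
    cat(sprintf("<target_vector> binary: %d %s (+), %d %s (-), %d unknown\n",
                sum(x$values == x$positive_label, na.rm = TRUE), x$positive_label,
                sum(x$values == x$negative_label, na.rm = TRUE), x$negative_label,
                sum(x$unknown_mask)))
  } else {
    cat(sprintf("<target_vector> continuous: n=%d, mean=%.3f, sd=%.3f\n",
                length(x$values), mean(x$values), stats::sd(x$values)))
  }
  invisible(x)
}

#' Subset a target vector by sample index
#' @param tv a `target_vector`
#' @param idx integer or logical index
#' @return a `target_vector` over the selected samples.
#' @export
subset_target <- function(tv, idx) {
  stopifnot(inherits(tv, "target_vector"))
  out <- tv
  out$values <- tv$values[idx]
  out$unknown_mask <- tv$unknown_mask[idx]
  out
}

# 0/1 coding of a binary target (positive class = 1); unknowns propagate NA
target_binary01 <- function(tv) {
  stopifnot(tv$kind == "binary")
  as.integer(tv$values == tv$positive_label)
}

# factor with the negative class first, positive second, unknowns NA
target_factor <- function(tv) {
  stopifnot(tv$kind == "binary")
  factor(tv$values, levels = c(tv$negative_label, tv$positive_label))
}
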