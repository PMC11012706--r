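#' Read an expression matrix (and optional target column) from CSV/TSV
#'
#' Expects a wide delimited table: one ID column plus one column per feature
#' (or, with `layout = "samples_in_cols"`, one column per sample). The
#' delimiter is auto-detected from the file extension (`.csv` vs
#' `.tsv`/`.tab`/`.txt`). Missing or non-numeric cells in the value block are
#' hard errors with coordinates: silent imputation could change downstream
#' feature selection invisibly.
#'
#' @param path path to a CSV or TSV file.
#' @param layout `"samples_in_rows"` (default: rows are samples, columns are
#'   features) or `"samples_in_cols"`.
#' @param target_column name of a column (a per-sample variable) to split out
#'   as the target; typed binary when it has at most 3 distinct string levels
#'   including "unknown", continuous otherwise.
#' @param positive_label positive class for a binary target.
#' @param gene_symbols optional path to a two-column TSV (feature ID, symbol)
#'   or a named character vector.
#' @return a list with elements `matrix` (an [expr_matrix]) and `target`
#'   (a [target_vector] or `NULL`).
#' @export
load_matrix <- function(path,
                        layout = c("samples_in_rows", "samples_in_cols"),
                        target_column = NULL,
                        positive_label = "methylated",
                        gene_symbols = NULL) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", comment.char = "")
  if (ncol(raw) < 2L)
    stop("expected an ID column plus at least one data column in ", path,
         call. = FALSE)
  hdr <- colnames(raw)[-1L]
  dup <- unique(hdr[duplicated(hdr)])
  if (length(dup))
    stop("duplicated column names in ", path, ": ",
         paste(dup, collapse = ", "), call. = FALSE)
  ids <- raw[[1L]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicated row IDs in ", path, ": ",
         paste(dup, collapse = ", "), call. = FALSE)

  target <- NULL
  if (!is.null(target_column)) {
    if (layout != "samples_in_rows")
      stop("a target column requires layout = 'samples_in_rows'", call. = FALSE)
    if (!target_column %in% hdr)
      stop("target column '", target_column, "' not found in ", path,
           call. = FALSE)
    target <- target_vector(raw[[target_column]],
                            positive_label = positive_label)
    raw[[target_column]] <- NULL
    hdr <- setdiff(hdr, target_column)
  }

  block <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(block), dim = dim(block)))
  bad <- is.na(num)
  if (any(bad)) {
    at <- which(bad, arr.ind = TRUE)[1L, ]
    cell <- block[at[1L], at[2L]]
    what <- if (is.na(cell) || cell == "") "missing value" else
      sprintf("non-numeric value '%s'", cell)
    stop(sprintf("%s at row '%s', column '%s' in %s",
                 what, ids[at[1L]], hdr[at[2L]], path), call. = FALSE)
  }
  dimnames(num) <- list(ids, hdr)
  if (layout == "samples_in_cols") num <- t(num)

  if (is.character(gene_symbols) && length(gene_symbols) == 1L &&
      is.null(names(gene_symbols))) {
    gene_symbols <- read_gene_symbols(gene_symbols)
  }
  if (!is.null(gene_symbols))
    gene_symbols <- gene_symbols[names(gene_symbols) %in% colnames(num)]
  if (!length(gene_symbols)) gene_symbols <- NULL

  list(matrix = expr_matrix(num, gene_symbols), target = target)
}

#' Read a feature-to-gene-symbol map from a two-column TSV
#'
#' @param path TSV with feature ID in column 1 and gene symbol in column 2;
#'   a header line is tolerated and skipped when it does not look like data.
#' @return named character vector (feature ID -> symbol).
#' @export
read_gene_symbols <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(tab) < 2L) stop("symbol map needs two columns: ", path, call. = FALSE)
  stats::setNames(tab[[2L]], tab[[1L]])
}

#' Write an expression matrix (and optional target column) to CSV/TSV
#'
#' Inverse of [load_matrix()] for the `samples_in_rows` layout; numeric
#' values are written with full double precision so a load/write round trip
#' reproduces the numeric block exactly.
#'
#' @param m an [expr_matrix].
#' @param path output path; `.csv` writes comma-separated, anything else tab.
#' @param target optional [target_vector] written as an extra column.
#' @param target_column name for the target column (default `"target"`).
#' @param id_column name for the leading sample-ID column.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, target = NULL, target_column = "target",
                         id_column = "sample_id") {
  stopifnot(inherits(m, "expr_matrix"))
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  df <- data.frame(sample_ids(m), stringsAsFactors = FALSE,
                   check.names = FALSE)
  colnames(df) <- id_column
  if (!is.null(target)) {
    stopifnot(inherits(target, "target_vector"),
              length(target) == nrow(m$values))
    col <- if (target$kind == "binary") {
      v <- target$values
      v[target$unknown_mask] <- "unknown"
      v
    } else {
      format_num(target$values)
    }
    df[[target_column]] <- col
  }
  vals <- apply(m$values, 2L, format_num)
  if (nrow(m$values) == 1L) vals <- matrix(vals, nrow = 1L)
  colnames(vals) <- feature_ids(m)
  df <- cbind(df, as.data.frame(vals, stringsAsFactors = FALSE,
                                check.names = FALSE))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

# shortest decimal strings that round-trip doubles exactly
format_num <- function(x) formatC(x, format = "g", digits = 17, width = 1)
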