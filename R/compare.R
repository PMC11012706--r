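#' Intersect winner feature lists across runs
#'
#' Reads 2–4 run reports (a report directory or its `winner.json`) and
#' computes pairwise and overall intersections of the winning feature
#' lists, both by feature ID and — separately — by gene symbol (several
#' markers can share a symbol, so the symbol-level intersection can be
#' larger than the ID-level one).
#'
#' @param paths character vector of 2 to 4 report directories or
#'   `winner.json` paths; names, if given, label the runs.
#' @return list with `runs` (feature/symbol lists), `pairs` (data.frame of
#'   pairwise intersection counts), `overall` (list with `ids`,
#'   `symbols`), printed compactly.
#' @export
compare_runs <- function(paths) {
  if (length(paths) < 2L || length(paths) > 4L)
    stop("compare_runs takes between 2 and 4 reports", call. = FALSE)
  labels <- names(paths) %||% paste0("run", seq_along(paths))
  labels[labels == ""] <- paste0("run", which(labels == ""))
  runs <- lapply(paths, read_winner)
  names(runs) <- labels

  combos <- utils::combn(length(runs), 2L)
  pairs <- data.frame(
    run_a = labels[combos[1L, ]], run_b = labels[combos[2L, ]],
    shared_ids = apply(combos, 2L, function(ij)
      length(intersect(runs[[ij[1L]]]$features, runs[[ij[2L]]]$features))),
    shared_symbols = apply(combos, 2L, function(ij)
      length(intersect(runs[[ij[1L]]]$symbols, runs[[ij[2L]]]$symbols))),
    stringsAsFactors = FALSE)

  overall_ids <- Reduce(intersect, lapply(runs, `[[`, "features"))
  overall_symbols <- Reduce(intersect, lapply(runs, `[[`, "symbols"))
  structure(list(runs = runs, pairs = pairs,
                 overall = list(ids = sort(overall_ids),
                                symbols = sort(overall_symbols))),
            class = "run_comparison")
}

read_winner <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "winner.json")
  if (!file.exists(path)) stop("no winner report at ", path, call. = FALSE)
  w <- jsonlite::read_json(path, simplifyVector = TRUE)
  feats <- as.character(w$features %||% character(0))
  syms <- as.character(w$gene_symbols %||% character(0))
  syms <- syms[!is.na(syms) & syms != ""]
  list(features = feats, symbols = unique(syms), task = w$task %||% NA)
}

#' @method print run_comparison
#' @export
print.run_comparison <- function(x, ...) {
  cat(sprintf("<run_comparison> %d runs\n", length(x$runs)))
  for (nm in names(x$runs))
    cat(sprintf("  %s: %d features, %d symbols\n", nm,
                length(x$runs[[nm]]$features), length(x$runs[[nm]]$symbols)))
  print(x$pairs, row.names = FALSE)
  cat(sprintf("  overall: %d shared IDs, %d shared symbols\n",
              length(x$overall$ids), length(x$overall$symbols)))
  invisible(x)
}

#' Write a run comparison as TSV files
#'
#' @param cmp a `run_comparison` from [compare_runs()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_comparison <- function(cmp, dir) {
  stopifnot(inherits(cmp, "run_comparison"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(cmp$pairs, file.path(dir, "pairwise_intersections.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  memb <- data.frame(
    level = rep(c("id", "symbol"),
                c(length(cmp$overall$ids), length(cmp$overall$symbols))),
    member = c(cmp$overall$ids, cmp$overall$symbols),
    stringsAsFactors = FALSE)
  utils::write.table(memb, file.path(dir, "overall_intersection.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
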