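#' Specification for a synthetic proteomic dataset
#'
#' Emulates the shape of serum/tissue proteomic panels used for
#' methylation-status classification and protein-expression regression:
#' mostly Gaussian noise markers, a small planted informative set, each
#' informative marker accompanied by correlated redundant copies (multiple
#' aptamers per protein, sharing a gene symbol), mild class imbalance, and
#' optionally a fraction of samples with unknown status.
#'
#' @param n_samples number of samples (default 100).
#' @param n_features number of markers (default 1000).
#' @param n_informative number of truly informative markers (default 10).
#' @param n_redundant_per_informative correlated copies per informative
#'   marker (default 2).
#' @param redundancy_rho correlation of each copy with its informative
#'   marker, in (0, 1) (default 0.8).
#' @param effect_size class mean shift (classification) or per-marker
#'   regression slope, in sd units (default 1.5).
#' @param class_ratio positive-class fraction (default 27/65, the mild
#'   methylated:unmethylated imbalance typical of such cohorts).
#' @param noise_sd standard deviation of noise markers and of the residual
#'   target noise (default 1).
#' @param unknown_fraction fraction of statuses masked as unknown
#'   (default 0).
#' @param task `"classification"` or `"regression"`.
#' @param seed RNG seed (default 0).
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples = 100L, n_features = 1000L,
                           n_informative = 10L,
                           n_redundant_per_informative = 2L,
                           redundancy_rho = 0.8, effect_size = 1.5,
                           class_ratio = 27 / 65, noise_sd = 1,
                           unknown_fraction = 0,
                           task = c("classification", "regression"),
                           seed = 0L) {
  task <- match.arg(task)
  spec <- list(n_samples = as.integer(n_samples),
               n_features = as.integer(n_features),
               n_informative = as.integer(n_informative),
               n_redundant_per_informative =
                 as.integer(n_redundant_per_informative),
               redundancy_rho = redundancy_rho, effect_size = effect_size,
               class_ratio = class_ratio, noise_sd = noise_sd,
               unknown_fraction = unknown_fraction, task = task,
               seed = as.integer(seed))
  with(spec, {
    stopifnot(n_samples >= 4L, n_features >= 1L, n_informative >= 0L,
              n_redundant_per_informative >= 0L,
              redundancy_rho > 0, redundancy_rho < 1,
              class_ratio > 0, class_ratio < 1, noise_sd > 0,
              unknown_fraction >= 0, unknown_fraction < 1)
    if (n_informative * (1L + n_redundant_per_informative) > n_features)
      stop("informative markers plus copies exceed n_features", call. = FALSE)
  })
  structure(spec, class = "synthetic_spec")
}

#' Generate a synthetic proteomic dataset with known ground truth
#'
#' Noise markers are i.i.d. Gaussian. Informative markers are Gaussian with
#' a between-class mean shift of `effect_size` (classification) or
#' contribute slope `effect_size` to a Gaussian-noise target (regression).
#' Each informative marker gets `n_redundant_per_informative` copies
#' correlated with it at `redundancy_rho`; group members share a gene
#' symbol. Marker positions are shuffled. Fully reproducible from the seed.
#'
#' @param spec a [synthetic_spec].
#' @return list with `matrix` (an [expr_matrix]), `target` (a
#'   [target_vector]), `truth` (list: `informative` IDs and `groups`, a
#'   named list mapping each informative ID to itself plus its copies), and
#'   `status` (for regression with `unknown_fraction > 0`: a binary
#'   [target_vector] with unknowns, else `NULL`).
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_samples; p <- spec$n_features
  ni <- spec$n_informative; nc <- spec$n_redundant_per_informative
  with_seed(spec$seed, {
    n_pos <- max(1L, min(n - 1L, round(spec$class_ratio * n)))
    y01 <- integer(n)
    y01[sample.int(n, n_pos)] <- 1L

    V <- matrix(stats::rnorm(n * p, sd = spec$noise_sd), n, p)
    roles <- rep("noise", p)
    group_of <- integer(p)
    slot <- 1L
    for (g in seq_len(ni)) {
      base <- stats::rnorm(n)
      if (spec$task == "classification")
        base <- base + spec$effect_size * y01
      V[, slot] <- base
      roles[slot] <- "informative"; group_of[slot] <- g
      slot <- slot + 1L
      for (cpy in seq_len(nc)) {
        V[, slot] <- spec$redundancy_rho * base +
          sqrt(1 - spec$redundancy_rho^2) * stats::rnorm(n)
        roles[slot] <- "copy"; group_of[slot] <- g
        slot <- slot + 1L
      }
    }
    perm <- sample.int(p)
    V <- V[, perm, drop = FALSE]
    roles <- roles[perm]; group_of <- group_of[perm]

    fid <- sprintf("M%05d", seq_len(p))
    sid <- sprintf("S%03d", seq_len(n))
    dimnames(V) <- list(sid, fid)
    grouped <- group_of > 0L
    symbols <- stats::setNames(sprintf("SYM%03d", group_of[grouped]),
                               fid[grouped])

    informative <- fid[roles == "informative"]
    groups <- lapply(which(roles == "informative"), function(j)
      fid[group_of == group_of[j]])
    names(groups) <- informative

    status <- NULL
    if (spec$task == "classification") {
      lab <- ifelse(y01 == 1L, "methylated", "unmethylated")
      if (spec$unknown_fraction > 0) {
        n_unk <- floor(spec$unknown_fraction * n)
        lab[sample.int(n, n_unk)] <- "unknown"
      }
      target <- target_vector(lab, kind = "binary",
                              positive_label = "methylated")
    } else {
      inf_idx <- which(roles == "informative")
      yc <- as.numeric(V[, inf_idx, drop = FALSE] %*%
                         rep(spec$effect_size, length(inf_idx))) +
        stats::rnorm(n, sd = spec$noise_sd)
      target <- target_vector(yc, kind = "continuous")
      if (spec$unknown_fraction > 0) {
        lab <- ifelse(y01 == 1L, "methylated", "unmethylated")
        n_unk <- floor(spec$unknown_fraction * n)
        lab[sample.int(n, n_unk)] <- "unknown"
        status <- target_vector(lab, kind = "binary",
                                positive_label = "methylated")
      }
    }
    list(matrix = expr_matrix(V, symbols), target = target,
         truth = list(informative = informative, groups = groups),
         status = status)
  })
}

#' Map z-scale values onto a positive RFU-like intensity scale
#'
#' Applies `2^(x + offset)`, producing strictly positive intensities whose
#' [log2_transform()] recovers the input plus the constant offset — so the
#' log2 preprocessing preset can be exercised on synthetic data.
#'
#' @param m an [expr_matrix].
#' @param offset constant added before exponentiation (default 10, giving
#'   intensities around 2^10, a plausible fluorescence scale).
#' @return an [expr_matrix] of positive values.
#' @export
rfu_like <- function(m, offset = 10) {
  stopifnot(inherits(m, "expr_matrix"))
  out <- m
  out$values <- 2^(m$values + offset)
  out
}

#' Fraction of planted informative groups recovered by a selection
#'
#' A group counts as recovered when the informative marker or any of its
#' correlated copies appears in `selected`.
#'
#' @param selected character vector of selected feature IDs.
#' @param truth the `truth` element returned by [generate_synthetic()].
#' @return list with `recovered` (count), `total`, `fraction`.
#' @export
group_recovery <- function(selected, truth) {
  hit <- vapply(truth$groups, function(g) any(g %in% selected), TRUE)
  list(recovered = sum(hit), total = length(hit),
       fraction = if (length(hit)) mean(hit) else NA_real_)
}
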