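# Dataset construction: greedy identity-based homology reduction over
# fixed-length peptide windows, positive-vs-negative cross-filtering, and
# deterministic negative sampling.
#
# The clustering contract mirrors CD-HIT's greedy incremental algorithm:
# sequences are scanned in input order and each either joins the first
# retained representative it matches at or above the identity threshold or
# founds a new cluster. Because windows all have the same length, identity
# is simply the fraction of positions with an exact symbol match (the
# padding symbol counts as a symbol), which coincides with CD-HIT's
# shorter-sequence denominator for equal-length inputs.

# Pairwise identity of one window (character vector) against rows of a
# window character matrix.
identity_to <- function(chars, mat) {
  if (!nrow(mat)) return(numeric(0))
  rowMeans(mat == matrix(chars, nrow(mat), length(chars), byrow = TRUE))
}

#' Greedy homology reduction of peptide windows
#'
#' Scans windows in input order; a window joins the first retained
#' representative whose pairwise identity is at least
#' `identity_threshold`, otherwise it is kept as a new representative.
#' Only representatives are returned. Identity is the number of exact
#' positional matches divided by the (fixed) window length.
#'
#' @param windows Window data frame ([extract_windows()]).
#' @param identity_threshold Fraction in (0, 1]; default 0.30.
#' @return The representative subset of `windows` (row order preserved).
#' @export
reduce_homology <- function(windows, identity_threshold = 0.30) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1)
  if (!nrow(windows)) return(windows)
  mat <- window_matrix(windows)
  keep <- integer(0)
  for (i in seq_len(nrow(mat))) {
    ident <- identity_to(mat[i, ], mat[keep, , drop = FALSE])
    if (!length(ident) || max(ident) < identity_threshold)
      keep <- c(keep, i)
  }
  windows[keep, , drop = FALSE]
}

#' Remove negatives homologous to any positive
#'
#' Drops every negative window whose identity to some positive window is
#' at or above `identity_threshold` (the cross-set analogue of running
#' cd-hit-2d between the two classes). Positives are unchanged.
#'
#' @param positives,negatives Window data frames of equal window length.
#' @param identity_threshold Fraction in (0, 1]; default 0.50.
#' @return The filtered negatives.
#' @export
cross_filter_negatives <- function(positives, negatives,
                                   identity_threshold = 0.50) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1)
  if (!nrow(negatives) || !nrow(positives)) return(negatives)
  pmat <- window_matrix(positives)
  nmat <- window_matrix(negatives)
  if (ncol(pmat) != ncol(nmat)) stop("window lengths differ between sets")
  keep <- vapply(seq_len(nrow(nmat)), function(i)
    max(identity_to(nmat[i, ], pmat)) < identity_threshold, logical(1))
  negatives[keep, , drop = FALSE]
}

#' Sample negatives at a fixed positive:negative ratio
#'
#' Draws `round(n_positives * ratio)` negatives uniformly without
#' replacement (all of them, with a warning, if the pool is smaller).
#' Deterministic for a fixed seed. The default ratio 2.33 reflects the
#' class balance of a homology-reduced ubiquitylation training set
#' (roughly 2.33 non-ubiquitylated lysines per ubiquitylated one).
#'
#' @param pool Negative window data frame.
#' @param n_positives Number of positive windows the sample is matched to.
#' @param ratio Negatives per positive; default 2.33.
#' @param seed Integer RNG seed; default 42.
#' @return A subset of `pool`.
#' @export
sample_negatives <- function(pool, n_positives, ratio = 2.33, seed = 42L) {
  stopifnot(ratio > 0, n_positives >= 0)
  want <- round(n_positives * ratio)
  if (!nrow(pool)) {
    warning("empty negative pool; returning empty subset", call. = FALSE)
    return(pool)
  }
  if (nrow(pool) <= want) {
    if (nrow(pool) < want)
      warning(sprintf("pool has %d < %d requested negatives; returning all",
                      nrow(pool), want), call. = FALSE)
    return(pool)
  }
  set.seed(seed)
  pool[sort(sample.int(nrow(pool), want)), , drop = FALSE]
}

#' Build a non-redundant training bundle from annotated proteins
#'
#' Runs the full dataset chain: window extraction, within-class homology
#' reduction at `train_identity`, and cross-filtering of negatives against
#' positives at `cross_identity`. Filter-by-filter counts are recorded as
#' provenance.
#'
#' @param proteins List of [annotated_protein] objects.
#' @param n Window flank length (default 6).
#' @param train_identity Within-class identity threshold (default 0.30).
#' @param cross_identity Positive-vs-negative threshold (default 0.50).
#' @return List of class `dataset_bundle`: `positives`, `negatives`
#'   (window data frames) and `provenance` (named count vector per stage).
#' @export
build_dataset <- function(proteins, n = 6L, train_identity = 0.30,
                          cross_identity = 0.50) {
  win <- extract_windows(proteins, n = n)
  pos <- win[win$label == "positive", , drop = FALSE]
  neg <- win[win$label == "negative", , drop = FALSE]
  prov <- c(extracted_positives = nrow(pos), extracted_negatives = nrow(neg))
  pos <- reduce_homology(pos, train_identity)
  neg <- reduce_homology(neg, train_identity)
  prov <- c(prov, reduced_positives = nrow(pos), reduced_negatives = nrow(neg))
  neg <- cross_filter_negatives(pos, neg, cross_identity)
  prov <- c(prov, crossfiltered_negatives = nrow(neg))
  structure(list(positives = pos, negatives = neg, provenance = prov),
            class = "dataset_bundle")
}

#' @export
print.dataset_bundle <- function(x, ...) {
  cat("<dataset_bundle>\n")
  cat(sprintf("  positives: %d, negatives: %d\n",
              nrow(x$positives), nrow(x$negatives)))
  for (nm in names(x$provenance))
    cat(sprintf("  %-24s %d\n", nm, x$provenance[[nm]]))
  invisible(x)
}
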