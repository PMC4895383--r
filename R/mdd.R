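# Maximal dependence decomposition (MDD): recursive chi-square partitioning
# of aligned positive windows into substrate-motif subgroups.
#
# At each node the algorithm scans every (flank position p, residue group g)
# candidate, scores it by the summed chi-square dependence between "g present
# at p" and "g present at q" over all other flank positions q (only pairs
# individually significant at `alpha` contribute), and splits the node on the
# highest-scoring candidate into a with-group and a without-group child.
# A branch stops when it is smaller than `max_cluster_size` or no candidate
# is significant. Ties break toward smaller |position|, then upstream
# (negative) before downstream, then the scheme's declared group order.

#' Residue group scheme for motif discovery
#'
#' Physicochemical residue classes used as MDD split candidates. The
#' default five groups cover the 20 amino acids disjointly: aromatic
#' (F, Y, W), acidic+amide (D, E, N, Q), basic (K, R, H),
#' nonpolar-aliphatic (A, G, I, L, V, M, P) and polar (S, T, C). The
#' padding symbol never belongs to any group.
#'
#' @param groups Named list of residue character vectors; the default is
#'   used when omitted.
#' @return Named list of class `residue_group_scheme`.
#' @export
residue_group_scheme <- function(groups = NULL) {
  if (is.null(groups))
    groups <- list(
      aromatic = c("F", "Y", "W"),
      acidic_amide = c("D", "E", "N", "Q"),
      basic = c("K", "R", "H"),
      nonpolar_aliphatic = c("A", "G", "I", "L", "V", "M", "P"),
      polar = c("S", "T", "C")
    )
  all <- unlist(groups)
  if (!setequal(intersect(all, aa_alphabet()), aa_alphabet()))
    stop("residue groups must cover the 20 standard amino acids")
  if (anyDuplicated(all))
    stop("a residue may appear in only one group")
  structure(groups, class = "residue_group_scheme")
}

#' Chi-square statistic of a 2x2 contingency table
#'
#' Closed form `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` without continuity
#' correction. Returns 0 when any margin is zero (the table carries no
#' dependence information); an all-zero table additionally warns.
#'
#' @param a,b,c,d Non-negative cell counts (a: both present, b: row only,
#'   c: column only, d: neither).
#' @return The chi-square statistic (1 degree of freedom).
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  if (n == 0) {
    warning("all-zero contingency table", call. = FALSE)
    return(0)
  }
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  if (denom == 0) return(0)
  n * (a * d - b * c)^2 / denom
}

# Logical matrix: group membership per window x flank position.
# Columns named by signed positions -n..-1, 1..n (centre excluded).
group_presence <- function(mat, group) {
  L <- ncol(mat); n <- (L - 1L) %/% 2L
  pres <- matrix(mat %in% group, nrow(mat), L)
  pos <- seq_len(L) - n - 1L
  colnames(pres) <- pos
  pres[, pos != 0L, drop = FALSE]
}

#' Dependence score of a (position, group) split candidate
#'
#' Sum over all other flank positions q of the 2x2 chi-square between
#' "group present at `p`" and "group present at q", counting only pairs
#' whose individual statistic exceeds the 1-df significance cutoff at
#' `alpha`.
#'
#' @param windows Window data frame with at least 2 rows.
#' @param p Signed flank position in `[-n, n]`, nonzero.
#' @param group Character vector of residues (one group of the scheme).
#' @param alpha Per-pair significance level (default 0.01).
#' @return List with `score` (summed significant chi-squares) and
#'   `n_significant` (number of contributing pairs).
#' @export
dependence_score <- function(windows, p, group, alpha = 0.01) {
  stopifnot(nrow(windows) >= 2L)
  pres <- group_presence(window_matrix(windows), group)
  dependence_score_pres(pres, as.character(p), alpha)
}

# Internal core on a precomputed presence matrix (column name = position).
dependence_score_pres <- function(pres, pcol, alpha = 0.01) {
  cutoff <- stats::qchisq(1 - alpha, df = 1L)
  x <- pres[, pcol]
  score <- 0; nsig <- 0L
  for (q in setdiff(colnames(pres), pcol)) {
    y <- pres[, q]
    a <- sum(x & y); b <- sum(x & !y); c <- sum(!x & y); d <- sum(!x & !y)
    chi <- chi_square_2x2(a, b, c, d)
    if (chi >= cutoff) {
      score <- score + chi
      nsig <- nsig + 1L
    }
  }
  list(score = score, n_significant = nsig)
}

# Best (position, group) candidate at a node, or NULL when nothing is
# significant. A candidate is admissible only when the group is enriched
# at p relative to its average rate over the node's flank positions: a
# motif is defined by the conserved presence of a residue class, and the
# chi-square of a 2x2 table is blind to presence vs. absence, so without
# this condition the maximal split can land on the depleted complement of
# a motif position. Tie-breaks: smaller |p|, then negative p first, then
# scheme group order.
best_split <- function(mat, scheme, alpha) {
  L <- ncol(mat); n <- (L - 1L) %/% 2L
  positions <- setdiff(-n:n, 0L)
  ord <- order(abs(positions), positions)  # |p| asc, upstream first
  best <- NULL
  for (g in seq_along(scheme)) {
    pres <- group_presence(mat, scheme[[g]])
    rate <- colMeans(pres)
    for (p in positions[ord]) {
      if (rate[as.character(p)] <= mean(rate)) next  # not enriched at p
      ds <- dependence_score_pres(pres, as.character(p), alpha)
      if (ds$n_significant == 0L) next
      if (is.null(best) || ds$score > best$score + 1e-12)
        best <- list(position = p, group_name = names(scheme)[g],
                     group = scheme[[g]], score = ds$score)
    }
  }
  best
}

#' Recursive MDD partition of positive windows
#'
#' Builds the binary decomposition tree: each internal node records its
#' (position, group) split and chi-square total; leaves are the disjoint
#' motif subgroups, labelled `Ub1..Ubk` depth-first with the with-group
#' branch first.
#'
#' @param windows Non-empty positive window data frame.
#' @param scheme A [residue_group_scheme()] (default scheme when omitted).
#' @param max_cluster_size Subgroups smaller than this are not divided
#'   further; default `ceiling(nrow(windows) / 6)`.
#' @param alpha Per-pair chi-square significance level (default 0.01,
#'   i.e. a 1-df cutoff of 6.63).
#' @return Object of class `mdd_partition`: list with `tree` (nested
#'   node list), `leaves` (list of window data frames), `constraints`
#'   (per-leaf list of constraint records), `sizes`, and the parameters.
#' @export
mdd_partition <- function(windows, scheme = residue_group_scheme(),
                          max_cluster_size = NULL, alpha = 0.01) {
  stopifnot(nrow(windows) >= 1L)
  if (is.null(max_cluster_size))
    max_cluster_size <- max(2L, ceiling(nrow(windows) / 6))
  stopifnot(max_cluster_size >= 2L)

  leaves <- list(); constraints <- list()

  grow <- function(win, path) {
    if (nrow(win) >= max_cluster_size && nrow(win) >= 2L) {
      sp <- best_split(window_matrix(win), scheme, alpha)
      if (!is.null(sp)) {
        pres <- group_presence(window_matrix(win), sp$group)
        has <- pres[, as.character(sp$position)]
        if (any(has) && any(!has)) {
          with_c <- grow(win[has, , drop = FALSE],
                         c(path, list(c(sp, present = TRUE))))
          without_c <- grow(win[!has, , drop = FALSE],
                            c(path, list(c(sp, present = FALSE))))
          return(list(split = sp, size = nrow(win),
                      with_group = with_c, without_group = without_c))
        }
      }
    }
    leaves[[length(leaves) + 1L]] <<- win
    constraints[[length(constraints) + 1L]] <<- path
    list(leaf = length(leaves), size = nrow(win))
  }

  tree <- grow(windows, list())
  names(leaves) <- paste0("Ub", seq_along(leaves))
  names(constraints) <- names(leaves)
  structure(list(tree = tree, leaves = leaves, constraints = constraints,
                 sizes = vapply(leaves, nrow, 0L),
                 max_cluster_size = max_cluster_size, alpha = alpha,
                 scheme = scheme),
            class = "mdd_partition")
}

#' @export
print.mdd_partition <- function(x, ...) {
  cat(sprintf("<mdd_partition> %d subgroup(s), %d windows\n",
              length(x$leaves), sum(x$sizes)))
  for (nm in names(x$leaves)) {
    d <- describe_subgroup(x, nm)
    cat(sprintf("  %-5s n=%-5d %s\n", nm, x$sizes[[nm]], d$constraints_text))
  }
  invisible(x)
}

# "+3 in {D,E,N,Q}" / "-4 not in {F,Y,W}" rendering of one constraint.
constraint_text <- function(con) {
  sprintf("%+d %s {%s}", con$position,
          if (isTRUE(con$present)) "in" else "not in",
          paste(con$group, collapse = ","))
}

#' Describe a motif subgroup
#'
#' Human-readable constraint path plus the position-wise residue frequency
#' matrix of the leaf (21 symbol rows x `2n + 1` position columns, each
#' column summing to 1), suitable for sequence-logo rendering.
#'
#' @param partition An [mdd_partition()].
#' @param leaf Leaf name (`"Ub1"`, ...) or index.
#' @return List with `name`, `size`, `constraints` (records),
#'   `constraints_text`, and `frequency` matrix.
#' @export
describe_subgroup <- function(partition, leaf) {
  stopifnot(inherits(partition, "mdd_partition"))
  win <- partition$leaves[[leaf]]
  if (is.null(win) || !nrow(win)) stop("no such (non-empty) leaf: ", leaf)
  cons <- partition$constraints[[leaf]]
  mat <- window_matrix(win)
  aa <- aa_alphabet21()
  freq <- vapply(seq_len(ncol(mat)), function(p)
    tabulate(match(mat[, p], aa), 21L) / nrow(mat), numeric(21L))
  rownames(freq) <- aa
  colnames(freq) <- seq_len(ncol(mat)) - (ncol(mat) + 1L) %/% 2L
  txt <- if (length(cons))
    paste(vapply(cons, constraint_text, ""), collapse = " AND ")
  else "(no constraint)"
  list(name = if (is.character(leaf)) leaf else names(partition$leaves)[leaf],
       size = nrow(win), constraints = cons, constraints_text = txt,
       frequency = freq)
}

#' Serialize an MDD partition tree to JSON
#'
#' Writes split positions, groups, chi-square totals and child sizes as a
#' nested JSON tree (leaf window memberships are not embedded).
#'
#' @param partition An [mdd_partition()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_partition_json <- function(partition, path) {
  strip <- function(node) {
    if (!is.null(node$leaf))
      return(list(leaf = names(partition$leaves)[node$leaf],
                  size = node$size))
    list(size = node$size,
         split = list(position = node$split$position,
                      group = node$split$group_name,
                      residues = paste(node$split$group, collapse = ""),
                      chi_square = node$split$score),
         with_group = strip(node$with_group),
         without_group = strip(node$without_group))
  }
  jsonlite::write_json(strip(partition$tree), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
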