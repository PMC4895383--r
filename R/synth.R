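# Synthetic annotated proteomes with planted substrate motifs.
#
# The generator emulates the statistical structure the method assumes:
# proteins drawn from a background residue composition, a subset of their
# lysines labelled as modified, and the flanks of labelled lysines carrying
# position-specific residue-group constraints (e.g. aromatic at +2 AND
# acidic/amide at +3) emitted with a stated probability. Profiles, SASA and
# secondary-structure streams are generated in the same file dialects the
# readers consume, so every pipeline stage is testable without external
# tools.

# Swiss-Prot-like background amino-acid frequencies (alphabetical order).
default_background <- function() {
  f <- c(A = 8.25, C = 1.38, D = 5.46, E = 6.72, F = 3.86, G = 7.07,
         H = 2.27, I = 5.91, K = 5.80, L = 9.65, M = 2.41, N = 4.06,
         P = 4.74, Q = 3.93, R = 5.53, S = 6.64, T = 5.35, V = 6.86,
         W = 1.10, Y = 2.92)
  f / sum(f)
}

#' Specification for a synthetic proteome
#'
#' @param n_proteins Number of proteins (default 150).
#' @param length_range Protein length bounds, `c(min, max)` (default
#'   `c(80, 160)`).
#' @param background Named 20-vector of residue frequencies summing to 1;
#'   defaults to Swiss-Prot-like composition.
#' @param n Window flank length the constraints refer to (default 6).
#' @param motif_classes List of classes, each
#'   `list(name, constraints = list(list(position, residues)), prob)`:
#'   at a labelled site of that class, each constrained flank position is
#'   overwritten by a residue drawn from `residues` with probability
#'   `prob`. Default: three well-separated two-constraint classes.
#' @param weights Class mixture weights (default equal); must sum to 1.
#' @param sites_range Labelled sites per protein, `c(min, max)` bounds on
#'   a uniform draw capped by the available lysines (default `c(1, 2)`).
#' @param contamination Fraction of unlabelled lysines that nevertheless
#'   carry a planted motif (label noise; default 0).
#' @param profile_noise SD of the integer noise added to synthetic
#'   profile scores (default 1; 0 gives a deterministic matrix).
#' @param sasa_shift Mean SASA increase (percentage points) at labelled
#'   sites versus background (default 15).
#' @param seed Integer RNG seed (default 42).
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_proteins = 150L, length_range = c(80L, 160L),
                           background = default_background(), n = 6L,
                           motif_classes = NULL, weights = NULL,
                           sites_range = c(1L, 2L), contamination = 0,
                           profile_noise = 1, sasa_shift = 15,
                           seed = 42L) {
  if (is.null(motif_classes))
    motif_classes <- list(
      list(name = "M1", prob = 0.9,
           constraints = list(list(position = 2L, residues = c("F", "Y", "W")),
                              list(position = 3L, residues = c("D", "E", "N", "Q")))),
      list(name = "M2", prob = 0.9,
           constraints = list(list(position = -4L, residues = c("D", "E", "N", "Q")),
                              list(position = -3L, residues = c("D", "E", "N", "Q")))),
      list(name = "M3", prob = 0.9,
           constraints = list(list(position = -1L, residues = c("F", "Y", "W")),
                              list(position = 1L, residues = c("F", "Y", "W")))))
  if (is.null(weights)) weights <- rep(1 / length(motif_classes),
                                       length(motif_classes))
  stopifnot(abs(sum(weights) - 1) < 1e-9,
            length(weights) == length(motif_classes),
            abs(sum(background) - 1) < 1e-6,
            contamination >= 0, contamination <= 1)
  for (cl in motif_classes) {
    stopifnot(cl$prob >= 0, cl$prob <= 1)
    for (con in cl$constraints)
      if (con$position == 0L || abs(con$position) > n)
        stop("constraint position ", con$position,
             " outside the flank range [-", n, ", ", n, "]")
  }
  structure(list(n_proteins = n_proteins, length_range = length_range,
                 background = background, n = n,
                 motif_classes = motif_classes, weights = weights,
                 sites_range = sites_range, contamination = contamination,
                 profile_noise = profile_noise, sasa_shift = sasa_shift,
                 seed = seed),
            class = "synthetic_spec")
}

# Plant one class's constraints around `center` in a character vector;
# positions occupied by reserved centres are never overwritten.
plant_motif <- function(chars, center, class, reserved) {
  for (con in class$constraints) {
    pos <- center + con$position
    if (pos < 1L || pos > length(chars) || pos %in% reserved) next
    if (stats::runif(1) < class$prob)
      chars[pos] <- sample(con$residues, 1L)
  }
  chars
}

#' Generate a synthetic annotated proteome
#'
#' Draws protein sequences from the background composition, labels a
#' subset of lysines as modified, and plants each labelled site's motif
#' class constraints in its flanks. Deterministic for a fixed spec seed.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `proteins` (list of [annotated_protein]) and
#'   `ground_truth` (data frame `protein_id`, `center_pos`, `class`,
#'   `labelled`).
#' @export
generate_proteome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  aa <- names(spec$background)
  proteins <- vector("list", spec$n_proteins)
  truth <- list()
  for (i in seq_len(spec$n_proteins)) {
    L <- sample(spec$length_range[1]:spec$length_range[2], 1L)
    chars <- sample(aa, L, replace = TRUE, prob = spec$background)
    ks <- which(chars == "K")
    id <- sprintf("synth%04d", i)
    sites <- integer(0)
    if (length(ks)) {
      want <- sample(spec$sites_range[1]:spec$sites_range[2], 1L)
      sites <- sort(ks[sample.int(length(ks), min(want, length(ks)))])
      contaminated <- setdiff(ks, sites)
      contaminated <- contaminated[stats::runif(length(contaminated)) <
                                     spec$contamination]
      for (s in c(sites, contaminated)) {
        cl <- spec$motif_classes[[sample.int(length(spec$motif_classes), 1L,
                                             prob = spec$weights)]]
        chars <- plant_motif(chars, s, cl, reserved = ks)
        truth[[length(truth) + 1L]] <- data.frame(
          protein_id = id, center_pos = s, class = cl$name,
          labelled = s %in% sites, stringsAsFactors = FALSE)
      }
    }
    proteins[[i]] <- annotated_protein(id, paste(chars, collapse = ""),
                                       ub_sites = sites)
  }
  list(proteins = proteins,
       ground_truth = if (length(truth)) do.call(rbind, truth)
       else data.frame(protein_id = character(0), center_pos = integer(0),
                       class = character(0), labelled = logical(0)))
}

#' Generate synthetic PSI-BLAST-style profiles
#'
#' Per-residue log-odds-like integer scores: the observed residue's column
#' scores high, all others low, plus rounded Gaussian noise of SD
#' `spec$profile_noise` (0 gives a deterministic matrix). Columns follow
#' the standard PSI-BLAST declared order and round-trip through
#' [read_pssm_ascii()] via [write_pssm_ascii()].
#'
#' @param proteins List of [annotated_protein] objects.
#' @param spec A [synthetic_spec()].
#' @return Named list of `pssm_profile` objects.
#' @export
generate_profiles <- function(proteins, spec) {
  set.seed(spec$seed + 1L)
  psiblast_order <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                      "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  out <- lapply(proteins, function(p) {
    chars <- strsplit(p$sequence, "")[[1]]
    L <- length(chars)
    sc <- matrix(-2L, L, 20L, dimnames = list(NULL, psiblast_order))
    hit <- match(chars, psiblast_order)
    ok <- which(!is.na(hit))
    sc[cbind(ok, hit[ok])] <- 6L
    if (spec$profile_noise > 0)
      sc <- sc + matrix(as.integer(round(stats::rnorm(L * 20L, 0,
                                                      spec$profile_noise))),
                        L, 20L)
    structure(list(protein_id = p$id,
                   residues = gsub("-", "X", p$sequence),
                   scores = sc),
              class = "pssm_profile")
  })
  stats::setNames(out, vapply(proteins, `[[`, "", "id"))
}

# Running-mean smoother with window k (edges shrink).
smooth_running <- function(x, k = 5L) {
  s <- as.numeric(stats::filter(x, rep(1 / k, k), sides = 2L))
  s[is.na(s)] <- x[is.na(s)]
  s
}

#' Generate synthetic SASA and secondary-structure streams
#'
#' SASA: smoothed Gaussian noise around a 30 % baseline, shifted upward by
#' `spec$sasa_shift` percentage points near labelled sites (modified
#' lysines tend to be solvent-exposed). Secondary structure: a sticky
#' three-state chain over H/E/C.
#'
#' @param proteins List of [annotated_protein] objects.
#' @param spec A [synthetic_spec()].
#' @return List with `sasa` and `ss`, each a named list of per-position
#'   vectors as produced by [read_residue_table()].
#' @export
generate_structure <- function(proteins, spec) {
  set.seed(spec$seed + 2L)
  sasa <- list(); ss <- list()
  for (p in proteins) {
    L <- nchar(p$sequence)
    base <- stats::rnorm(L, 30, 12)
    for (s in p$ub_sites) {
      idx <- max(1L, s - 3L):min(L, s + 3L)
      base[idx] <- base[idx] + spec$sasa_shift
    }
    sasa[[p$id]] <- as.character(round(pmin(100, pmax(0,
                                                      smooth_running(base))), 1))
    states <- character(L)
    states[1] <- sample(c("H", "E", "C"), 1L)
    for (i in seq_len(L - 1L))
      states[i + 1L] <- if (stats::runif(1) < 0.8) states[i]
      else sample(setdiff(c("H", "E", "C"), states[i]), 1L)
    ss[[p$id]] <- states
  }
  list(sasa = sasa, ss = ss)
}

#' Write a complete synthetic fixture directory
#'
#' Emits FASTA sequences, the site-annotation TSV, per-protein profile
#' files in the PSI-BLAST ASCII dialect, SASA and secondary-structure
#' TSVs, and the ground-truth JSON.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the generated object list (`proteins`,
#'   `ground_truth`, `profiles`, `structure`).
#' @export
write_fixture_dir <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gen <- generate_proteome(spec)
  profiles <- generate_profiles(gen$proteins, spec)
  struct <- generate_structure(gen$proteins, spec)
  write_fasta(gen$proteins, file.path(dir, "proteins.fasta"))
  sites <- do.call(rbind, lapply(gen$proteins, function(p)
    if (length(p$ub_sites)) data.frame(protein_id = p$id,
                                       position = p$ub_sites)))
  utils::write.table(sites, file.path(dir, "sites.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  pssm_dir <- file.path(dir, "pssm")
  dir.create(pssm_dir, showWarnings = FALSE)
  for (pr in profiles)
    write_pssm_ascii(pr, file.path(pssm_dir, paste0(pr$protein_id, ".pssm")))
  write_table3 <- function(lst, path) {
    rows <- do.call(rbind, lapply(names(lst), function(id)
      data.frame(protein_id = id, position = seq_along(lst[[id]]),
                 value = lst[[id]])))
    utils::write.table(rows, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  write_table3(struct$sasa, file.path(dir, "sasa.tsv"))
  write_table3(struct$ss, file.path(dir, "ss.tsv"))
  jsonlite::write_json(gen$ground_truth, file.path(dir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  invisible(list(proteins = gen$proteins, ground_truth = gen$ground_truth,
                 profiles = profiles, structure = struct))
}
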