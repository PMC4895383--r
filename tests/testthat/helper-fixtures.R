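# Shared fixture builders for the test suite. Everything is generated in
# code; no binary fixtures.

# Build a window data frame directly from residue strings.
make_windows <- function(residues, label = "negative",
                         protein_id = NULL, center_pos = NULL) {
  L <- unique(nchar(residues))
  stopifnot(length(L) == 1L, L %% 2L == 1L)
  n <- (L - 1L) %/% 2L
  data.frame(
    protein_id = protein_id %||% sprintf("w%03d", seq_along(residues)),
    center_pos = center_pos %||% rep(n + 1L, length(residues)),
    n = n,
    residues = residues,
    label = rep_len(label, length(residues)),
    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random windows with 'K' centre over the 20-aa alphabet.
random_windows <- function(m, n = 6L, seed = 1L, label = "negative") {
  set.seed(seed)
  aa <- aa_alphabet()
  res <- vapply(seq_len(m), function(i) {
    ch <- sample(aa, 2L * n + 1L, replace = TRUE)
    ch[n + 1L] <- "K"
    paste(ch, collapse = "")
  }, "")
  make_windows(res, label = label)
}

# Two planted classes vs pure background, sized so positives number ~600
# (about 300 per class): the motif-mixture condition for decomposition
# recovery checks.
two_class_spec <- function(seed) {
  synthetic_spec(
    n_proteins = 400L,
    motif_classes = list(
      list(name = "A", prob = 1.0,
           constraints = list(list(position = 2L, residues = c("F", "Y", "W")),
                              list(position = 3L, residues = c("D", "E", "N", "Q")))),
      list(name = "BG", prob = 0,
           constraints = list(list(position = 1L, residues = "A")))),
    weights = c(0.5, 0.5), seed = seed)
}

# Three fully penetrant (well-separated) motif classes at the full smoke
# scale (~600 positive windows).
well_separated_spec <- function(seed, n_proteins = 400L) {
  sp <- synthetic_spec(n_proteins = n_proteins, seed = seed)
  for (i in seq_along(sp$motif_classes)) sp$motif_classes[[i]]$prob <- 1.0
  sp
}

# Positive/negative training windows from a generated proteome, negatives
# sampled at the default 1:2.33.
training_windows <- function(spec, seed = spec$seed) {
  gen <- generate_proteome(spec)
  win <- extract_windows(gen$proteins, spec$n)
  pos <- win[win$label == "positive", , drop = FALSE]
  neg <- sample_negatives(win[win$label == "negative", , drop = FALSE],
                          nrow(pos), seed = seed)
  list(positives = pos, negatives = neg, proteins = gen$proteins,
       ground_truth = gen$ground_truth)
}

# The (position, group-name) pairs planted by a synthetic spec, as
# "pos:group" strings under the default residue group scheme.
planted_pairs <- function(spec) {
  scheme <- residue_group_scheme()
  gname <- function(res) {
    hit <- vapply(scheme, function(g) all(res %in% g), logical(1))
    names(scheme)[which(hit)[1]]
  }
  unlist(lapply(spec$motif_classes, function(cl) {
    if (cl$prob == 0) return(character(0))
    vapply(cl$constraints, function(con)
      paste0(con$position, ":", gname(con$residues)), "")
  }))
}

# All (position, group, present) constraints across a partition's leaves,
# as "pos:group" strings (present-branch only).
recovered_pairs <- function(partition) {
  unique(unlist(lapply(partition$constraints, function(path)
    vapply(Filter(function(cn) isTRUE(cn$present), path),
           function(cn) paste0(cn$position, ":", cn$group_name), ""))))
}

extdata <- function(...) {
  system.file("extdata", ..., package = "ubimotif", mustWork = TRUE)
}

read_case_study <- function(file) {
  tab <- utils::read.delim(extdata(file), comment.char = "#")
  list(experimental = tab$position[tab$set == "experimental"],
       predicted = tab$position[tab$set == "predicted"])
}
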