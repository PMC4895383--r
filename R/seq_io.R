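# Sequence input/output: FASTA reading, site annotations, peptide window
# extraction, and the PSI-BLAST ASCII PSSM reader.

#' Create an annotated protein
#'
#' A protein sequence together with the set of experimentally labelled
#' ubiquitylated lysine positions (1-based). Every site must index a `K`
#' in the sequence.
#'
#' @param id Non-empty protein identifier.
#' @param sequence Amino-acid sequence (uppercase; non-standard residues
#'   already mapped to `"-"`).
#' @param ub_sites Integer vector of 1-based lysine positions (may be empty).
#' @return An object of class `annotated_protein` with fields `id`,
#'   `sequence`, `ub_sites`.
#' @export
annotated_protein <- function(id, sequence, ub_sites = integer(0)) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- toupper(as.character(sequence))
  ub_sites <- sort(unique(as.integer(ub_sites)))
  if (length(ub_sites)) {
    if (any(ub_sites < 1L | ub_sites > nchar(sequence)))
      stop("ub_sites out of range for protein '", id, "'")
    res <- substring(sequence, ub_sites, ub_sites)
    if (any(res != "K"))
      stop("ub_sites of protein '", id, "' must index lysine (K) residues")
  }
  structure(list(id = id, sequence = sequence, ub_sites = ub_sites),
            class = "annotated_protein")
}

#' @export
print.annotated_protein <- function(x, ...) {
  cat(sprintf("<annotated_protein> %s: %d aa, %d ubiquitylation site(s)\n",
              x$id, nchar(x$sequence), length(x$ub_sites)))
  invisible(x)
}

# Replace non-standard residue codes by the padding symbol (with a warning),
# and reject characters that are not residues at all.
sanitize_sequence <- function(seq, id) {
  seq <- toupper(seq)
  chars <- strsplit(seq, "")[[1]]
  bad <- chars %in% nonstandard_residues()
  if (any(bad)) {
    warning(sprintf("protein '%s': %d non-standard residue(s) (%s) mapped to '-'",
                    id, sum(bad), paste(unique(chars[bad]), collapse = ",")),
            call. = FALSE)
    chars[bad] <- pad_symbol()
  }
  unknown <- !(chars %in% aa_alphabet21())
  if (any(unknown))
    stop(sprintf("protein '%s': invalid character(s) in sequence: %s",
                 id, paste(unique(chars[unknown]), collapse = ",")))
  paste(chars, collapse = "")
}

#' Read protein sequences from a FASTA file
#'
#' Sequences are uppercased and non-standard residues (B, J, O, U, X, Z)
#' are mapped to the padding symbol `"-"` with a warning. Record order is
#' preserved; `ub_sites` are left empty. Entries with an empty sequence are
#' rejected.
#'
#' @param path Path to a FASTA file.
#' @return A list of [annotated_protein] objects.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) return(list())
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1L)
  if (anyNA(ids) || any(!nzchar(ids)))
    stop("FASTA header without an identifier in ", path)
  if (anyDuplicated(ids))
    stop("duplicate FASTA identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- as.character(set)
  if (any(!nzchar(seqs)))
    stop("FASTA record(s) with empty sequence: ",
         paste(ids[!nzchar(seqs)], collapse = ", "))
  mapply(function(id, s) annotated_protein(id, sanitize_sequence(s, id)),
         ids, seqs, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write proteins to a FASTA file
#'
#' @param proteins List of [annotated_protein] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  seqs <- vapply(proteins, `[[`, "", "sequence")
  names(seqs) <- vapply(proteins, `[[`, "", "id")
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Attach site annotations to proteins
#'
#' Reads a TSV of `(protein_id, position[, label])` rows and attaches each
#' position to the matching protein's `ub_sites`. Rows whose position does
#' not index a lysine, or whose protein id is unknown, are rejected with a
#' warning; duplicates collapse to set semantics.
#'
#' @param path Path to a tab-separated file with at least two columns:
#'   protein id and 1-based position. A header line is detected
#'   automatically.
#' @param proteins List of [annotated_protein] objects.
#' @return A list with `proteins` (annotations attached) and `rejected`
#'   (number of rejected rows).
#' @export
read_site_annotations <- function(path, proteins) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  raw <- utils::read.delim(path, header = FALSE, colClasses = "character",
                           comment.char = "#", blank.lines.skip = TRUE)
  if (nrow(raw) && is.na(suppressWarnings(as.integer(raw[1, 2]))))
    raw <- raw[-1, , drop = FALSE]  # header line
  ids <- vapply(proteins, `[[`, "", "id")
  names(proteins) <- ids
  rejected <- 0L
  for (i in seq_len(nrow(raw))) {
    pid <- raw[i, 1]
    pos <- suppressWarnings(as.integer(raw[i, 2]))
    if (is.na(pos) || !(pid %in% ids)) {
      warning("annotation row ", i, ": unknown protein id or bad position (",
              pid, ", ", raw[i, 2], ")", call. = FALSE)
      rejected <- rejected + 1L
      next
    }
    p <- proteins[[pid]]
    if (pos < 1L || pos > nchar(p$sequence) ||
        substring(p$sequence, pos, pos) != "K") {
      warning("annotation row ", i, ": position ", pos, " of '", pid,
              "' is not a lysine; row rejected", call. = FALSE)
      rejected <- rejected + 1L
      next
    }
    proteins[[pid]]$ub_sites <- sort(unique(c(p$ub_sites, pos)))
  }
  list(proteins = unname(proteins), rejected = rejected)
}

#' Extract lysine-centred peptide windows
#'
#' One window of length `2n + 1` per lysine in the protein, centred on the
#' lysine; positions beyond the termini are filled with the padding symbol
#' `"-"`. A window is labelled positive when its centre is an annotated
#' ubiquitylation site.
#'
#' @param protein An [annotated_protein], or a list of them.
#' @param n Flank length (window is `2n + 1` residues; default 6).
#' @return A data frame with columns `protein_id`, `center_pos`, `n`,
#'   `residues`, `label` (`"positive"`/`"negative"`). Zero rows if the
#'   protein has no lysine.
#' @export
extract_windows <- function(protein, n = 6L) {
  stopifnot(n >= 1L)
  if (is.list(protein) && !inherits(protein, "annotated_protein")) {
    out <- lapply(protein, extract_windows, n = n)
    return(do.call(rbind, c(out, list(make.row.names = FALSE))))
  }
  chars <- strsplit(protein$sequence, "")[[1]]
  centers <- which(chars == "K")
  if (!length(centers))
    return(data.frame(protein_id = character(0), center_pos = integer(0),
                      n = integer(0), residues = character(0),
                      label = character(0), stringsAsFactors = FALSE))
  padded <- c(rep(pad_symbol(), n), chars, rep(pad_symbol(), n))
  residues <- vapply(centers, function(c0)
    paste(padded[c0:(c0 + 2L * n)], collapse = ""), "")
  data.frame(protein_id = protein$id,
             center_pos = as.integer(centers),
             n = as.integer(n),
             residues = residues,
             label = ifelse(centers %in% protein$ub_sites,
                            "positive", "negative"),
             stringsAsFactors = FALSE)
}

#' Split window strings into a residue character matrix
#'
#' @param windows Window data frame from [extract_windows()].
#' @return Character matrix, one row per window, `2n + 1` columns.
#' @export
window_matrix <- function(windows) {
  if (!nrow(windows)) return(matrix(character(0), nrow = 0))
  len <- unique(nchar(windows$residues))
  if (length(len) != 1L) stop("windows of mixed length")
  matrix(unlist(strsplit(windows$residues, ""), use.names = FALSE),
         nrow = nrow(windows), ncol = len, byrow = TRUE)
}

#' Read a PSI-BLAST ASCII PSSM profile
#'
#' Parses the ASCII matrix PSI-BLAST emits (`-out_ascii_pssm`): header
#' lines, a column-header row of 20 amino-acid letters, then one row per
#' residue position with the first 20 integer score columns. The column
#' order declared in the file header is trusted and recorded.
#'
#' @param path Path to the ASCII profile.
#' @param protein_id Identifier to attach; defaults to the file stem.
#' @return An object of class `pssm_profile`: list with `protein_id`,
#'   `residues` (sequence read from the row labels) and `scores`
#'   (L x 20 integer matrix, columns named by the declared order).
#' @export
read_pssm_ascii <- function(path, protein_id = NULL) {
  if (!file.exists(path)) stop("PSSM file not found: ", path)
  if (is.null(protein_id))
    protein_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  toks <- lapply(lines, function(l) strsplit(trimws(l), "\\s+")[[1]])
  hdr <- which(vapply(toks, function(t)
    length(t) >= 20 && all(t[1:20] %in% aa_alphabet()), logical(1)))[1]
  if (is.na(hdr)) stop("no PSSM column header found in ", path)
  cols <- toks[[hdr]][1:20]
  rows <- list(); residues <- character(0)
  for (i in seq(hdr + 1L, length.out = max(0L, length(lines) - hdr))) {
    t <- toks[[i]]
    if (length(t) == 0L || is.na(suppressWarnings(as.integer(t[1])))) break
    if (length(t) < 22L)
      stop("truncated PSSM row ", length(rows) + 1L, " in ", path)
    scores <- suppressWarnings(as.integer(t[3:22]))
    if (anyNA(scores))
      stop("non-integer scores in PSSM row ", length(rows) + 1L, " in ", path)
    residues <- c(residues, t[2])
    rows[[length(rows) + 1L]] <- scores
  }
  if (!length(rows)) stop("no score rows in PSSM file ", path)
  scores <- do.call(rbind, rows)
  colnames(scores) <- cols
  structure(list(protein_id = protein_id,
                 residues = paste(residues, collapse = ""),
                 scores = scores),
            class = "pssm_profile")
}

#' Write a profile in the PSI-BLAST ASCII dialect
#'
#' Counterpart of [read_pssm_ascii()]; used by the synthetic-profile
#' generator and for round-trip testing.
#'
#' @param profile A `pssm_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pssm_ascii <- function(profile, path) {
  stopifnot(inherits(profile, "pssm_profile"))
  sc <- profile$scores
  res <- strsplit(profile$residues, "")[[1]]
  stopifnot(nrow(sc) == length(res))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("", "Last position-specific scoring matrix computed",
               paste0("           ", paste(sprintf("%3s", colnames(sc)),
                                           collapse = ""))), con)
  for (i in seq_len(nrow(sc)))
    writeLines(paste0(sprintf("%5d %s ", i, res[i]),
                      paste(sprintf("%3d", sc[i, ]), collapse = "")), con)
  invisible(path)
}

#' Read per-residue SASA or secondary-structure tables
#'
#' Tab-separated files keyed by protein id and 1-based position. SASA
#' values are percentages in `[0, 100]`; secondary-structure states are
#' `H` (helix), `E` (sheet) or `C` (coil).
#'
#' @param path Path to the TSV (`protein_id`, `position`, `value`).
#' @return Named list (by protein id) of value vectors indexed by position.
#' @export
read_residue_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, header = FALSE, colClasses = "character",
                           comment.char = "#")
  if (nrow(raw) && is.na(suppressWarnings(as.integer(raw[1, 2]))))
    raw <- raw[-1, , drop = FALSE]
  out <- list()
  for (pid in unique(raw[, 1])) {
    sub <- raw[raw[, 1] == pid, , drop = FALSE]
    pos <- as.integer(sub[, 2])
    v <- rep(NA_character_, max(pos))
    v[pos] <- sub[, 3]
    out[[pid]] <- v
  }
  out
}
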