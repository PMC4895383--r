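# Feature encoders: each turns a peptide window (or a set of windows) into
# a fixed-length numeric vector. Dimensionalities at n = 6 (13-mer):
#   binary20 = 260, aac = 21, aapc = 441, pwm = 13, pssm = 400,
#   sasa = 13, ss = 39.
# All outputs lie in [0, 1]; the one-hot encoder is {0, 1}-valued.

#' One-hot (20D binary) window encoding
#'
#' Each window position is a 20-dimensional indicator block over the amino
#' acids in alphabetical order, so alanine is `1 0 0 ... 0` and cysteine
#' `0 1 0 ... 0`. The padding symbol encodes as an all-zero block.
#'
#' @param windows Window data frame ([extract_windows()]).
#' @return Numeric matrix, one row per window, `(2n + 1) * 20` columns.
#' @export
encode_binary20 <- function(windows) {
  mat <- window_matrix(windows)
  L <- ncol(mat); aa <- aa_alphabet()
  out <- matrix(0, nrow(mat), L * 20L)
  for (p in seq_len(L)) {
    idx <- match(mat[, p], aa)            # NA for padding
    hit <- which(!is.na(idx))
    out[cbind(hit, (p - 1L) * 20L + idx[hit])] <- 1
  }
  colnames(out) <- paste0("p", rep(seq_len(L), each = 20L), "_", rep(aa, L))
  out
}

#' Amino-acid composition (AAC) encoding
#'
#' Counts of the 20 amino acids plus the padding ("non-existing residue")
#' symbol, normalised by window length; each row sums to 1.
#'
#' @inheritParams encode_binary20
#' @return Numeric matrix with 21 columns.
#' @export
encode_aac <- function(windows) {
  mat <- window_matrix(windows)
  aa <- aa_alphabet21()
  out <- t(apply(mat, 1L, function(r) tabulate(match(r, aa), 21L))) / ncol(mat)
  if (nrow(mat) == 1L) out <- matrix(out, 1L)  # apply() drops to vector
  colnames(out) <- aa
  out
}

#' Amino-acid pair composition (AAPC) encoding
#'
#' Adjacent ordered residue pairs (positions i, i+1) counted over the
#' 21 x 21 symbol alphabet and normalised by the `2n` pairs in a window;
#' 441 dimensions, each row sums to 1.
#'
#' @inheritParams encode_binary20
#' @return Numeric matrix with 441 columns.
#' @export
encode_aapc <- function(windows) {
  mat <- window_matrix(windows)
  L <- ncol(mat); aa <- aa_alphabet21()
  out <- matrix(0, nrow(mat), 441L)
  first <- match(mat[, -L, drop = FALSE], aa)   # column-major over pairs
  second <- match(mat[, -1L, drop = FALSE], aa)
  cell <- (first - 1L) * 21L + second
  row <- rep(seq_len(nrow(mat)), times = L - 1L)
  for (k in seq_along(cell))
    out[row[k], cell[k]] <- out[row[k], cell[k]] + 1
  out <- out / (L - 1L)
  colnames(out) <- paste0(rep(aa, each = 21L), rep(aa, 21L))
  out
}

#' Build a position weight matrix from positive windows
#'
#' Per-position occurrence rates of the 21 symbols among aligned positive
#' training windows; every position row sums to 1.
#'
#' @param windows Positive window data frame (non-empty).
#' @return Object of class `pwm_matrix`: `(2n + 1) x 21` rate matrix.
#' @export
build_pwm <- function(windows) {
  if (!nrow(windows)) stop("cannot build a PWM from zero windows")
  mat <- window_matrix(windows)
  aa <- aa_alphabet21()
  rates <- t(vapply(seq_len(ncol(mat)), function(p)
    tabulate(match(mat[, p], aa), 21L) / nrow(mat), numeric(21L)))
  colnames(rates) <- aa
  rownames(rates) <- seq_len(ncol(mat)) - (ncol(mat) + 1L) %/% 2L
  structure(rates, class = "pwm_matrix")
}

#' PWM window encoding
#'
#' Per position, the training occurrence rate of the window's own residue
#' at that position: a `2n + 1`-dimensional profile-match vector.
#'
#' @inheritParams encode_binary20
#' @param pwm A `pwm_matrix` from [build_pwm()].
#' @return Numeric matrix with `2n + 1` columns.
#' @export
encode_pwm <- function(windows, pwm) {
  stopifnot(inherits(pwm, "pwm_matrix"))
  mat <- window_matrix(windows)
  if (ncol(mat) != nrow(pwm)) stop("window length does not match PWM")
  aa <- aa_alphabet21()
  out <- vapply(seq_len(ncol(mat)), function(p)
    unclass(pwm)[p, match(mat[, p], aa)], numeric(nrow(mat)))
  if (nrow(mat) == 1L) out <- matrix(out, 1L)
  colnames(out) <- rownames(pwm)
  out
}

#' Logistic squashing function
#'
#' `1 / (1 + exp(-x))`, computed without overflow for large `|x|`.
#'
#' @param x Numeric vector.
#' @return Values in (0, 1).
#' @export
sigmoid <- function(x) {
  out <- ifelse(x >= 0, 1 / (1 + exp(-x)), exp(x) / (1 + exp(x)))
  out
}

#' PSSM window encoding
#'
#' Slices the `2n + 1` profile rows centred on the window (rows falling
#' outside the protein contribute zeros), sums rows sharing the same
#' window residue type into a 20 x 20 matrix (rows = residue types in
#' alphabetical order, columns = the profile's declared score order
#' remapped to alphabetical), divides by the window length and squashes
#' each element through the logistic function. Flattened row-type-major
#' to 400 dimensions.
#'
#' @param windows Window data frame; all rows must belong to
#'   `profile$protein_id` unless `profiles` is a named list covering every
#'   protein present.
#' @param profiles A single `pssm_profile` or a named list of them.
#' @return Numeric matrix with 400 columns, values in (0, 1).
#' @export
encode_pssm <- function(windows, profiles) {
  if (inherits(profiles, "pssm_profile"))
    profiles <- stats::setNames(list(profiles), profiles$protein_id)
  aa <- aa_alphabet()
  mat <- window_matrix(windows)
  L <- ncol(mat); n <- (L - 1L) %/% 2L
  out <- matrix(0, nrow(windows), 400L)
  for (i in seq_len(nrow(windows))) {
    prof <- profiles[[windows$protein_id[i]]]
    if (is.null(prof))
      stop("no PSSM profile for protein '", windows$protein_id[i], "'")
    sc <- prof$scores[, aa, drop = FALSE]   # canonical column order
    c0 <- windows$center_pos[i]
    if (c0 > nrow(sc))
      stop("profile of '", prof$protein_id, "' shorter than the protein")
    rows <- (c0 - n):(c0 + n)
    sl <- matrix(0, L, 20L)
    inside <- rows >= 1L & rows <= nrow(sc)
    sl[inside, ] <- sc[rows[inside], , drop = FALSE]
    agg <- matrix(0, 20L, 20L)
    type <- match(mat[i, ], aa)             # NA for padding: contributes nothing
    for (p in which(!is.na(type)))
      agg[type[p], ] <- agg[type[p], ] + sl[p, ]
    out[i, ] <- sigmoid(as.vector(t(agg)) / L)
  }
  colnames(out) <- paste0(rep(aa, each = 20L), "_", rep(aa, 20L))
  out
}

#' Solvent-accessibility window encoding
#'
#' Per-position SASA percentages divided by 100; padded positions (NA)
#' encode as 0.
#'
#' @param sasa Numeric matrix or vector of per-position SASA values in
#'   `[0, 100]`, one row per window, `2n + 1` columns; `NA` marks padded
#'   positions.
#' @return Numeric matrix with values in `[0, 1]`.
#' @export
encode_sasa <- function(sasa) {
  if (is.null(dim(sasa))) sasa <- matrix(sasa, 1L)
  if (any(sasa < 0 | sasa > 100, na.rm = TRUE))
    stop("SASA values must lie in [0, 100]")
  sasa[is.na(sasa)] <- 0
  sasa / 100
}

#' Secondary-structure window encoding
#'
#' Orthogonal 3-bit coding per position: helix `H` is `1 0 0`, sheet `E`
#' is `0 1 0`, coil `C` is `0 0 1`; padded positions (NA) are `0 0 0`.
#'
#' @param states Character matrix or vector of per-position states in
#'   `{H, E, C}` with `NA` for padding; one row per window.
#' @return Numeric matrix with `3 * (2n + 1)` columns.
#' @export
encode_ss <- function(states) {
  if (is.null(dim(states))) states <- matrix(states, 1L)
  lv <- c("H", "E", "C")
  bad <- !(states %in% lv) & !is.na(states)
  if (any(bad)) stop("invalid secondary-structure state(s): ",
                     paste(unique(states[bad]), collapse = ","))
  L <- ncol(states)
  out <- matrix(0, nrow(states), 3L * L)
  for (p in seq_len(L)) {
    idx <- match(states[, p], lv)
    hit <- which(!is.na(idx))
    out[cbind(hit, (p - 1L) * 3L + idx[hit])] <- 1
  }
  colnames(out) <- paste0("p", rep(seq_len(L), each = 3L), "_", rep(lv, L))
  out
}

# Slice per-protein residue tables into per-window position matrices.
# `tables` is the output of read_residue_table(); padded positions -> NA.
window_values <- function(windows, tables, as_numeric = TRUE) {
  L <- 2L * windows$n[1] + 1L; n <- windows$n[1]
  out <- matrix(NA_character_, nrow(windows), L)
  for (i in seq_len(nrow(windows))) {
    v <- tables[[windows$protein_id[i]]]
    pos <- (windows$center_pos[i] - n):(windows$center_pos[i] + n)
    inside <- pos >= 1L & pos <= length(v)
    out[i, inside] <- v[pos[inside]]
  }
  if (as_numeric) matrix(as.numeric(out), nrow(out)) else out
}

#' Encode windows by encoder name
#'
#' Registry front end over the individual encoders. Hybrid features are
#' addressed as `"concat:a+b"` and produced by plain column
#' concatenation (e.g. `"concat:pssm+aac"`).
#'
#' @param windows Window data frame.
#' @param encoder One of `binary20`, `aac`, `aapc`, `pwm`, `pssm`,
#'   `sasa`, `ss`, or `concat:<a>+<b>`.
#' @param state Named list of fitted/external encoder state: `pwm`
#'   (a `pwm_matrix`), `profiles` (named list of `pssm_profile`), `sasa`
#'   and `ss` (tables from [read_residue_table()]).
#' @return Numeric feature matrix, one row per window.
#' @export
encode_windows <- function(windows, encoder, state = list()) {
  if (startsWith(encoder, "concat:")) {
    parts <- strsplit(sub("^concat:", "", encoder), "+", fixed = TRUE)[[1]]
    return(do.call(cbind, lapply(parts, encode_windows,
                                 windows = windows, state = state)))
  }
  switch(encoder,
    binary20 = encode_binary20(windows),
    aac = encode_aac(windows),
    aapc = encode_aapc(windows),
    pwm = {
      if (is.null(state$pwm)) stop("encoder 'pwm' needs state$pwm")
      encode_pwm(windows, state$pwm)
    },
    pssm = {
      if (is.null(state$profiles)) stop("encoder 'pssm' needs state$profiles")
      encode_pssm(windows, state$profiles)
    },
    sasa = encode_sasa(window_values(windows, state$sasa)),
    ss = encode_ss(window_values(windows, state$ss, as_numeric = FALSE)),
    stop("unknown encoder: ", encoder)
  )
}

#' Fit whatever state an encoder needs from training positives
#'
#' Currently only the PWM encoder carries fitted state (its rate matrix,
#' estimated from the positive training windows); external state
#' (profiles, SASA, SS tables) is passed through unchanged.
#'
#' @param encoder Encoder name as in [encode_windows()].
#' @param positives Positive training windows.
#' @param state Existing state list to extend.
#' @return The (possibly extended) state list.
#' @export
fit_encoder_state <- function(encoder, positives, state = list()) {
  needs_pwm <- encoder == "pwm" ||
    (startsWith(encoder, "concat:") && grepl("\\bpwm\\b", encoder))
  if (needs_pwm && is.null(state$pwm)) state$pwm <- build_pwm(positives)
  state
}
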