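test_that("one-hot encoding follows the declared alphabetical blocks", {
  w <- make_windows("ACDEFGKGFEDCA")
  b <- encode_binary20(w)
  expect_equal(ncol(b), 260L)
  expect_equal(unname(b[1, 1:20]),
               c(1, rep(0, 19)))                       # A block
  expect_equal(unname(b[1, 21:40]),
               c(0, 1, rep(0, 18)))                    # C block
  expect_equal(sum(b), 13)

  wp <- make_windows("-----MKA-----")
  bp <- encode_binary20(wp)
  expect_equal(sum(bp), 3)                             # pads all-zero
})

test_that("composition encodings are normalised distributions", {
  w <- make_windows(c("AAAAAAKAAAAAA", "-----MKA-----"))
  a <- encode_aac(w)
  expect_equal(ncol(a), 21L)
  expect_equal(unname(a[1, "A"]), 12 / 13)
  expect_equal(unname(a[1, "K"]), 1 / 13)
  expect_equal(unname(a[2, "-"]), 10 / 13)
  expect_equal(unname(rowSums(a)), c(1, 1))

  ap <- encode_aapc(w)
  expect_equal(ncol(ap), 441L)
  expect_equal(unname(rowSums(ap)), c(1, 1))

  toy <- make_windows("ACK")                          # n = 1: pairs AC, CK
  apt <- encode_aapc(toy)
  expect_equal(unname(apt[1, "AC"]), 0.5)
  expect_equal(unname(apt[1, "CK"]), 0.5)
  expect_equal(sum(apt), 1)
})

test_that("encoder invariants hold on random windows", {
  w <- random_windows(40, seed = 8)
  expect_true(all(encode_binary20(w) %in% c(0, 1)))
  expect_equal(unname(rowSums(encode_aac(w))), rep(1, 40))
  expect_equal(unname(rowSums(encode_aapc(w))), rep(1, 40))
  pwm <- build_pwm(w)
  expect_equal(unname(rowSums(unclass(pwm))), rep(1, 13))
  enc <- encode_pwm(w, pwm)
  expect_true(all(enc >= 0 & enc <= 1))
})

test_that("PWM reflects training occurrence rates", {
  same <- make_windows(rep("AAAAAAKAAAAAA", 5), "positive")
  pwm <- build_pwm(same)
  expect_true(all(unclass(pwm) %in% c(0, 1)))
  expect_equal(unname(encode_pwm(same[1, ], pwm))[1, ], rep(1, 13))

  two <- make_windows(c("AAAAAAKAAAAAA", "AAAAAAKADAAAA"), "positive")
  pwm2 <- build_pwm(two)                               # differ at +2
  expect_equal(unclass(pwm2)["2", "A"], 0.5)
  expect_equal(unclass(pwm2)["2", "D"], 0.5)
  expect_error(build_pwm(same[0, ]), "zero windows")
})

test_that("sigmoid is the standard logistic with safe tails", {
  expect_equal(sigmoid(0), 0.5)
  expect_equal(sigmoid(2) + sigmoid(-2), 1)
  expect_equal(sigmoid(1000), 1)
  expect_equal(sigmoid(-1000), 0)
  expect_true(all(diff(sigmoid(seq(-5, 5, 0.5))) > 0))
})

# Literal loop re-implementation of the PSSM window transform.
pssm_oracle <- function(window_chars, slice) {
  aa <- aa_alphabet()
  agg <- matrix(0, 20, 20)
  for (p in seq_along(window_chars)) {
    t <- match(window_chars[p], aa)
    if (is.na(t)) next
    for (j in 1:20) agg[t, j] <- agg[t, j] + slice[p, j]
  }
  out <- numeric(0)
  for (i in 1:20) for (j in 1:20)
    out <- c(out, 1 / (1 + exp(-agg[i, j] / length(window_chars))))
  out
}

test_that("PSSM encoding matches hand-computed and brute-force oracles", {
  ord <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  zero <- structure(list(protein_id = "z", residues = strrep("K", 13),
                         scores = matrix(0L, 13, 20,
                                         dimnames = list(NULL, ord))),
                    class = "pssm_profile")
  w <- make_windows(strrep("K", 13), protein_id = "z", center_pos = 7L)
  expect_equal(unname(encode_pssm(w, zero))[1, ], rep(0.5, 400))

  ones <- zero; ones$scores[] <- 1L
  enc <- encode_pssm(w, ones)[1, ]
  m <- matrix(enc, 20, 20, byrow = TRUE)     # rows = residue type
  kk <- which(aa_alphabet() == "K")
  expect_equal(unname(m[kk, ]), rep(1 / (1 + exp(-1)), 20))
  expect_equal(unname(m[-kk, ]), matrix(0.5, 19, 20), ignore_attr = TRUE)

  set.seed(33)
  for (i in 1:30) {
    L <- sample(20:40, 1)
    prof <- structure(list(protein_id = "r", residues = strrep("A", L),
                           scores = matrix(sample(-8:8, L * 20, TRUE), L, 20,
                                           dimnames = list(NULL, ord))),
                      class = "pssm_profile")
    c0 <- sample(7:(L - 6), 1)
    chars <- sample(c(aa_alphabet(), "-"), 13, replace = TRUE)
    chars[7] <- "K"
    wr <- make_windows(paste(chars, collapse = ""), protein_id = "r",
                       center_pos = c0)
    slice <- prof$scores[(c0 - 6):(c0 + 6), aa_alphabet()]
    expect_equal(unname(encode_pssm(wr, prof))[1, ],
                 pssm_oracle(chars, slice), tolerance = 1e-12)
  }
})

test_that("PSSM encoding zeroes padded context and validates lengths", {
  ord <- colnames(generate_profiles(list(annotated_protein("t", "MKA")),
                                    synthetic_spec(seed = 1))[[1]]$scores)
  prof <- structure(list(protein_id = "t", residues = "MKA",
                         scores = matrix(5L, 3, 20,
                                         dimnames = list(NULL, ord))),
                    class = "pssm_profile")
  w <- extract_windows(annotated_protein("t", "MKA"), 6)
  enc <- encode_pssm(w, prof)
  expect_true(all(enc >= 0.5))          # positive scores, zero pads neutral
  expect_error(encode_pssm(make_windows(strrep("K", 13), protein_id = "t",
                                        center_pos = 9L), prof),
               "shorter")
})

test_that("structure encoders follow the orthogonal codings", {
  expect_equal(encode_sasa(c(35, NA, 100))[1, ], c(0.35, 0, 1))
  expect_error(encode_sasa(c(35, 120)), "\\[0, 100\\]")

  s <- encode_ss(matrix(c("H", "E", "C", NA), 1))
  expect_equal(unname(s[1, ]), c(1, 0, 0, 0, 1, 0, 0, 0, 1, 0, 0, 0))
  expect_error(encode_ss("Q"), "invalid")
  expect_equal(sum(encode_ss(matrix(NA_character_, 1, 13))), 0)
})

test_that("encoder registry produces the declared dimensionalities", {
  spec <- synthetic_spec(n_proteins = 4L, seed = 6L)
  gen <- generate_proteome(spec)
  profiles <- generate_profiles(gen$proteins, spec)
  struct <- generate_structure(gen$proteins, spec)
  win <- extract_windows(gen$proteins, 6)[1:5, ]
  state <- list(pwm = build_pwm(win), profiles = profiles,
                sasa = struct$sasa, ss = struct$ss)
  dims <- c(binary20 = 260L, aac = 21L, aapc = 441L, pwm = 13L,
            pssm = 400L, sasa = 13L, ss = 39L)
  for (enc in names(dims)) {
    x <- encode_windows(win, enc, state)
    expect_equal(ncol(x), dims[[enc]], info = enc)
    expect_true(all(is.finite(x)), info = enc)
    expect_true(all(x >= 0 & x <= 1), info = enc)
  }
  hybrid <- encode_windows(win, "concat:pssm+aac", state)
  expect_equal(ncol(hybrid), 421L)
  expect_error(encode_windows(win, "nope"), "unknown encoder")
})
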