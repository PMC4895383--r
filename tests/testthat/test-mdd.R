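test_that("2x2 chi-square matches the closed form and stats oracle", {
  expect_equal(chi_square_2x2(30, 10, 10, 30), 20)
  expect_equal(chi_square_2x2(10, 10, 10, 10), 0)
  expect_equal(chi_square_2x2(5, 0, 7, 0), 0)          # zero margin
  expect_warning(expect_equal(chi_square_2x2(0, 0, 0, 0), 0), "all-zero")

  set.seed(17)
  for (i in 1:100) {
    tab <- matrix(sample(0:40, 4, TRUE), 2)
    got <- suppressWarnings(chi_square_2x2(tab[1, 1], tab[1, 2],
                                           tab[2, 1], tab[2, 2]))
    marg0 <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
    ref <- if (marg0) 0 else
      unname(suppressWarnings(
        stats::chisq.test(tab, correct = FALSE)$statistic))
    expect_equal(got, ref, tolerance = 1e-10)
  }
})

test_that("dependence score sums significant pairs only", {
  # group at +1 perfectly co-occurs with group at +2, 50/50 split
  res <- c(rep("AAAAAAKFFAAAA", 30), rep("AAAAAAKAAAAAA", 30))
  w <- make_windows(res, "positive")
  scheme <- residue_group_scheme()
  ds <- dependence_score(w, 1, scheme$aromatic)
  expect_equal(ds$n_significant, 1L)
  expect_equal(ds$score, 60)                # perfect association: chi2 = N

  # independence: constant group column everywhere -> nothing significant
  w0 <- make_windows(rep("AAAAAAKAAAAAA", 40), "positive")
  ds0 <- dependence_score(w0, 1, scheme$aromatic)
  expect_equal(ds0$score, 0)
})

test_that("dependence score equals a brute-force double loop", {
  w <- random_windows(200, seed = 19, label = "positive")
  scheme <- residue_group_scheme()
  mat <- window_matrix(w)
  cutoff <- qchisq(0.99, 1)
  for (g in c("aromatic", "acidic_amide", "basic")) {
    for (p in c(-3L, 2L)) {
      ref <- 0; nsig <- 0L
      for (q in setdiff(-6:6, c(0L, p))) {
        x <- mat[, p + 7] %in% scheme[[g]]
        yq <- mat[, q + 7] %in% scheme[[g]]
        chi <- suppressWarnings(
          chi_square_2x2(sum(x & yq), sum(x & !yq),
                         sum(!x & yq), sum(!x & !yq)))
        if (chi >= cutoff) { ref <- ref + chi; nsig <- nsig + 1L }
      }
      ds <- dependence_score(w, p, scheme[[g]])
      expect_equal(ds$score, ref)
      expect_equal(ds$n_significant, nsig)
    }
  }
})

test_that("degenerate inputs give the single-leaf partition", {
  w <- make_windows(rep("AAAAAAKAAAAAA", 100), "positive")
  part <- mdd_partition(w)
  expect_length(part$leaves, 1L)
  expect_equal(unname(part$sizes), 100L)
  expect_equal(describe_subgroup(part, "Ub1")$constraints_text,
               "(no constraint)")

  one <- mdd_partition(w[1, ])
  expect_length(one$leaves, 1L)
})

test_that("partition is a deterministic disjoint cover", {
  tw <- training_windows(synthetic_spec(n_proteins = 60L, seed = 23L))
  pos <- tw$positives
  p1 <- mdd_partition(pos)
  p2 <- mdd_partition(pos)
  expect_identical(p1$sizes, p2$sizes)
  expect_identical(p1$constraints, p2$constraints)
  expect_equal(sum(p1$sizes), nrow(pos))
  key <- unlist(lapply(p1$leaves, function(lf)
    paste(lf$protein_id, lf$center_pos)))
  expect_equal(sort(unname(key)), sort(paste(pos$protein_id, pos$center_pos)))
  expect_equal(names(p1$leaves), paste0("Ub", seq_along(p1$leaves)))
})

test_that("leaf count is monotone non-increasing in max_cluster_size", {
  tw <- training_windows(synthetic_spec(n_proteins = 80L, seed = 29L))
  pos <- tw$positives
  sizes <- c(20L, 50L, 100L, 200L, nrow(pos) + 1L)
  counts <- vapply(sizes, function(mcs)
    length(mdd_partition(pos, max_cluster_size = mcs)$leaves), 0L)
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[length(counts)], 1L)
})

test_that("planted two-class mixture splits on a planted (position, group)", {
  hits <- 0L
  for (s in 1:10) {
    tw <- training_windows(two_class_spec(s))
    part <- mdd_partition(tw$positives)
    sp <- part$tree$split
    hits <- hits + (paste0(sp$position, ":", sp$group_name) %in%
                      c("2:aromatic", "3:acidic_amide"))
  }
  expect_gte(hits, 9L)
})

test_that("planted class windows land in motif-consistent leaves", {
  # a leaf is consistent with the planted class when its constraint path
  # asserts the presence of a planted (position, group) pair; recursion may
  # subdivide a class across several such leaves, but should not scatter it
  # into unrelated ones
  cohesion <- vapply(1:10, function(s) {
    tw <- training_windows(two_class_spec(s))
    gt <- tw$ground_truth
    key <- paste(gt$protein_id, gt$center_pos)
    part <- mdd_partition(tw$positives)
    consistent <- vapply(part$constraints, function(path)
      any(vapply(path, function(cn)
        isTRUE(cn$present) &&
          paste0(cn$position, ":", cn$group_name) %in%
            c("2:aromatic", "3:acidic_amide"), logical(1))), logical(1))
    in_consistent <- unlist(lapply(part$leaves[consistent], function(lf)
      paste(lf$protein_id, lf$center_pos)))
    a_key <- key[gt$class == "A"]
    mean(a_key %in% in_consistent)
  }, 0)
  expect_gte(sum(cohesion >= 0.9), 9L)
})

test_that("subgroup descriptors expose constraints and logo frequencies", {
  tw <- training_windows(two_class_spec(1L))
  part <- mdd_partition(tw$positives)
  d1 <- describe_subgroup(part, "Ub1")
  expect_equal(d1$size, unname(part$sizes[1]))
  expect_length(d1$constraints, length(part$constraints$Ub1))
  expect_equal(unname(colSums(d1$frequency)), rep(1, 13))
  all_text <- vapply(names(part$leaves), function(nm)
    describe_subgroup(part, nm)$constraints_text, "")
  expect_true(any(grepl("\\+3 in \\{D,E,N,Q\\}|\\+2 in \\{F,Y,W\\}",
                        all_text)))
})

test_that("partition serializes to a JSON tree with consistent sizes", {
  tw <- training_windows(synthetic_spec(n_proteins = 60L, seed = 31L))
  part <- mdd_partition(tw$positives)
  tf <- withr::local_tempfile(fileext = ".json")
  write_partition_json(part, tf)
  tree <- jsonlite::read_json(tf)
  sum_leaves <- function(node) {
    if (!is.null(node$leaf)) return(node$size)
    sum_leaves(node$with_group) + sum_leaves(node$without_group)
  }
  expect_equal(sum_leaves(tree), nrow(tw$positives))
})
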