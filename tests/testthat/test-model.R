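# Small separable fixture: positives all-alanine flanks, negatives
# all-glycine flanks, so any sensible classifier separates them.
separable_fixture <- function(n_pos = 30L, n_neg = 70L) {
  list(positives = make_windows(rep("AAAAAAKAAAAAA", n_pos), "positive",
                                protein_id = sprintf("pos%03d", seq_len(n_pos))),
       negatives = make_windows(rep("GGGGGGKGGGGGG", n_neg), "negative",
                                protein_id = sprintf("neg%03d", seq_len(n_neg))))
}

test_that("svm_config validates its parameters", {
  expect_error(svm_config(cost = 0), "cost")
  expect_error(svm_config(gamma = -1), "gamma")
  expect_equal(svm_config(cost = 4, gamma = 0.5)$cost, 4)
})

test_that("a separable toy problem is fit perfectly by the two layers", {
  fx <- separable_fixture()
  model <- suppressWarnings(
    train_two_layer(fx$positives, fx$negatives, encoder = "binary20",
                    seed = 1L))
  expect_s3_class(model, "two_layer_model")
  sc <- score_first_layer(model, rbind(fx$positives, fx$negatives))
  expect_equal(ncol(sc), length(model$first_layer))
  expect_true(all(sc >= 0 & sc <= 1))
  expect_gt(min(sc[seq_len(nrow(fx$positives)), 1]), 0.5)

  pred <- predict(model, rbind(fx$positives, fx$negatives))
  expect_true(all(pred$call[grepl("^pos", pred$protein_id)]))
  expect_false(any(pred$call[grepl("^neg", pred$protein_id)]))
})

test_that("first-layer sampling draws round(size * ratio) negatives", {
  fx <- separable_fixture(n_pos = 20L, n_neg = 100L)
  part <- mdd_partition(fx$positives)       # single leaf (no dependence)
  fl <- ubimotif:::train_first_layer(part, fx$negatives, "binary20",
                                     svm_config(), ratio = 2.33, seed = 1L)
  expect_equal(nrow(fl$sampled_negatives[[1]]), round(20 * 2.33))
})

test_that("undersized leaves merge into a sibling with a warning", {
  fx <- separable_fixture(n_pos = 24L)
  part <- mdd_partition(fx$positives)
  # fabricate a partition with one tiny leaf
  part$leaves <- list(Ub1 = fx$positives[1:20, ], Ub2 = fx$positives[21:24, ])
  part$constraints <- list(Ub1 = list(), Ub2 = list())
  part$sizes <- c(Ub1 = 20L, Ub2 = 4L)
  expect_warning(
    fl <- ubimotif:::train_first_layer(part, fx$negatives, "binary20",
                                       svm_config(), seed = 1L),
    "merged")
  expect_length(fl$fits, 1L)
})

test_that("prediction output contract: empty, sorted, deterministic", {
  fx <- separable_fixture()
  model <- suppressWarnings(
    train_two_layer(fx$positives, fx$negatives, seed = 3L))
  expect_equal(nrow(predict(model, annotated_protein("nok", "MAMAM"))), 0L)

  p <- annotated_protein("multi", "KAAAKAAAGGGGKAA")
  out <- predict(model, p)
  expect_equal(out$position, sort(out$position))
  expect_equal(nrow(out), 3L)

  model2 <- suppressWarnings(
    train_two_layer(fx$positives, fx$negatives, seed = 3L))
  expect_identical(predict(model2, p), out)
})

test_that("model bundles round-trip through save/load", {
  fx <- separable_fixture()
  model <- suppressWarnings(
    train_two_layer(fx$positives, fx$negatives, seed = 5L))
  probe <- random_windows(50, seed = 55)
  tf <- withr::local_tempfile(fileext = ".rds")
  save_model(model, tf)
  back <- load_model(tf)
  expect_identical(predict(back, probe), predict(model, probe))

  writeLines("garbage", tf)
  expect_error(load_model(tf), "model bundle")
  saveRDS(list(format = "ubimotif_two_layer_model", version = 999L,
               model = NULL), tf)
  expect_error(load_model(tf), "version")
})

test_that("grid search is exhaustive with deterministic tie-breaks", {
  fx <- separable_fixture(n_pos = 20L, n_neg = 30L)
  x <- encode_binary20(rbind(fx$positives, fx$negatives))
  y <- c(fx$positives$label, fx$negatives$label)
  one <- grid_search(x, y, c_grid = 2, gamma_grid = 0.1, k = 2, seed = 1L)
  expect_equal(one$cfg$cost, 2)
  expect_equal(one$cfg$gamma, 0.1)

  gs <- grid_search(x, y, c_grid = c(1, 4), gamma_grid = c(0.05, 0.2),
                    k = 2, seed = 1L)
  expect_equal(gs$accuracy, max(gs$grid$accuracy))
  # separable data: everything ties at 1 -> smallest cost, then gamma
  expect_equal(gs$cfg$cost, 1)
  expect_equal(gs$cfg$gamma, 0.05)
  expect_error(grid_search(x, y, numeric(0), 1, k = 2), "empty")
})

test_that("motif assignment tracks the planted class on positive calls", {
  # correspondence metric: each effective leaf is identified with the
  # planted class that dominates its training members; a called window
  # should be assigned a leaf of its own class
  tw <- training_windows(well_separated_spec(2L))
  model <- suppressWarnings(
    train_two_layer(tw$positives, tw$negatives, seed = 2L))
  gt <- tw$ground_truth
  key <- paste(gt$protein_id, gt$center_pos)
  pred <- predict(model, tw$positives)
  pred <- pred[pred$call, ]
  cls <- gt$class[match(paste(pred$protein_id, pred$position), key)]
  leaf_major <- vapply(model$leaves, function(lf) {
    lc <- gt$class[match(paste(lf$protein_id, lf$center_pos), key)]
    names(which.max(table(lc)))
  }, "")
  expect_gte(mean(leaf_major[pred$motif] == cls), 0.8)
})
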