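# Two-layered SVM model over MDD motif subgroups.
#
# Layer 1: one RBF-kernel SVM per motif subgroup, trained on the subgroup's
# positives against negatives sampled at ~1:2.33 from the negative pool
# (without replacement, disjointly across subgroups while the pool allows).
# Layer 2: an RBF SVM over the k-vector of first-layer probability
# estimates, trained on all positives plus the full negative pool. All
# probability estimates are LIBSVM's Platt-style calibrated outputs
# (e1071 with probability = TRUE).

#' SVM configuration
#'
#' @param cost Soft-margin cost `c` (> 0, default 1).
#' @param gamma RBF kernel width `gamma` (> 0). The default `NULL` uses
#'   the variance-scale heuristic `1 / (d * mean column variance)` of the
#'   training matrix, which adapts the kernel width to the encoding's
#'   spread (LIBSVM's fixed `1/d` is far too smooth for sparse one-hot
#'   features).
#' @return List of class `svm_config`.
#' @export
svm_config <- function(cost = 1, gamma = NULL) {
  stopifnot(cost > 0, is.null(gamma) || gamma > 0)
  structure(list(kernel = "radial", cost = cost, gamma = gamma,
                 probability = TRUE), class = "svm_config")
}

#' Fit a probability-estimating RBF SVM
#'
#' Thin wrapper used for every classifier in the package: radial kernel,
#' unscaled features (the encoders already produce `[0, 1]`-ranged
#' values), probability estimates enabled, and the [svm_config()] gamma
#' rule applied.
#'
#' @param x Feature matrix.
#' @param y Labels: factor or character over
#'   `{"negative", "positive"}`.
#' @param cfg An [svm_config()].
#' @return A fitted `e1071::svm` object.
#' @export
fit_rbf_svm <- function(x, y, cfg = svm_config()) {
  if (!is.factor(y)) y <- label_factor(as.character(y))
  stopifnot(nlevels(droplevels(y)) == 2L)
  gamma <- cfg$gamma
  if (is.null(gamma)) {
    v <- mean(apply(x, 2L, stats::var))
    gamma <- if (is.finite(v) && v > 0) 1 / (ncol(x) * v) else 1 / ncol(x)
  }
  e1071::svm(x = x, y = y, kernel = "radial", cost = cfg$cost,
             gamma = gamma, probability = TRUE, scale = FALSE)
}

#' @rdname fit_rbf_svm
#' @param fit A fitted `e1071::svm` from [fit_rbf_svm()].
#' @return `svm_probability` returns the positive-class probability
#'   estimates for the rows of `x`.
#' @export
svm_probability <- function(fit, x) {
  pr <- attr(stats::predict(fit, x, probability = TRUE), "probabilities")
  unname(pr[, "positive"])
}

label_factor <- function(label) {
  factor(label, levels = c("negative", "positive"))
}

#' Train the first layer of per-motif SVMs
#'
#' For each partition leaf, samples `round(leaf_size * ratio)` negatives
#' without replacement from the pool (disjointly across leaves while the
#' pool allows) and fits an RBF SVM with probability estimates on the
#' encoded windows. Leaves smaller than `min_leaf` are merged into the
#' preceding leaf with a warning.
#'
#' @param partition An [mdd_partition()] over the positive training windows.
#' @param negatives Negative window pool (disjoint from the positives).
#' @param encoder Encoder name ([encode_windows()]).
#' @param cfg An [svm_config()].
#' @param ratio Negatives per positive within each leaf (default 2.33).
#' @param seed Integer RNG seed.
#' @param state Encoder state ([fit_encoder_state()] output).
#' @param min_leaf Minimum trainable leaf size (default 10).
#' @return List with `fits` (one SVM per effective leaf), `leaves`
#'   (the possibly merged positive window sets) and `sampled_negatives`.
#' @keywords internal
train_first_layer <- function(partition, negatives, encoder, cfg,
                              ratio = 2.33, seed = 42L, state = list(),
                              min_leaf = 10L) {
  leaves <- partition$leaves
  # merge under-sized leaves into the preceding (nearest) sibling
  i <- 1L
  while (length(leaves) > 1L && i <= length(leaves)) {
    if (nrow(leaves[[i]]) < min_leaf) {
      tgt <- if (i > 1L) i - 1L else 2L
      warning(sprintf("leaf %s (%d windows) merged into %s",
                      names(leaves)[i], nrow(leaves[[i]]),
                      names(leaves)[tgt]), call. = FALSE)
      leaves[[tgt]] <- rbind(leaves[[tgt]], leaves[[i]])
      leaves[[i]] <- NULL
    } else i <- i + 1L
  }
  set.seed(seed)
  pool_idx <- sample.int(nrow(negatives))  # shuffled once; drawn disjointly
  taken <- 0L
  fits <- list(); sampled <- list()
  for (j in seq_along(leaves)) {
    want <- round(nrow(leaves[[j]]) * ratio)
    if (taken + want > length(pool_idx)) {          # pool exhausted:
      set.seed(seed + j)                            # fall back to overlap
      idx <- sample.int(nrow(negatives), min(want, nrow(negatives)))
    } else {
      idx <- pool_idx[(taken + 1L):(taken + want)]
      taken <- taken + want
    }
    neg_j <- negatives[idx, , drop = FALSE]
    win_j <- rbind(leaves[[j]], neg_j)
    x <- encode_windows(win_j, encoder, state)
    y <- label_factor(win_j$label)
    set.seed(seed + 1000L + j)
    fits[[j]] <- fit_rbf_svm(x, y, cfg)
    sampled[[j]] <- neg_j
  }
  names(fits) <- names(leaves)
  list(fits = fits, leaves = leaves, sampled_negatives = sampled)
}

#' Train a two-layered motif model
#'
#' Runs MDD over the positive windows (unless a partition is supplied),
#' trains the per-motif first layer, scores every training window through
#' it, and fits the second-layer combiner on the resulting k-dimensional
#' probability vectors (all positives plus the full negative pool).
#'
#' @param positives,negatives Window data frames (disjoint).
#' @param encoder Encoder name (default `"binary20"`).
#' @param cfg An [svm_config()].
#' @param partition Optional precomputed [mdd_partition()]; computed from
#'   `positives` when `NULL`.
#' @param ratio First-layer negatives per positive (default 2.33).
#' @param threshold Decision cutoff on the second-layer probability
#'   (default 0.5).
#' @param seed Integer RNG seed (default 42).
#' @param state Encoder state; fitted via [fit_encoder_state()] first.
#' @param combiner_scores How the second layer's training scores are
#'   produced: `"resubstitution"` (default) reuses the final first layer
#'   on its own training windows; `"out_of_fold"` scores each training
#'   window with first-layer SVMs retrained on the other inner folds,
#'   avoiding the optimistic bias of resubstitution scores at the cost of
#'   `inner_k` extra first-layer fits.
#' @param inner_k Inner folds for out-of-fold scoring (default 3).
#' @param ... Passed to [mdd_partition()] when the partition is computed
#'   here (`scheme`, `max_cluster_size`, `alpha`).
#' @return Object of class `two_layer_model`.
#' @export
train_two_layer <- function(positives, negatives, encoder = "binary20",
                            cfg = svm_config(), partition = NULL,
                            ratio = 2.33, threshold = 0.5, seed = 42L,
                            state = list(),
                            combiner_scores = c("resubstitution",
                                                "out_of_fold"),
                            inner_k = 3L, ...) {
  combiner_scores <- match.arg(combiner_scores)
  stopifnot(nrow(positives) > 0L, nrow(negatives) > 0L)
  state <- fit_encoder_state(encoder, positives, state)
  if (is.null(partition)) partition <- mdd_partition(positives, ...)
  fl <- train_first_layer(partition, negatives, encoder, cfg,
                          ratio = ratio, seed = seed, state = state)
  model <- structure(list(partition = partition, first_layer = fl$fits,
                          leaves = fl$leaves, encoder = encoder,
                          state = state, cfg = cfg, threshold = threshold,
                          seed = seed, second_layer = NULL,
                          version = MODEL_VERSION),
                     class = "two_layer_model")
  train_win <- rbind(positives, negatives)
  y <- label_factor(train_win$label)
  scores <- if (combiner_scores == "resubstitution")
    score_first_layer(model, train_win)
  else oof_first_layer_scores(model, fl$leaves, positives, negatives,
                              encoder, cfg, ratio, seed, state, inner_k)
  set.seed(seed + 99L)
  model$second_layer <- fit_rbf_svm(scores, y, cfg)
  model
}

# Out-of-fold first-layer scores for the combiner: for each inner fold,
# retrain every leaf SVM without the fold's windows and score only those.
# Score matrix rows follow rbind(positives, negatives) order.
oof_first_layer_scores <- function(model, leaves, positives, negatives,
                                   encoder, cfg, ratio, seed, state,
                                   inner_k) {
  set.seed(seed + 7L)
  fold_pos <- sample(rep_len(seq_len(inner_k), nrow(positives)))
  fold_neg <- sample(rep_len(seq_len(inner_k), nrow(negatives)))
  scores <- matrix(NA_real_, nrow(positives) + nrow(negatives),
                   length(leaves), dimnames = list(NULL, names(leaves)))
  pos_key <- paste(positives$protein_id, positives$center_pos)
  for (f in seq_len(inner_k)) {
    held_key <- pos_key[fold_pos == f]
    fold_leaves <- lapply(leaves, function(lf)
      lf[!(paste(lf$protein_id, lf$center_pos) %in% held_key), ,
         drop = FALSE])
    sub_part <- model$partition
    sub_part$leaves <- fold_leaves
    fl <- suppressWarnings(
      train_first_layer(sub_part, negatives[fold_neg != f, , drop = FALSE],
                        encoder, cfg, ratio = ratio, seed = seed + f,
                        state = state, min_leaf = 2L))
    sub_model <- model
    sub_model$first_layer <- fl$fits
    held <- c(fold_pos == f, fold_neg == f)
    sc <- score_first_layer(sub_model,
                            rbind(positives, negatives)[held, , drop = FALSE])
    scores[held, colnames(sc)] <- sc
  }
  scores[is.na(scores)] <- 0.5  # leaf dropped in a fold: neutral score
  scores
}

MODEL_VERSION <- 1L

#' First-layer probability estimates for windows
#'
#' @param model A `two_layer_model` (second layer may be unfitted).
#' @param windows Window data frame.
#' @return Numeric matrix, one row per window, one column per motif
#'   subgroup; entries in `[0, 1]`.
#' @export
score_first_layer <- function(model, windows) {
  stopifnot(inherits(model, "two_layer_model"))
  if (!length(model$first_layer)) stop("model has no trained first layer")
  x <- encode_windows(windows, model$encoder, model$state)
  out <- vapply(model$first_layer, svm_probability,
                numeric(nrow(windows)), x = x)
  if (nrow(windows) == 1L) out <- matrix(out, 1L,
                                         dimnames = list(NULL, names(model$first_layer)))
  out
}

#' Predict ubiquitylation sites on a protein
#'
#' Scores every lysine of the protein through both layers. The motif
#' assigned to a site is the subgroup whose first-layer SVM gives the
#' highest probability estimate.
#'
#' @param object A trained `two_layer_model`.
#' @param protein An [annotated_protein] (annotations, if any, are
#'   ignored), or a window data frame.
#' @param ... Unused.
#' @return Data frame with columns `protein_id`, `position`, `window`,
#'   `probability`, `call` (logical), `motif` and `motif_constraints`,
#'   sorted by position. Zero rows for a lysine-free protein.
#' @export
predict.two_layer_model <- function(object, protein, ...) {
  if (is.null(object$second_layer)) stop("model is not fully trained")
  windows <- if (inherits(protein, "annotated_protein"))
    extract_windows(protein, n = object$partition$leaves[[1]]$n[1])
  else protein
  if (!nrow(windows))
    return(data.frame(protein_id = character(0), position = integer(0),
                      window = character(0), probability = numeric(0),
                      call = logical(0), motif = character(0),
                      motif_constraints = character(0)))
  scores <- score_first_layer(object, windows)
  prob <- svm_probability(object$second_layer, scores)
  motif <- colnames(scores)[max.col(scores, ties.method = "first")]
  cons <- vapply(motif, function(m) {
    cns <- object$partition$constraints[[m]]
    if (is.null(cns) || !length(cns)) "(no constraint)"
    else paste(vapply(cns, constraint_text, ""), collapse = " AND ")
  }, "")
  out <- data.frame(protein_id = windows$protein_id,
                    position = windows$center_pos,
                    window = windows$residues,
                    probability = prob,
                    call = prob >= object$threshold,
                    motif = motif,
                    motif_constraints = unname(cons),
                    stringsAsFactors = FALSE)
  out[order(out$protein_id, out$position), , drop = FALSE]
}

#' @export
print.two_layer_model <- function(x, ...) {
  cat(sprintf("<two_layer_model> %d motif subgroup(s), encoder '%s', threshold %.2f\n",
              length(x$first_layer), x$encoder, x$threshold))
  invisible(x)
}

#' Grid search over SVM cost and gamma by cross-validated accuracy
#'
#' Exhaustive grid with stratified k-fold cross-validation at each point;
#' ties break toward smaller cost, then smaller gamma.
#'
#' @param x Feature matrix.
#' @param y Label factor or character (`"positive"`/`"negative"`).
#' @param c_grid,gamma_grid Numeric grids (non-empty); powers of 2 are the
#'   conventional choice, e.g. `2^(-2:4)`.
#' @param k Folds (default 5).
#' @param seed Integer RNG seed.
#' @return List with `cfg` (best [svm_config()]), `accuracy`, and the
#'   full `grid` data frame of CV accuracies.
#' @export
grid_search <- function(x, y, c_grid = 2^(-1:3), gamma_grid = 2^(-5:1),
                        k = 5L, seed = 42L) {
  if (!length(c_grid) || !length(gamma_grid)) stop("empty parameter grid")
  y <- label_factor(as.character(y))
  grid <- expand.grid(cost = sort(c_grid), gamma = sort(gamma_grid))
  grid$accuracy <- NA_real_
  for (i in seq_len(nrow(grid))) {
    cfg <- svm_config(cost = grid$cost[i], gamma = grid$gamma[i])
    cv <- kfold_cv(x, y, k = k, seed = seed,
                   train_fun = function(xt, yt) fit_rbf_svm(xt, yt, cfg),
                   predict_fun = function(fit, xt)
                     ifelse(svm_probability(fit, xt) >= 0.5, "positive", "negative"))
    grid$accuracy[i] <- cv$metrics$Acc
  }
  # order(): among equal accuracies the first row (smallest cost, then gamma)
  ord <- order(-grid$accuracy, grid$cost, grid$gamma)
  best <- grid[ord[1L], ]
  list(cfg = svm_config(cost = best$cost, gamma = best$gamma),
       accuracy = best$accuracy, grid = grid)
}

#' Save / load a two-layer model bundle
#'
#' The bundle is a versioned RDS archive carrying the partition, the
#' fitted SVMs, encoder name and state, configuration and seed; a
#' round-trip preserves predictions exactly.
#'
#' @param model A `two_layer_model`.
#' @param path File path.
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "two_layer_model"))
  saveRDS(list(format = "ubimotif_two_layer_model",
               version = MODEL_VERSION, model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("cannot read model bundle: ",
                                           conditionMessage(e)))
  if (!is.list(obj) || !identical(obj$format, "ubimotif_two_layer_model"))
    stop("not a ubimotif model bundle: ", path)
  if (!identical(obj$version, MODEL_VERSION))
    stop("model bundle version ", obj$version,
         " is not supported (expected ", MODEL_VERSION, ")")
  obj$model
}
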