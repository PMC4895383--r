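# Evaluation: confusion-matrix metrics, stratified k-fold cross-validation,
# position-specific two-sample composition analysis, and site-level
# case-study matching.

#' Confusion-matrix performance metrics
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy
#' `(TP+TN)/total` and the Matthews correlation coefficient
#' `(TP*TN - FN*FP) / sqrt((TP+FN)(TN+FP)(TP+FP)(TN+FN))`. MCC is defined
#' as 0 when any denominator factor vanishes.
#'
#' @param TP,TN,FP,FN Non-negative counts with positive total.
#' @return Object of class `metrics_report`: list with the four counts and
#'   `Sn`, `Sp`, `Acc`, `MCC`.
#' @export
metrics <- function(TP, TN, FP, FN) {
  if (any(c(TP, TN, FP, FN) < 0)) stop("counts must be non-negative")
  TP <- as.numeric(TP); TN <- as.numeric(TN)
  FP <- as.numeric(FP); FN <- as.numeric(FN)
  total <- TP + TN + FP + FN
  if (total == 0) stop("empty confusion matrix")
  denom <- (TP + FN) * (TN + FP) * (TP + FP) * (TN + FN)
  structure(list(
    TP = TP, TN = TN, FP = FP, FN = FN,
    Sn = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
    Sp = if (TN + FP > 0) TN / (TN + FP) else NA_real_,
    Acc = (TP + TN) / total,
    MCC = if (denom > 0) (TP * TN - FN * FP) / sqrt(denom) else 0
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("TP=%.0f TN=%.0f FP=%.0f FN=%.0f | Sn=%.4f Sp=%.4f Acc=%.4f MCC=%.4f\n",
              x$TP, x$TN, x$FP, x$FN, x$Sn, x$Sp, x$Acc, x$MCC))
  invisible(x)
}

# metrics from predicted/true label vectors ("positive"/"negative")
metrics_from_labels <- function(pred, truth) {
  metrics(TP = sum(pred == "positive" & truth == "positive"),
          TN = sum(pred == "negative" & truth == "negative"),
          FP = sum(pred == "positive" & truth == "negative"),
          FN = sum(pred == "negative" & truth == "positive"))
}

#' Stratified k-fold cross-validation
#'
#' Splits samples into k stratified folds (every fold holds both classes),
#' trains on k-1 folds and predicts the held-out fold, so each sample is
#' tested exactly once. Metrics are pooled over the union of held-out
#' predictions by default; per-fold reports are also returned.
#'
#' @param x Feature matrix (or any object `train_fun`/`predict_fun` index
#'   by row via `x[idx, , drop = FALSE]`).
#' @param y Labels (`"positive"`/`"negative"`, factor or character).
#' @param train_fun `function(x_train, y_train)` returning a fitted model.
#' @param predict_fun `function(model, x_test)` returning predicted labels.
#' @param k Number of folds (default 5).
#' @param seed Integer RNG seed controlling the fold assignment.
#' @param pool Pool held-out predictions into one confusion matrix
#'   (default) or average per-fold metrics.
#' @return List with `metrics` (a [metrics()] report; averaged fields when
#'   `pool = FALSE`), `fold` (assignment vector) and `per_fold`.
#' @export
kfold_cv <- function(x, y, train_fun, predict_fun, k = 5L, seed = 42L,
                     pool = TRUE) {
  stopifnot(k >= 2L)
  y <- as.character(y)
  n <- length(y)
  if (any(table(y) < k))
    stop("every class needs at least k = ", k, " members")
  set.seed(seed)
  fold <- integer(n)
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  pred <- character(n)
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    te <- which(fold == f); tr <- which(fold != f)
    fit <- train_fun(x[tr, , drop = FALSE], label_factor(y[tr]))
    pred[te] <- as.character(predict_fun(fit, x[te, , drop = FALSE]))
    per_fold[[f]] <- metrics_from_labels(pred[te], y[te])
  }
  m <- if (pool) metrics_from_labels(pred, y)
  else {
    avg <- function(field) mean(vapply(per_fold, `[[`, 0, field))
    structure(list(TP = NA, TN = NA, FP = NA, FN = NA, Sn = avg("Sn"),
                   Sp = avg("Sp"), Acc = avg("Acc"), MCC = avg("MCC")),
              class = "metrics_report")
  }
  list(metrics = m, fold = fold, per_fold = per_fold, predictions = pred)
}

#' Cross-validated comparison of a full model pipeline
#'
#' Convenience wrapper running [kfold_cv()] at the window level with a
#' trainer that rebuilds the whole model (including any motif partition)
#' within each training fold, so no held-out window influences training.
#'
#' @param positives,negatives Window data frames.
#' @param trainer `function(positives, negatives)` returning an object
#'   with a `predict` method producing a `call` column on windows.
#' @param k,seed As in [kfold_cv()].
#' @return As [kfold_cv()].
#' @export
kfold_cv_windows <- function(positives, negatives, trainer, k = 5L,
                             seed = 42L) {
  win <- rbind(positives, negatives)
  kfold_cv(win, win$label, k = k, seed = seed,
           train_fun = function(w, yl) {
             trainer(w[w$label == "positive", , drop = FALSE],
                     w[w$label == "negative", , drop = FALSE])
           },
           predict_fun = function(model, w) {
             p <- stats::predict(model, w)
             p <- p[match(paste(w$protein_id, w$center_pos),
                          paste(p$protein_id, p$position)), ]
             ifelse(p$call, "positive", "negative")
           })
}

#' Position-specific residue enrichment between two window sets
#'
#' For every non-centre position and each of the 20 amino acids, compares
#' the residue frequency in positives against negatives with a
#' two-proportion z-test (pooled variance, no continuity correction) and
#' flags cells as enriched or depleted at `alpha`.
#'
#' @param pos_windows,neg_windows Non-empty window data frames of equal
#'   window length.
#' @param alpha Significance level (default 0.01).
#' @return Data frame with one row per (position, residue): `position`
#'   (signed, centre excluded), `residue`, `freq_pos`, `freq_neg`, `diff`,
#'   `p`, `call` (`"enriched"`, `"depleted"` or `"ns"`).
#' @export
two_sample_logo <- function(pos_windows, neg_windows, alpha = 0.01) {
  if (!nrow(pos_windows) || !nrow(neg_windows))
    stop("both window sets must be non-empty")
  pm <- window_matrix(pos_windows); nm <- window_matrix(neg_windows)
  if (ncol(pm) != ncol(nm)) stop("window lengths differ")
  L <- ncol(pm); half <- (L + 1L) %/% 2L
  n1 <- nrow(pm); n2 <- nrow(nm)
  aa <- aa_alphabet()
  rows <- list()
  for (p in setdiff(seq_len(L), half)) {
    for (r in aa) {
      x1 <- sum(pm[, p] == r); x2 <- sum(nm[, p] == r)
      p1 <- x1 / n1; p2 <- x2 / n2
      pool <- (x1 + x2) / (n1 + n2)
      se <- sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
      pval <- if (se == 0) 1 else 2 * stats::pnorm(-abs((p1 - p2) / se))
      rows[[length(rows) + 1L]] <- data.frame(
        position = p - half, residue = r, freq_pos = p1, freq_neg = p2,
        diff = p1 - p2, p = pval,
        call = if (pval < alpha) (if (p1 > p2) "enriched" else "depleted")
               else "ns",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Match predicted against experimental site positions
#'
#' Set arithmetic of a site-level case study: true positives are the
#' intersection, false positives the predictions absent from the
#' experimental list, false negatives the experimental sites missed.
#' Precision is reported as a percentage of the predicted sites.
#'
#' @param predicted,experimental Integer vectors of 1-based positions.
#' @return List with `TP`, `FP`, `FN` (sorted integer vectors) and
#'   `precision` (percent; `NA` with a warning when nothing is predicted).
#' @export
match_site_predictions <- function(predicted, experimental) {
  predicted <- sort(unique(as.integer(predicted)))
  experimental <- sort(unique(as.integer(experimental)))
  if (length(c(predicted, experimental)) &&
      any(c(predicted, experimental) < 1L))
    stop("positions must be positive integers")
  tp <- intersect(predicted, experimental)
  res <- list(TP = tp,
              FP = setdiff(predicted, experimental),
              FN = setdiff(experimental, predicted),
              precision = NA_real_)
  if (!length(predicted))
    warning("no predicted sites; precision undefined", call. = FALSE)
  else res$precision <- 100 * length(tp) / length(predicted)
  res
}
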