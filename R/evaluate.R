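#' Confusion counts
#'
#' @param TP,TN,FP,FN nonnegative integer counts.
#' @return a `confusion_counts` list.
#' @export
confusion_counts <- function(TP, TN, FP, FN) {
  counts <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  if (any(counts < 0)) stop("negative confusion count", call. = FALSE)
  structure(as.list(counts), class = "confusion_counts")
}

#' Confusion counts from truth and prediction
#'
#' @param truth,pred character vectors over "positive"/"negative".
#' @return a `confusion_counts`.
#' @export
confusion_from_labels <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  confusion_counts(
    TP = sum(truth == "positive" & pred == "positive"),
    TN = sum(truth == "negative" & pred == "negative"),
    FP = sum(truth == "negative" & pred == "positive"),
    FN = sum(truth == "positive" & pred == "negative"))
}

add_counts <- function(a, b) {
  confusion_counts(a$TP + b$TP, a$TN + b$TN, a$FP + b$FP, a$FN + b$FN)
}

safe_ratio <- function(num, den) if (den == 0) 0 else num / den

#' The six performance measures from confusion counts
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP), accuracy
#' (TP+TN)/total, positive predictive value TP/(TP+FP), negative
#' predictive value TN/(TN+FN) and the Matthews correlation coefficient
#' (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)).  Any measure
#' whose denominator is zero is reported as 0 by convention so batch
#' evaluations survive degenerate groups.
#'
#' @param counts a [confusion_counts()].
#' @return a `metric_set`: named list with sensitivity, specificity,
#'   accuracy, ppv, npv (proportions in \[0, 1\]) and mcc in \[-1, 1\].
#' @export
metrics <- function(counts) {
  TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  total <- TP + TN + FP + FN
  if (total < 1) stop("all confusion counts are zero", call. = FALSE)
  mcc_den <- sqrt(as.numeric(TP + FP) * (TP + FN) * (TN + FP) * (TN + FN))
  structure(list(
    sensitivity = safe_ratio(TP, TP + FN),
    specificity = safe_ratio(TN, TN + FP),
    accuracy = (TP + TN) / total,
    ppv = safe_ratio(TP, TP + FP),
    npv = safe_ratio(TN, TN + FN),
    mcc = if (mcc_den == 0) 0 else (TP * TN - FP * FN) / mcc_den,
    counts = counts), class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf(paste0("sensitivity %6.2f%%  specificity %6.2f%%  accuracy %6.2f%%\n",
                     "ppv         %6.2f%%  npv         %6.2f%%  mcc      %6.3f\n"),
              100 * x$sensitivity, 100 * x$specificity, 100 * x$accuracy,
              100 * x$ppv, 100 * x$npv, x$mcc))
  invisible(x)
}

#' ROC curve and AUC from decision values
#'
#' Sweeps the threshold over the unique decision values; the area under
#' the curve is computed by the trapezoid rule.
#'
#' @param labels character truth labels ("positive"/"negative").
#' @param decision numeric scores, larger meaning more positive.
#' @return a `roc_curve`: list with `points` (data.frame fpr, tpr,
#'   threshold) and `auc`.
#' @export
roc_curve <- function(labels, decision) {
  stopifnot(length(labels) == length(decision))
  np <- sum(labels == "positive"); nn <- sum(labels == "negative")
  if (np == 0L || nn == 0L)
    stop("ROC requires both classes", call. = FALSE)
  ord <- order(decision, decreasing = TRUE)
  lab <- labels[ord]; dec <- decision[ord]
  tp <- cumsum(lab == "positive")
  fp <- cumsum(lab == "negative")
  last <- c(dec[-1L] != dec[-length(dec)], TRUE)  # collapse score ties
  tpr <- c(0, tp[last] / np)
  fpr <- c(0, fp[last] / nn)
  auc <- sum(diff(fpr) * (head(tpr, -1L) + tpr[-1L]) / 2)
  structure(list(points = data.frame(fpr = fpr, tpr = tpr,
                                     threshold = c(Inf, dec[last])),
                 auc = auc), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve: %d points, AUC %.4f>\n", nrow(x$points), x$auc))
  invisible(x)
}

#' Write ROC points as two-column text
#' @param roc a `roc_curve`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_roc <- function(roc, path) {
  utils::write.table(roc$points[, c("fpr", "tpr")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

## length-safe permutation (sample(x) on a length-1 integer would
## permute 1:x instead)
shuffle <- function(x) x[sample.int(length(x))]

## stratified fold assignment: within each class a seeded shuffle, fold
## ids continuing cyclically across classes so no fold is left empty
## (k = n gives leave-one-out)
stratified_folds <- function(y, k, seed) {
  stopifnot(k >= 2L, k <= length(y))
  fold_id <- integer(length(y))
  offset <- 0L
  withr::with_seed(seed, {
    for (cls in unique(y)) {
      idx <- shuffle(which(y == cls))
      fold_id[idx] <- ((offset + seq_along(idx) - 1L) %% k) + 1L
      offset <- offset + length(idx)
    }
  })
  fold_id
}

## shared single-split evaluation: build PWMs on train, encode, fit,
## predict test
evaluate_split <- function(train, test, config, blocks, alpha, scale,
                           protein = NULL) {
  pos <- train[record_labels(train) == "positive"]
  neg <- train[record_labels(train) == "negative"]
  if (length(pos) == 0L || length(neg) == 0L)
    stop("a training split lacks one class", call. = FALSE)
  mpwm <- build_pwm(pos, neg, k = 1L, alpha = alpha)
  dpwm <- build_pwm(pos, neg, k = 2L, alpha = alpha)
  enc_train <- encode_set(train, mpwm, dpwm, blocks = blocks,
                          protein = protein)
  enc_test <- encode_set(test, mpwm, dpwm, blocks = blocks,
                         protein = protein)
  model <- svm_train(enc_train, config = config, scale = scale)
  pred <- svm_predict(model, enc_test)
  list(counts = confusion_from_labels(record_labels(test), pred$labels),
       truth = record_labels(test), decision = pred$decision)
}

#' Stratified k-fold cross-validation of the full pipeline
#'
#' For every fold the PWMs are rebuilt from the training folds only, all
#' sequences re-encoded against them, the SVM retrained, and the held-out
#' fold predicted; confusion counts are pooled over folds and the metric
#' set computed from the pooled counts (fold-averaged metrics are also
#' returned for comparison).
#'
#' @param data a [labeled_set()] or list of [seq_record()].
#' @param k number of folds (default 10).
#' @param seed integer seed for the stratified fold split.
#' @param config an [svm_config()].
#' @param blocks RNA feature blocks (see [encode_rna()]).
#' @param alpha PWM pseudocount.
#' @param scale logical, feature rescaling.
#' @param protein optional per-RBP protein CTD map (see [encode_set()]).
#' @return list with `metrics` (pooled [metrics()]), `roc`
#'   ([roc_curve()] over pooled decision values), `fold_counts`
#'   (data.frame, one row per fold) and `fold_metrics` (averaged).
#' @export
kfold_cv <- function(data, k = 10L, seed = 1L, config = svm_config(),
                     blocks = c("mpwm", "dpwm", "composition"),
                     alpha = 1, scale = TRUE, protein = NULL) {
  records <- dataset_records(data)
  stopifnot(k >= 2L)
  y <- record_labels(records)
  fold_id <- stratified_folds(y, k, seed)
  pooled <- confusion_counts(0L, 0L, 0L, 0L)
  truth_all <- character(0); dec_all <- numeric(0)
  fold_rows <- vector("list", k)
  for (f in seq_len(k)) {
    res <- evaluate_split(records[fold_id != f], records[fold_id == f],
                          config, blocks, alpha, scale, protein)
    pooled <- add_counts(pooled, res$counts)
    truth_all <- c(truth_all, res$truth)
    dec_all <- c(dec_all, res$decision)
    fold_rows[[f]] <- data.frame(fold = f, TP = res$counts$TP,
                                 TN = res$counts$TN, FP = res$counts$FP,
                                 FN = res$counts$FN)
  }
  fold_counts <- do.call(rbind, fold_rows)
  fold_metrics <- colMeans(do.call(rbind, lapply(seq_len(k), function(f) {
    m <- metrics(confusion_counts(fold_counts$TP[f], fold_counts$TN[f],
                                  fold_counts$FP[f], fold_counts$FN[f]))
    unlist(m[c("sensitivity", "specificity", "accuracy", "ppv", "npv",
               "mcc")])
  })))
  list(metrics = metrics(pooled), roc = roc_curve(truth_all, dec_all),
       fold_counts = fold_counts, fold_metrics = fold_metrics)
}

#' Leave-one-protein-out cross-validation
#'
#' Every RBP group in turn forms the test set (both its binding and
#' non-binding sequences); PWMs and the SVM are rebuilt from the
#' remaining groups.  The weighted-average metric set is computed from
#' the summed TP/TN/FP/FN over all runs, never by averaging per-group
#' metrics.  Negative records without an RBP tag are assigned to groups
#' round-robin.
#'
#' @inheritParams kfold_cv
#' @return list with `per_group` (data.frame: group, counts, metrics),
#'   `metrics` (pooled, weighted-average [metrics()]), `counts` (pooled
#'   [confusion_counts()]) and `flagged` (groups holding a single class).
#' @export
lopo_cv <- function(data, config = svm_config(),
                    blocks = c("mpwm", "dpwm", "composition"),
                    alpha = 1, scale = TRUE, protein = NULL) {
  records <- dataset_records(data)
  rbps <- record_rbps(records)
  untagged <- which(is.na(rbps) | !nzchar(rbps))
  groups <- sort(unique(rbps[!is.na(rbps) & nzchar(rbps)]))
  if (length(groups) < 2L)
    stop("leave-one-protein-out needs at least 2 RBP groups", call. = FALSE)
  rbps[untagged] <- groups[((seq_along(untagged) - 1L) %% length(groups)) + 1L]
  pooled <- confusion_counts(0L, 0L, 0L, 0L)
  rows <- vector("list", length(groups))
  flagged <- character(0)
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    test <- records[rbps == g]
    train <- records[rbps != g]
    if (length(unique(record_labels(test))) < 2L) flagged <- c(flagged, g)
    res <- evaluate_split(train, test, config, blocks, alpha, scale,
                          protein)
    m <- metrics(res$counts)
    pooled <- add_counts(pooled, res$counts)
    rows[[gi]] <- data.frame(
      rbp = g, TP = res$counts$TP, TN = res$counts$TN, FP = res$counts$FP,
      FN = res$counts$FN, sensitivity = m$sensitivity,
      specificity = m$specificity, accuracy = m$accuracy, ppv = m$ppv,
      npv = m$npv, mcc = m$mcc)
  }
  list(per_group = do.call(rbind, rows), metrics = metrics(pooled),
       counts = pooled, flagged = flagged)
}

#' Tab-separated evaluation report
#'
#' One row per fold or group plus a pooled row, mirroring the standard
#' LOPO report layout (counts then the six measures).
#'
#' @param result a [lopo_cv()] or [kfold_cv()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path) {
  if (!is.null(result$per_group)) {
    tab <- result$per_group
    id_col <- "rbp"
  } else {
    tab <- result$fold_counts
    tab <- cbind(tab, t(vapply(seq_len(nrow(tab)), function(f) {
      m <- metrics(confusion_counts(tab$TP[f], tab$TN[f], tab$FP[f],
                                    tab$FN[f]))
      unlist(m[c("sensitivity", "specificity", "accuracy", "ppv", "npv",
                 "mcc")])
    }, c(sensitivity = 0, specificity = 0, accuracy = 0, ppv = 0,
         npv = 0, mcc = 0))))
    id_col <- "fold"
  }
  pm <- result$metrics
  pooled <- data.frame(id = "pooled", TP = pm$counts$TP, TN = pm$counts$TN,
                       FP = pm$counts$FP, FN = pm$counts$FN,
                       sensitivity = pm$sensitivity,
                       specificity = pm$specificity, accuracy = pm$accuracy,
                       ppv = pm$ppv, npv = pm$npv, mcc = pm$mcc)
  names(pooled)[1L] <- id_col
  utils::write.table(rbind(tab, pooled), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
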