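test_that("metrics are exact ratios with the zero-denominator convention", {
  m <- metrics(confusion_counts(3, 7, 0, 1))
  expect_equal(m$accuracy, 10 / 11)
  expect_equal(m$mcc, 21 / sqrt(672), tolerance = 1e-12)

  perfect <- metrics(confusion_counts(5, 5, 0, 0))
  expect_equal(unlist(perfect[c("sensitivity", "specificity", "accuracy",
                                "ppv", "npv", "mcc")]),
               c(sensitivity = 1, specificity = 1, accuracy = 1, ppv = 1,
                 npv = 1, mcc = 1))

  # no positive calls at all: ppv denominator is 0 -> reported as 0
  degenerate <- metrics(confusion_counts(0, 5, 0, 5))
  expect_equal(degenerate$ppv, 0)
  expect_equal(degenerate$mcc, 0)

  expect_error(metrics(confusion_counts(0, 0, 0, 0)), "zero")
  expect_error(confusion_counts(-1, 0, 0, 0), "negative")
})

test_that("swapping the classes swaps sensitivity/specificity and ppv/npv", {
  set.seed(41)
  for (i in 1:10) {
    counts <- as.list(sample(1:200, 4))
    names(counts) <- c("TP", "TN", "FP", "FN")
    m <- metrics(do.call(confusion_counts, counts))
    swapped <- metrics(confusion_counts(TP = counts$TN, TN = counts$TP,
                                        FP = counts$FN, FN = counts$FP))
    expect_equal(swapped$sensitivity, m$specificity)
    expect_equal(swapped$specificity, m$sensitivity)
    expect_equal(swapped$ppv, m$npv)
    expect_equal(swapped$npv, m$ppv)
    expect_equal(swapped$accuracy, m$accuracy)
    expect_equal(swapped$mcc, m$mcc)
  }
})

test_that("ROC construction spans perfect, anti-ranked and random scores", {
  lab <- c(rep("positive", 5), rep("negative", 5))
  expect_equal(roc_curve(lab, 10:1)$auc, 1.0)
  expect_equal(roc_curve(lab, 1:10)$auc, 0.0)

  set.seed(42)
  lab2 <- rep(c("positive", "negative"), 1000)
  r <- roc_curve(lab2, rnorm(2000))
  expect_true(abs(r$auc - 0.5) < 0.05)
  expect_true(all(diff(r$points$fpr) >= 0))
  expect_true(all(diff(r$points$tpr) >= 0))

  expect_error(roc_curve(rep("positive", 4), 1:4), "both classes")
})

test_that("in-package AUC matches the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(43)
  lab <- sample(c("positive", "negative"), 300, replace = TRUE)
  dec <- rnorm(300) + (lab == "positive")
  ours <- roc_curve(lab, dec)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = factor(lab, levels = c("negative", "positive")),
    predictor = dec, quiet = TRUE, direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("k-fold CV pools counts over folds and supports the leave-one-out limit", {
  strong <- motif_model(consensus_prob = 0.97)
  small <- synth_generate(strong, n_pos = 80, n_neg = 80, n_groups = 4,
                          seed = 51)
  res <- kfold_cv(small, k = 4, seed = 52)
  expect_equal(sum(res$fold_counts$TP + res$fold_counts$TN +
                     res$fold_counts$FP + res$fold_counts$FN), 160)
  pooled <- metrics(confusion_counts(sum(res$fold_counts$TP),
                                     sum(res$fold_counts$TN),
                                     sum(res$fold_counts$FP),
                                     sum(res$fold_counts$FN)))
  expect_equal(res$metrics$accuracy, pooled$accuracy)
  expect_gt(res$metrics$accuracy, 0.95)

  # k = dataset size behaves as leave-one-out
  tiny <- synth_generate(strong, n_pos = 8, n_neg = 8, n_groups = 2,
                         seed = 53)
  loo <- kfold_cv(tiny, k = 16, seed = 54)
  expect_equal(nrow(loo$fold_counts), 16L)
  expect_true(all(rowSums(loo$fold_counts[, c("TP", "TN", "FP", "FN")]) == 1))
})

test_that("permuting the labels drives pooled MCC to zero", {
  set <- synth_generate(n_pos = 300, n_neg = 300, n_groups = 4, seed = 55)
  permuted <- lapply(seq_along(set$records), function(i) {
    r <- set$records[[i]]
    r$label <- c("positive", "negative")[(i %% 2) + 1]
    r
  })
  # alternate labels irrespective of motif content
  res <- kfold_cv(labeled_set(permuted), k = 5, seed = 56)
  expect_lt(abs(res$metrics$mcc), 0.1)
})

test_that("LOPO weighted averages come from pooled counts, not metric means", {
  # pooling arithmetic on hand-built group counts
  g1 <- confusion_counts(1, 1, 0, 0)
  g2 <- confusion_counts(0, 1, 1, 1)
  pooled <- metrics(confusion_counts(g1$TP + g2$TP, g1$TN + g2$TN,
                                     g1$FP + g2$FP, g1$FN + g2$FN))
  expect_equal(pooled$sensitivity, 1 / 2)
  # pooled counts weight groups by size: accuracy is 3/5, not the
  # per-group metric mean (1 + 1/3)/2 = 2/3
  expect_equal(pooled$accuracy, 3 / 5)
  expect_false(isTRUE(all.equal(
    pooled$accuracy,
    mean(c(metrics(g1)$accuracy, metrics(g2)$accuracy)))))

  set <- synth_generate(n_pos = 150, n_neg = 150, n_groups = 5, seed = 57)
  res <- lopo_cv(set)
  expect_equal(nrow(res$per_group), 5L)
  expect_equal(sum(res$per_group$TP + res$per_group$TN + res$per_group$FP +
                     res$per_group$FN), 300)
  recomputed <- metrics(confusion_counts(sum(res$per_group$TP),
                                         sum(res$per_group$TN),
                                         sum(res$per_group$FP),
                                         sum(res$per_group$FN)))
  expect_equal(res$metrics$mcc, recomputed$mcc)
  expect_equal(res$metrics$sensitivity, recomputed$sensitivity)
})

test_that("LOPO flags single-class groups and assigns untagged negatives round-robin", {
  strong <- motif_model(consensus_prob = 0.97)
  set <- synth_generate(strong, n_pos = 60, n_neg = 60, n_groups = 3,
                        seed = 58)
  # strip tags from negatives and convert one group to positives only
  recs <- lapply(set$records, function(r) {
    if (r$label == "negative") r$rbp <- NA_character_
    r
  })
  res <- lopo_cv(labeled_set(recs))
  expect_equal(nrow(res$per_group), 3L)
  expect_equal(sum(res$per_group$TP + res$per_group$TN + res$per_group$FP +
                     res$per_group$FN), 120)

  negs <- recs[record_labels(recs) == "negative"]
  negs <- lapply(seq_along(negs), function(i) {
    r <- negs[[i]]
    r$rbp <- c("RBP01", "RBP02")[(i %% 2) + 1]  # leave RBP03 positives-only
    r
  })
  res2 <- lopo_cv(labeled_set(c(recs[record_labels(recs) == "positive"],
                                negs)))
  expect_equal(res2$flagged, "RBP03")
})

test_that("evaluation reports carry per-run rows plus a pooled row that recomputes", {
  strong <- motif_model(consensus_prob = 0.97)
  set <- synth_generate(strong, n_pos = 40, n_neg = 40, n_groups = 2,
                        seed = 59)
  res <- kfold_cv(set, k = 4, seed = 60)
  path <- tempfile(fileext = ".tsv")
  write_report(res, path)
  tab <- read.delim(path)
  expect_equal(nrow(tab), 5L)  # 4 folds + pooled
  pooled_row <- tab[tab$fold == "pooled", ]
  m <- metrics(confusion_counts(sum(tab$TP[tab$fold != "pooled"]),
                                sum(tab$TN[tab$fold != "pooled"]),
                                sum(tab$FP[tab$fold != "pooled"]),
                                sum(tab$FN[tab$fold != "pooled"])))
  expect_equal(pooled_row$accuracy, m$accuracy, tolerance = 1e-9)
  expect_equal(pooled_row$mcc, m$mcc, tolerance = 1e-9)
})
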