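#' SVM configuration
#'
#' Kernel parameters of the soft-margin classifier.  The defaults
#' (Gaussian radial-basis kernel, C = 32, gamma = 0.0078125 = 2^-7) are
#' the grid-search optimum used throughout the study design; a linear
#' kernel is reachable for sensitivity checks.
#'
#' @param C positive soft-margin cost.
#' @param gamma positive RBF kernel width.
#' @param kernel `"radial"` or `"linear"`.
#' @return an `svm_config`.
#' @export
svm_config <- function(C = 32, gamma = 0.0078125, kernel = c("radial", "linear")) {
  kernel <- match.arg(kernel)
  stopifnot(C > 0, gamma > 0)
  structure(list(C = C, gamma = gamma, kernel = kernel),
            class = "svm_config")
}

## per-feature linear scaling to [-1, 1]; constant features map to 0
fit_scaler <- function(x) {
  mins <- apply(x, 2L, min)
  maxs <- apply(x, 2L, max)
  span <- maxs - mins
  span[span == 0] <- 1
  list(mins = mins, span = span, constant = maxs == mins)
}

apply_scaler <- function(scaler, x) {
  x <- sweep(x, 2L, scaler$mins, "-")
  x <- sweep(x, 2L, scaler$span, "/")
  x <- 2 * x - 1
  if (any(scaler$constant)) x[, scaler$constant] <- 0
  x
}

#' Train the binding-region classifier
#'
#' Fits a C-classification SVM (libsvm via e1071) on encoded feature
#' vectors.  Features are linearly rescaled to \[-1, 1\] using the
#' minimum/maximum of the training data only; the scaling state travels
#' with the model and is re-applied at prediction time.
#'
#' @param x numeric feature matrix (rows = instances), or the list
#'   returned by [encode_set()].
#' @param y labels: "positive"/"negative" (or a factor with those
#'   levels).  Ignored when `x` is an [encode_set()] result carrying
#'   labels.
#' @param config an [svm_config()].
#' @param scale logical; disable the \[-1, 1\] rescaling for sensitivity
#'   checks.
#' @param layout optional block layout; stored and enforced at
#'   prediction.
#' @return a `trained_model`.
#' @export
svm_train <- function(x, y = NULL, config = svm_config(), scale = TRUE,
                      layout = NULL) {
  if (is.list(x) && !is.data.frame(x) && !is.null(x$x)) {
    if (is.null(y)) y <- x$labels
    if (is.null(layout)) layout <- x$layout
    x <- x$x
  }
  x <- as.matrix(x)
  y <- factor(as.character(y), levels = c("positive", "negative"))
  if (anyNA(y)) stop("labels must be 'positive' or 'negative'", call. = FALSE)
  if (nrow(x) != length(y)) stop("|x| != |y|", call. = FALSE)
  if (nlevels(droplevels(y)) < 2L)
    stop("training data contains a single class", call. = FALSE)
  scaler <- if (scale) fit_scaler(x) else NULL
  xs <- if (scale) apply_scaler(scaler, x) else x
  fit <- e1071::svm(xs, y, type = "C-classification",
                    kernel = config$kernel, cost = config$C,
                    gamma = config$gamma, scale = FALSE)
  structure(list(fit = fit, scaler = scaler, config = config,
                 n_features = ncol(x), layout = layout),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model: %s kernel, C=%g, gamma=%g, %d features, %d SVs%s>\n",
              x$config$kernel, x$config$C, x$config$gamma, x$n_features,
              x$fit$tot.nSV, if (is.null(x$scaler)) ", unscaled" else ""))
  invisible(x)
}

#' Predict binding labels and decision values
#'
#' Decision values are oriented so that positive values mean the
#' "positive" (binding) class; the label is the sign of the decision
#' value.
#'
#' @param model a `trained_model`.
#' @param x feature matrix with the layout the model was trained on, or
#'   an [encode_set()] result.
#' @return list with `labels` (character) and `decision` (numeric).
#' @export
svm_predict <- function(model, x) {
  layout <- NULL
  if (is.list(x) && !is.data.frame(x) && !is.null(x$x)) {
    layout <- x$layout
    x <- x$x
  }
  x <- as.matrix(x)
  if (ncol(x) != model$n_features) {
    stop("feature layout mismatch: model expects ", model$n_features,
         " features, got ", ncol(x), call. = FALSE)
  }
  if (!is.null(layout) && !is.null(model$layout) &&
      !identical(layout$block, model$layout$block)) {
    stop("feature block layout differs from the training layout",
         call. = FALSE)
  }
  xs <- if (!is.null(model$scaler)) apply_scaler(model$scaler, x) else x
  pred <- stats::predict(model$fit, xs, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  sign_flip <- if (grepl("^positive/", colnames(dv)[1L])) 1 else -1
  decision <- sign_flip * as.numeric(dv[, 1L])
  list(labels = ifelse(decision > 0, "positive", "negative"),
       decision = decision)
}

#' Grid search over (C, gamma)
#'
#' Exhaustive cross-validated accuracy over the Cartesian product of the
#' two grids; the libsvm-style defaults are powers of two, C in
#' 2^-5..2^15 and gamma in 2^-15..2^3 (exponent step 2).  Ties are broken
#' toward the smaller C, then the smaller gamma.
#'
#' @param x feature matrix.
#' @param y labels.
#' @param C_grid,gamma_grid candidate values.
#' @param folds number of stratified CV folds.
#' @param seed integer seed for the fold split (shared by all pairs).
#' @param scale passed to [svm_train()].
#' @return the winning [svm_config()], with the full result table in
#'   attribute `"grid"`.
#' @export
grid_search <- function(x, y, C_grid = 2^seq(-5, 15, 2),
                        gamma_grid = 2^seq(-15, 3, 2), folds = 5L,
                        seed = 1L, scale = TRUE) {
  stopifnot(length(C_grid) > 0, length(gamma_grid) > 0)
  x <- as.matrix(x)
  y <- as.character(y)
  fold_id <- stratified_folds(y, folds, seed)
  grid <- expand.grid(C = sort(C_grid), gamma = sort(gamma_grid),
                      KEEP.OUT.ATTRS = FALSE)
  grid$accuracy <- vapply(seq_len(nrow(grid)), function(i) {
    cfg <- svm_config(C = grid$C[i], gamma = grid$gamma[i])
    correct <- 0L
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      m <- svm_train(x[tr, , drop = FALSE], y[tr], cfg, scale = scale)
      p <- svm_predict(m, x[!tr, , drop = FALSE])
      correct <- correct + sum(p$labels == y[!tr])
    }
    correct / length(y)
  }, numeric(1))
  best <- grid[order(-grid$accuracy, grid$C, grid$gamma), ][1L, ]
  out <- svm_config(C = best$C, gamma = best$gamma)
  attr(out, "grid") <- grid
  out
}

#' Persist a trained model to a file
#' @param model a `trained_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' Load a model saved by [save_model()]
#' @param path model file.
#' @return a `trained_model`.
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "trained_model")) stop("not a trained_model: ", path,
                                          call. = FALSE)
  m
}
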