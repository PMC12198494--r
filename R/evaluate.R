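#' Area under the ROC curve (Mann-Whitney form)
#'
#' The probability that a uniformly chosen positive sample outscores a
#' uniformly chosen negative one, ties counting one half — computed from
#' midranks, equivalent to the trapezoidal area under the ROC curve.
#' The positive class is the second factor level (so `1` for 0/1 labels).
#' Scores should be continuous decision values, not thresholded labels.
#'
#' @param scores numeric decision scores, higher meaning more positive.
#' @param labels binary labels, both classes present.
#' @return AUC in `[0, 1]`.
#' @examples
#' roc_auc(c(0.9, 0.6, 0.4, 0.2), c(1, 0, 1, 0))  # 0.75
#' @export
roc_auc <- function(scores, labels) {
  labels <- as_binary_factor(labels)
  if (length(scores) != length(labels))
    stop("scores and labels must have the same length", call. = FALSE)
  pos <- labels == levels(labels)[2L]
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present to compute AUC", call. = FALSE)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}

#' Matthews correlation coefficient
#'
#' The correlation between predicted and true binary labels computed from
#' the confusion matrix, robust to class imbalance:
#' \eqn{(TP \cdot TN - FP \cdot FN) / \sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}.
#' By convention a zero marginal (e.g. a constant predictor) yields 0,
#' i.e. as good as random.
#'
#' @param pred predicted binary labels.
#' @param labels true binary labels (defines the level coding; `pred` is
#'   matched against it).
#' @return MCC in `[-1, 1]`.
#' @export
mcc <- function(pred, labels) {
  labels <- as_binary_factor(labels)
  pred <- factor(pred, levels = levels(labels))
  if (anyNA(pred))
    stop("pred contains labels outside the label set", call. = FALSE)
  if (length(pred) != length(labels))
    stop("pred and labels must have the same length", call. = FALSE)
  pos <- levels(labels)[2L]
  tp <- sum(pred == pos & labels == pos)
  tn <- sum(pred != pos & labels != pos)
  fp <- sum(pred == pos & labels != pos)
  fn <- sum(pred != pos & labels == pos)
  mcc_from_counts(tp, tn, fp, fn)
}

mcc_from_counts <- function(tp, tn, fp, fn) {
  denom <- sqrt(as.double(tp + fp)) * sqrt(as.double(tp + fn)) *
    sqrt(as.double(tn + fp)) * sqrt(as.double(tn + fn))
  if (denom == 0) return(0)
  (as.double(tp) * tn - as.double(fp) * fn) / denom
}

#' Cross-validated evaluation of a HABiC classifier
#'
#' Runs one of two stratified protocols and reports per-split ROC AUC
#' (from continuous decision margins) and MCC (from predicted labels),
#' with their means and standard deviations. `protocol = "kfold"` is
#' stratified k-fold cross-validation (the default for synthetic
#' benchmarks); `protocol = "holdout"` repeats `n_repeats` independent
#' stratified train/test splits at `train_frac` (70/30 by default). In
#' every split the training side is balanced by random undersampling
#' before fitting; the test side is left untouched.
#'
#' @param x,y data and binary labels, as in [habic()].
#' @param k number of folds for `"kfold"`; both classes must have at
#'   least `k` members.
#' @param protocol `"kfold"` or `"holdout"`.
#' @param n_repeats,train_frac holdout protocol parameters.
#' @param seed master seed; folds, balancing and fits all derive from it,
#'   so reports are fully reproducible.
#' @param fit_fun optional custom fitter `function(x, y, seed)` returning
#'   an object whose `predict` supports `type = "margin"` and
#'   `type = "class"`; by default [habic()] with the extra arguments in
#'   `...`.
#' @param ... passed to [habic()] (e.g. `variant`, `q`).
#' @return An object of class `"habic_cv"`: list with `per_split` (data
#'   frame of split, auc, mcc), `auc_mean`, `auc_sd`, `mcc_mean`,
#'   `mcc_sd`, `protocol`, `seed`.
#' @examples
#' d <- generate_classification(n_obs = 60, n_vars = 20, n_informative = 2,
#'                              class_sep = 3, seed = 7)
#' habic_cv(d$x, d$y, k = 3, seed = 1)
#' @export
habic_cv <- function(x, y, k = 5L, protocol = c("kfold", "holdout"),
                     n_repeats = 5L, train_frac = 0.7, seed = 1L,
                     fit_fun = NULL, ...) {
  protocol <- match.arg(protocol)
  x <- as_feature_matrix(x)
  y <- as_binary_factor(y)
  if (nrow(x) != length(y))
    stop("x and y must have the same number of samples", call. = FALSE)
  if (is.null(fit_fun))
    fit_fun <- function(x, y, seed) habic(x, y, seed = seed, ...)
  idx_by_class <- split(seq_along(y), y)
  splits <- if (protocol == "kfold") {
    if (any(lengths(idx_by_class) < k))
      stop(sprintf("each class needs at least k = %d members for stratified folds",
                   k), call. = FALSE)
    folds <- with_seed(seed, {
      f <- integer(length(y))
      for (cl in idx_by_class)
        f[sample(cl)] <- rep_len(seq_len(k), length(cl))
      f
    })
    lapply(seq_len(k), function(i) which(folds == i))
  } else {
    if (any(lengths(idx_by_class) < 2L))
      stop("each class needs at least 2 members", call. = FALSE)
    with_seed(seed, lapply(seq_len(n_repeats), function(i) {
      unlist(lapply(idx_by_class, function(cl) {
        n_test <- max(1L, round((1 - train_frac) * length(cl)))
        sample(cl, n_test)
      }), use.names = FALSE)
    }))
  }
  seeds <- child_seeds(seed, 2L * length(splits))
  res <- lapply(seq_along(splits), function(i) {
    test <- splits[[i]]
    train <- setdiff(seq_along(y), test)
    b <- balance_classes(x[train, , drop = FALSE], y[train],
                         seed = seeds[2L * i - 1L])
    fit <- fit_fun(b$x, b$y, seed = seeds[2L * i])
    margin <- predict(fit, x[test, , drop = FALSE], type = "margin")
    cls <- predict(fit, x[test, , drop = FALSE], type = "class")
    c(auc = roc_auc(margin, y[test]), mcc = mcc(cls, y[test]))
  })
  per_split <- data.frame(split = seq_along(res),
                          auc = vapply(res, `[[`, numeric(1), "auc"),
                          mcc = vapply(res, `[[`, numeric(1), "mcc"))
  structure(list(per_split = per_split,
                 auc_mean = mean(per_split$auc), auc_sd = sd(per_split$auc),
                 mcc_mean = mean(per_split$mcc), mcc_sd = sd(per_split$mcc),
                 protocol = if (protocol == "kfold")
                   sprintf("%d-fold stratified CV", length(splits))
                 else sprintf("%d-repeat stratified %.0f/%.0f holdout",
                              n_repeats, 100 * train_frac,
                              100 * (1 - train_frac)),
                 seed = as.integer(seed)),
            class = "habic_cv")
}

#' @export
print.habic_cv <- function(x, ...) {
  cat(sprintf("HABiC evaluation, %s (seed %d)\n", x$protocol, x$seed))
  cat(sprintf("  AUC: %.3f +/- %.3f\n", x$auc_mean, x$auc_sd))
  cat(sprintf("  MCC: %.3f +/- %.3f\n", x$mcc_mean, x$mcc_sd))
  invisible(x)
}
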