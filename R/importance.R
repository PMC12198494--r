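#' PLS-DA variable importance
#'
#' Fits a PLS regression of the 0/1 class indicator on the features
#' (training-set centering, no scaling) and returns the absolute
#' regression coefficient of each feature at the final component —
#' "variables of importance" are the ones with the highest model
#' coefficients in absolute value. Constant feature columns get zero
#' importance.
#'
#' @param x numeric matrix, samples in rows.
#' @param y binary labels (two-level factor or coercible).
#' @param ncomp number of PLS components.
#' @return Named numeric vector of importances, one per column of `x`.
#' @export
plsda_importance <- function(x, y, ncomp = 2L) {
  x <- as_feature_matrix(x)
  yf <- as_binary_factor(y)
  if (nrow(x) != length(yf))
    stop("x and y must have the same number of samples", call. = FALSE)
  nm <- colnames(x)
  if (is.null(nm)) nm <- paste0("V", seq_len(ncol(x)))
  imp <- stats::setNames(numeric(ncol(x)), nm)
  keep <- which(apply(x, 2L, function(v) diff(range(v)) > 0))
  if (length(keep) < 1L) return(imp)
  xm <- x[, keep, drop = FALSE]
  colnames(xm) <- paste0("V", keep)   # unique internal identifiers
  ncomp <- min(as.integer(ncomp), length(keep), nrow(xm) - 1L)
  fit <- mixOmics::pls(xm, as.numeric(yf) - 1, ncomp = ncomp,
                       mode = "regression", scale = FALSE)
  b <- predict(fit, xm[1L, , drop = FALSE])$B.hat
  imp[keep] <- abs(b[, 1L, ncomp])
  imp
}

# Random-forest impurity importance for the bagging filter: a
# default-parameter forest of 100 trees, mean decrease in Gini impurity.
rf_importance <- function(x, y, ntree = 100L, seed = 1L) {
  yf <- as_binary_factor(y)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  fit <- with_seed(seed,
    randomForest::randomForest(x, yf, ntree = ntree))
  imp <- fit$importance[, "MeanDecreaseGini"]
  stats::setNames(as.numeric(imp), colnames(x))
}
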