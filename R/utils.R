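# Internal helpers: seeded evaluation, label normalisation, input checks.

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Independent child seeds spawned from one master seed (kept < 2^31).
child_seeds <- function(seed, n) {
  with_seed(seed, sample.int(2147483646L, n))
}

# Coerce to a finite numeric matrix, with a named error on failure.
as_feature_matrix <- function(x, what = "x") {
  x <- as.matrix(x)
  if (!is.numeric(x))
    stop(sprintf("'%s' must be a numeric matrix", what), call. = FALSE)
  if (!all(is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1L, ]
    stop(sprintf("'%s' contains a non-finite value at row %d, column %d",
                 what, bad[1L], bad[2L]), call. = FALSE)
  }
  x
}

# Normalise labels to a 2-level factor. Numeric 0/1 keeps 0 as the first
# level; anything else uses factor level order (or an explicit `positive`
# level placed second).
as_binary_factor <- function(y, positive = NULL) {
  if (is.factor(y)) y <- droplevels(y)
  else y <- factor(y)
  lv <- levels(y)
  if (length(lv) != 2L)
    stop(sprintf("labels must have exactly 2 classes, got %d (%s)",
                 length(lv), paste(head(lv, 5L), collapse = ", ")),
         call. = FALSE)
  if (!is.null(positive)) {
    if (!positive %in% lv)
      stop(sprintf("positive class '%s' not among labels (%s)",
                   positive, paste(lv, collapse = ", ")), call. = FALSE)
    y <- factor(y, levels = c(setdiff(lv, positive), positive))
  }
  y
}

# Align a query matrix to the feature names a model was fitted with.
align_features <- function(newdata, features, p) {
  newdata <- as_feature_matrix(newdata, "newdata")
  if (!is.null(features) && !is.null(colnames(newdata))) {
    missing <- setdiff(features, colnames(newdata))
    if (length(missing) > 0L)
      stop(sprintf("newdata is missing %d training feature(s); first missing: '%s'",
                   length(missing), missing[1L]), call. = FALSE)
    newdata <- newdata[, features, drop = FALSE]
  } else if (ncol(newdata) != p) {
    stop(sprintf("newdata has %d features but the model was fitted with %d",
                 ncol(newdata), p), call. = FALSE)
  }
  newdata
}

rowwise_max <- function(m) {
  m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
}
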