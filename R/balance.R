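#' Balance classes by random undersampling
#'
#' Removes samples from the majority class by picking, uniformly at random
#' and without replacement, as many of its rows as the minority class has.
#' The minority class is untouched. Exactly balanced classes are a hard
#' precondition of the assignment solve, which pairs observations one to
#' one.
#'
#' @param x numeric feature matrix, samples in rows.
#' @param y binary labels (two-level factor, or values coercible to one).
#' @param seed integer seed; the result is deterministic given the seed.
#' @return A list with the undersampled `x`, `y`, and `idx`, the retained
#'   row indices of the original matrix (in original order).
#' @export
balance_classes <- function(x, y, seed = 1L) {
  x <- as_feature_matrix(x)
  y <- as_binary_factor(y)
  if (nrow(x) != length(y))
    stop("x and y must have the same number of samples", call. = FALSE)
  cnt <- table(y)
  if (any(cnt == 0L)) stop("both classes must be non-empty", call. = FALSE)
  n_min <- min(cnt)
  keep <- with_seed(seed, {
    unlist(lapply(levels(y), function(lv) {
      rows <- which(y == lv)
      if (length(rows) > n_min) sort(sample(rows, n_min)) else rows
    }), use.names = FALSE)
  })
  keep <- sort(keep)
  list(x = x[keep, , drop = FALSE], y = droplevels(y[keep]), idx = keep)
}
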