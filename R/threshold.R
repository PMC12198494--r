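#' Decision-threshold configuration
#'
#' Builds the threshold specification consumed by [habic()]. Two families
#' are available. The aggregation family places the threshold midway
#' between trimmed class-score means: `method = "aggregate_pct"` averages
#' the top `value`% of the high-scoring class's training scores and the
#' bottom `value`% of the low-scoring class's (at the default
#' `value = 100` this is simply the midpoint of the two class means, the
#' variant retained as the package default for its robustness/speed
#' balance); `"aggregate_k"` uses the top/bottom `value` scores instead of
#' a percentage. The criterion-optimization family (`method = "optimize"`)
#' reserves a stratified fraction of the training set, scores it, and
#' picks the threshold from the grid of midpoints between consecutive
#' held-out scores that optimizes `criterion`.
#'
#' @param method one of `"aggregate_pct"`, `"aggregate_k"`, `"optimize"`.
#' @param value percentage in (0, 100] for `"aggregate_pct"`, or a positive
#'   count for `"aggregate_k"`; ignored for `"optimize"`.
#' @param criterion for `"optimize"`: `"mcc"` or `"accuracy"` (maximized),
#'   or `"roc01_distance"` (distance to the ideal ROC corner, minimized).
#' @param holdout_frac for `"optimize"`: fraction of the training set used
#'   to fit the optimizer; the remainder selects the threshold.
#' @return A list of class `"habic_threshold"`.
#' @export
threshold_control <- function(method = c("aggregate_pct", "aggregate_k",
                                         "optimize"),
                              value = 100,
                              criterion = c("mcc", "roc01_distance",
                                            "accuracy"),
                              holdout_frac = 0.75) {
  method <- match.arg(method)
  criterion <- match.arg(criterion)
  if (method == "aggregate_pct" && (value <= 0 || value > 100))
    stop("'value' must be a percentage in (0, 100]", call. = FALSE)
  if (method == "aggregate_k" && (value < 1 || value != round(value)))
    stop("'value' must be a positive integer count for aggregate_k",
         call. = FALSE)
  if (holdout_frac <= 0 || holdout_frac >= 1)
    stop("'holdout_frac' must be in (0, 1)", call. = FALSE)
  structure(list(method = method, value = value, criterion = criterion,
                 holdout_frac = holdout_frac),
            class = "habic_threshold")
}

#' Compute the decision threshold from class-wise scores
#'
#' `scores_high` are the training (or held-out) scores of the class the
#' optimizer scores high, `scores_low` those of the other class. See
#' [threshold_control()] for the methods. When all supplied scores are
#' identical the threshold is degenerate (no separation); it is returned
#' with a warning and attribute `degenerate = TRUE`.
#'
#' @param scores_high,scores_low numeric score vectors, both non-empty.
#' @inheritParams threshold_control
#' @return The threshold `alpha`, a single number.
#' @examples
#' compute_threshold(c(3, 2, 1), c(-1, -2, -3))                          # 0
#' compute_threshold(c(3, 2, 1), c(-1, -2, -3), "aggregate_k", value = 1) # 0
#' @export
compute_threshold <- function(scores_high, scores_low,
                              method = c("aggregate_pct", "aggregate_k",
                                         "optimize"),
                              value = 100,
                              criterion = c("mcc", "roc01_distance",
                                            "accuracy")) {
  method <- match.arg(method)
  criterion <- match.arg(criterion)
  if (length(scores_high) == 0L || length(scores_low) == 0L)
    stop("both score vectors must be non-empty", call. = FALSE)
  alpha <- switch(method,
    aggregate_pct = {
      if (value <= 0 || value > 100)
        stop("'value' must be a percentage in (0, 100]", call. = FALSE)
      kh <- max(1L, round(value / 100 * length(scores_high)))
      kl <- max(1L, round(value / 100 * length(scores_low)))
      (mean(sort(scores_high, decreasing = TRUE)[seq_len(kh)]) +
         mean(sort(scores_low)[seq_len(kl)])) / 2
    },
    aggregate_k = {
      k <- as.integer(value)
      if (k < 1L || k > min(length(scores_high), length(scores_low)))
        stop(sprintf("k = %d out of range: classes have %d and %d scores",
                     k, length(scores_high), length(scores_low)),
             call. = FALSE)
      (mean(sort(scores_high, decreasing = TRUE)[seq_len(k)]) +
         mean(sort(scores_low)[seq_len(k)])) / 2
    },
    optimize = {
      s <- sort(unique(c(scores_high, scores_low)))
      grid <- if (length(s) == 1L) s else (s[-length(s)] + s[-1L]) / 2
      vals <- vapply(grid, function(a) {
        tp <- sum(scores_high > a); fn <- length(scores_high) - tp
        fp <- sum(scores_low > a);  tn <- length(scores_low) - fp
        switch(criterion,
               accuracy = (tp + tn) / (tp + tn + fp + fn),
               mcc = mcc_from_counts(tp, tn, fp, fn),
               roc01_distance = -sqrt((1 - tp / (tp + fn))^2 +
                                        (fp / (fp + tn))^2))
      }, numeric(1))
      grid[which.max(vals)]
    })
  if (max(scores_high, scores_low) == min(scores_high, scores_low)) {
    warning("degenerate threshold: all scores identical, no separation",
            call. = FALSE)
    attr(alpha, "degenerate") <- TRUE
  }
  alpha
}
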