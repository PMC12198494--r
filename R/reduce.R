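#' Knee of a cumulative curve
#'
#' Returns the index of the point with the largest perpendicular distance
#' to the chord joining the first and last points of the curve — the
#' standard geometric "elbow" heuristic. An exactly linear curve has no
#' knee and returns 1.
#'
#' @param curve numeric vector, typically a cumulative explained-variance
#'   curve (non-decreasing).
#' @return Integer index of the knee.
#' @examples
#' knee_point(c(0.5, 0.9, 0.95, 0.97, 0.99, 1.0))  # 2
#' @export
knee_point <- function(curve) {
  k <- length(curve)
  if (k < 3L) return(1L)
  x <- seq_len(k)
  dx <- k - 1
  dy <- curve[k] - curve[1L]
  len <- sqrt(dx^2 + dy^2)
  # signed perpendicular distance of (x, curve) to the first-last chord
  d <- abs(dy * (x - 1) - dx * (curve - curve[1L])) / len
  if (max(d) < 1e-12) return(1L)
  which.max(d)
}

#' Choose a component count by the PCA elbow method
#'
#' Fits a PCA (training-set centering, no scaling), computes the
#' cumulative explained-variance curve over up to `max_components`
#' components, and returns the knee of that curve ([knee_point()]). This
#' drives the default component count of the reduction-regularized
#' classifier variants; the same PCA-based count is used whether the
#' subsequent projection is PCA or PLS-DA.
#'
#' @param x numeric matrix, samples in rows.
#' @param max_components upper bound on the number of components examined;
#'   default `min(n - 1, p)`.
#' @return Integer number of components.
#' @export
elbow_components <- function(x, max_components = NULL) {
  x <- as_feature_matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 samples", call. = FALSE)
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  ev <- ev[ev > max(ev) * 1e-12]
  if (length(ev) == 0L || max(ev) == 0)
    stop("degenerate input: zero variance in every direction", call. = FALSE)
  if (!is.null(max_components)) ev <- ev[seq_len(min(max_components, length(ev)))]
  knee_point(cumsum(ev) / sum(ev))
}

# Reduction-regularized fit: project (PCA or PLS-DA, fitted on training
# data only, centering but no scaling) then fit the naive classifier in
# the reduced coordinates.
fit_reduced_model <- function(x, yf, method, n_components, q, threshold,
                              seed, ncomp_pls, chunk_size) {
  if (identical(n_components, "elbow")) {
    n_components <- elbow_components(x)
  }
  n_components <- as.integer(n_components)
  max_rank <- min(nrow(x) - 1L, ncol(x))
  if (n_components > max_rank) {
    warning(sprintf("n_components = %d exceeds the data rank bound %d; clipped",
                    n_components, max_rank), call. = FALSE)
    n_components <- max_rank
  }
  if (method == "pca") {
    pc <- prcomp(x, center = TRUE, scale. = FALSE)
    n_components <- min(n_components, ncol(pc$rotation))
    reducer <- list(method = "pca", n_components = n_components,
                    center = pc$center,
                    rotation = pc$rotation[, seq_len(n_components),
                                           drop = FALSE])
  } else {
    xm <- x
    colnames(xm) <- paste0("V", seq_len(ncol(xm)))  # unique internal ids
    fit <- mixOmics::plsda(xm, yf, ncomp = n_components, scale = FALSE)
    reducer <- list(method = "plsda", n_components = n_components,
                    fit = fit, feature_names = colnames(xm))
  }
  z <- project_reducer(reducer, x)
  base <- fit_kr_model(z, yf, q = q, threshold = threshold, seed = seed,
                       chunk_size = chunk_size)
  base$reducer <- reducer
  base
}

project_reducer <- function(reducer, newdata) {
  if (reducer$method == "pca") {
    scale(newdata, center = reducer$center, scale = FALSE) %*%
      reducer$rotation
  } else {
    colnames(newdata) <- reducer$feature_names
    pr <- predict(reducer$fit, newdata)
    pr$variates[, seq_len(reducer$n_components), drop = FALSE]
  }
}
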