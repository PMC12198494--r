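#' Fit an exact-Wasserstein binary classifier
#'
#' Fits the HABiC classifier: the decision function is the
#' Kantorovich-Rubinstein optimizer of the 1-Wasserstein distance between
#' the two class-conditional empirical distributions, recovered exactly
#' from the dual potentials of a linear-sum-assignment solve on the
#' Minkowski-q cost matrix and extended to new points by an averaged
#' 1-Lipschitz extension. A point is assigned to the class whose training
#' scores sit on the same side of the decision threshold `alpha`.
#'
#' Variants: `"naive"` is the plain classifier. `"redPCA"` / `"redPLS"`
#' first project onto `n_components` PCA or PLS-DA components (fitted on
#' the training data only) and fit the naive classifier in the reduced
#' space. `"bagSTD"` / `"bagRF"` / `"bagPLS"` fit `B` naive classifiers on
#' stratified bootstrap resamples and random feature subsets of size
#' `mtry` (default `floor(sqrt(p))`), the RF/PLS flavours additionally
#' keeping only the `n_keep` most important drawn features (random-forest
#' impurity or absolute PLS-DA coefficients), and predict by majority
#' vote.
#'
#' The assignment pairs observations one to one, so the classes must be
#' exactly balanced; by default the majority class is undersampled at fit
#' time (with a warning) via [balance_classes()].
#'
#' Which class scores high is not fixed by the label coding: the
#' orientation is learned as the class with the higher mean training
#' score, making the decision rule invariant to swapping the label
#' convention.
#'
#' @param x numeric feature matrix, samples in rows. Column names, when
#'   present, are recorded and used to align features at prediction time.
#' @param y binary labels: a two-level factor, or values coercible to one
#'   (e.g. 0/1).
#' @param variant one of `"naive"`, `"redPCA"`, `"redPLS"`, `"bagSTD"`,
#'   `"bagRF"`, `"bagPLS"`.
#' @param q Minkowski order of the ground metric; `q = 1` (Manhattan) is
#'   the default, best suited to high-dimensional expression-like data.
#' @param threshold a [threshold_control()] specification.
#' @param balance undersample the majority class automatically (default
#'   `TRUE`); with `FALSE`, unbalanced input is an error.
#' @param seed integer seed driving balancing, bootstraps and any internal
#'   splits; fits are deterministic given data and seed.
#' @param n_components for reduction variants: a count, or `"elbow"`
#'   (default) to choose it by the knee of the PCA cumulative
#'   explained-variance curve (see [elbow_components()]).
#' @param B number of bagged members.
#' @param mtry number of features drawn per member; default
#'   `floor(sqrt(p))`.
#' @param n_keep number of important features kept per member
#'   (`bagRF`/`bagPLS`).
#' @param importance_fraction if set (e.g. `0.7`), overrides `n_keep`:
#'   keep the smallest importance-ranked prefix reaching this fraction of
#'   the member's total importance.
#' @param ncomp_pls number of PLS-DA components used for importance
#'   ranking and the `redPLS` projection default.
#' @param chunk_size query rows per distance block when scoring.
#' @return An object of class `"habic"` with `print`, `summary`,
#'   [predict.habic()] and `plot` methods.
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(40, -1), 20), matrix(rnorm(40, 1), 20))
#' y <- rep(0:1, each = 20)
#' fit <- habic(x, y, seed = 1)
#' table(predict(fit, x), y)
#' @seealso [habic_cv()] for cross-validated evaluation,
#'   [generate_classification()] for synthetic benchmarks.
#' @export
habic <- function(x, y,
                  variant = c("naive", "redPCA", "redPLS",
                              "bagSTD", "bagRF", "bagPLS"),
                  q = 1,
                  threshold = threshold_control(),
                  balance = TRUE,
                  seed = 1L,
                  n_components = "elbow",
                  B = 100L,
                  mtry = NULL,
                  n_keep = 3L,
                  importance_fraction = NULL,
                  ncomp_pls = 2L,
                  chunk_size = 256L) {
  variant <- match.arg(variant)
  stopifnot(inherits(threshold, "habic_threshold"))
  x <- as_feature_matrix(x)
  y <- as_binary_factor(y)
  if (nrow(x) != length(y))
    stop("x and y must have the same number of samples", call. = FALSE)
  cnt <- table(y)
  if (any(cnt < 1L)) stop("both classes must be present", call. = FALSE)
  seeds <- child_seeds(seed, 3L)
  if (cnt[1L] != cnt[2L]) {
    if (!balance)
      stop(sprintf(
        "classes are unbalanced (%d vs %d); set balance = TRUE or undersample first",
        cnt[1L], cnt[2L]), call. = FALSE)
    warning(sprintf(
      "unbalanced classes (%d vs %d): undersampling the majority class to %d",
      cnt[1L], cnt[2L], min(cnt)), call. = FALSE)
    b <- balance_classes(x, y, seed = seeds[1L])
    x <- b$x
    y <- b$y
  }
  if (min(table(y)) < 2L && variant != "naive")
    stop("regularized variants need at least 2 samples per class",
         call. = FALSE)

  model <- switch(variant,
    naive = fit_kr_model(x, y, q = q, threshold = threshold,
                         seed = seeds[2L], chunk_size = chunk_size),
    redPCA = ,
    redPLS = fit_reduced_model(x, y, method = if (variant == "redPCA") "pca"
                                              else "plsda",
                               n_components = n_components, q = q,
                               threshold = threshold, seed = seeds[2L],
                               ncomp_pls = ncomp_pls,
                               chunk_size = chunk_size),
    bagSTD = ,
    bagRF = ,
    bagPLS = fit_bagged_model(x, y,
                              filter = switch(variant, bagSTD = "none",
                                              bagRF = "rf", bagPLS = "pls"),
                              B = B, mtry = mtry, n_keep = n_keep,
                              importance_fraction = importance_fraction,
                              q = q, threshold = threshold,
                              seed = seeds[2L], ncomp_pls = ncomp_pls,
                              chunk_size = chunk_size))
  model$variant <- variant
  model$levels <- levels(y)
  model$q <- q
  model$seed <- seed
  model$n <- nrow(x)
  model$p <- ncol(x)
  model$features <- colnames(x)
  model$threshold_config <- threshold
  class(model) <- "habic"
  model
}

# Core naive fit on an exactly balanced, validated (x, yf).
fit_kr_model <- function(x, yf, q, threshold, seed, chunk_size) {
  lv <- levels(yf)
  i0 <- which(yf == lv[1L])
  i1 <- which(yf == lv[2L])
  if (length(i0) != length(i1))
    stop(sprintf("classes must be exactly balanced for the assignment solve (%d vs %d)",
                 length(i0), length(i1)), call. = FALSE)
  degenerate <- length(i0) < 2L

  if (threshold$method == "optimize") {
    n0 <- length(i0)
    nfit <- max(1L, floor(threshold$holdout_frac * n0))
    if (nfit >= n0)
      stop("not enough samples per class to reserve a threshold holdout",
           call. = FALSE)
    pick <- with_seed(seed, list(f0 = sample(i0, nfit), f1 = sample(i1, nfit)))
    h0 <- setdiff(i0, pick$f0)
    h1 <- setdiff(i1, pick$f1)
    core <- fit_kr_core(x[pick$f0, , drop = FALSE], x[pick$f1, , drop = FALSE],
                        q, lv)
    s_h0 <- predict(core$optimizer, x[h0, , drop = FALSE],
                    chunk_size = chunk_size)
    s_h1 <- predict(core$optimizer, x[h1, , drop = FALSE],
                    chunk_size = chunk_size)
    held <- if (core$high_class == lv[1L]) list(s_h0, s_h1) else list(s_h1, s_h0)
    alpha <- compute_threshold(held[[1L]], held[[2L]], method = "optimize",
                               criterion = threshold$criterion)
  } else {
    core <- fit_kr_core(x[i0, , drop = FALSE], x[i1, , drop = FALSE], q, lv)
    s <- core$train_scores
    high <- core$high_class
    low <- setdiff(lv, high)
    alpha <- compute_threshold(s[[high]], s[[low]], method = threshold$method,
                               value = threshold$value)
  }
  c(core, list(alpha = as.numeric(alpha), degenerate = degenerate,
               chunk_size = chunk_size))
}

fit_kr_core <- function(x0, x1, q, lv) {
  cost <- minkowski_cost(x0, x1, q)
  plan <- solve_assignment(cost)
  opt <- kr_optimizer(x0, x1, plan, q)
  s0 <- plan$psi      # g-hat at class-0 support, by construction
  s1 <- -plan$phi     # g-hat at class-1 support
  train_scores <- stats::setNames(list(s0, s1), lv)
  high_class <- if (mean(s0) >= mean(s1)) lv[1L] else lv[2L]
  list(optimizer = opt, w1 = plan$w1, train_scores = train_scores,
       high_class = high_class)
}

#' Predict from a fitted HABiC model
#'
#' @param object a fitted [habic()] model.
#' @param newdata numeric matrix of query points; when both the model and
#'   `newdata` carry feature names, columns are aligned by name and every
#'   training feature must be present.
#' @param type `"class"` for predicted labels; `"score"` for the raw KR
#'   optimizer value \eqn{\hat g(t)} (naive and reduction variants);
#'   `"margin"` for the orientation-signed decision margin, positive
#'   toward the second factor level (bagged variants report the mean
#'   member margin); `"components"` for the two one-sided extensions
#'   (naive variant only).
#' @param ... unused.
#' @details Ties (`score == alpha` exactly) go to the low-score class.
#'   For bagged models each member votes on its own feature subset and the
#'   majority wins; an exact vote tie is broken by the sign of the summed
#'   member margins.
#' @return A factor of labels, or a numeric vector/matrix of scores.
#' @export
predict.habic <- function(object, newdata,
                          type = c("class", "score", "margin", "components"),
                          ...) {
  type <- match.arg(type)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- align_features(newdata, object$features, object$p)
  lv <- object$levels
  if (object$variant %in% c("bagSTD", "bagRF", "bagPLS"))
    return(predict_bagged(object, newdata, type))
  z <- if (object$variant %in% c("redPCA", "redPLS"))
    project_reducer(object$reducer, newdata) else newdata
  if (type == "components") {
    if (!object$variant %in% c("naive"))
      stop("components are only available for the naive variant",
           call. = FALSE)
    return(predict(object$optimizer, z, type = "components",
                   chunk_size = object$chunk_size))
  }
  g <- predict(object$optimizer, z, chunk_size = object$chunk_size)
  if (type == "score") return(g)
  if (type == "margin")
    return((g - object$alpha) * if (object$high_class == lv[2L]) 1 else -1)
  low <- setdiff(lv, object$high_class)
  factor(ifelse(g > object$alpha, object$high_class, low), levels = lv)
}

#' @export
print.habic <- function(x, ...) {
  cat(sprintf("HABiC classifier (variant: %s)\n", x$variant))
  cat(sprintf("  %d training samples, %d features, q = %g\n", x$n, x$p, x$q))
  if (!is.null(x$w1))
    cat(sprintf("  empirical W1 between classes: %.6g\n", x$w1))
  if (!is.null(x$alpha))
    cat(sprintf("  threshold alpha = %.6g, high-score class: '%s'\n",
                x$alpha, x$high_class))
  if (!is.null(x$members))
    cat(sprintf("  %d bagged members, %d features drawn each\n",
                length(x$members), x$mtry))
  if (!is.null(x$reducer))
    cat(sprintf("  %s reduction to %d components\n",
                toupper(x$reducer$method), x$reducer$n_components))
  invisible(x)
}

#' @export
summary.habic <- function(object, ...) {
  print(object)
  if (!is.null(object$train_scores)) {
    s <- object$train_scores
    cat("  training scores by class:\n")
    for (lv in names(s))
      cat(sprintf("    %s: mean %.4g, range [%.4g, %.4g]\n",
                  lv, mean(s[[lv]]), min(s[[lv]]), max(s[[lv]])))
  }
  invisible(object)
}

#' Plot training score distributions of a fitted model
#'
#' Overlaid histograms of the two classes' training scores with the
#' decision threshold, for naive and reduction variants.
#'
#' @param x a fitted [habic()] model with training scores.
#' @param ... passed to [graphics::hist()].
#' @return `x`, invisibly.
#' @export
plot.habic <- function(x, ...) {
  if (is.null(x$train_scores))
    stop("no training scores stored for this variant", call. = FALSE)
  s <- x$train_scores
  rng <- range(unlist(s))
  br <- seq(rng[1L], rng[2L], length.out = 30L)
  h1 <- hist(s[[1L]], breaks = br, plot = FALSE)
  h2 <- hist(s[[2L]], breaks = br, plot = FALSE)
  ylim <- c(0, max(h1$counts, h2$counts))
  hist(s[[1L]], breaks = br, col = grDevices::adjustcolor("steelblue", 0.6),
       ylim = ylim, xlab = "KR optimizer score", main = "Training scores",
       ...)
  hist(s[[2L]], breaks = br, col = grDevices::adjustcolor("firebrick", 0.6),
       add = TRUE)
  abline(v = x$alpha, lwd = 2, lty = 2)
  legend("topright", legend = c(names(s), "alpha"),
         fill = c("steelblue", "firebrick", NA), border = NA,
         lty = c(NA, NA, 2), bty = "n")
  invisible(x)
}
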