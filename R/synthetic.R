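#' Generate a synthetic binary classification benchmark
#'
#' Produces an arbitrary classification problem with controlled counts of
#' informative, redundant and noise variables, emulating the widely used
#' hypercube generator: class clusters are standard Gaussians placed at
#' distinct vertices of a hypercube of side `2 * class_sep` in the
#' informative subspace, mixed by a random uniform(-1, 1) within-cluster
#' covariance transform; redundant features are random linear combinations
#' of the informative ones (pure collinearity); remaining features are
#' independent standard-normal noise. Classes are exactly balanced.
#' Increasing `n_informative` at fixed geometry spreads the class signal
#' over more variables, diluting the information carried by each.
#'
#' With `shuffle = FALSE` the columns are ordered
#' `[informative | redundant | noise]` (useful for structural checks);
#' with the default `shuffle = TRUE` both samples and feature columns are
#' randomly permuted, as in benchmark use.
#'
#' @param n_obs number of observations (must be even; split equally
#'   between the classes). Default 700.
#' @param n_vars total number of variables. Default 10000.
#' @param n_informative number of informative variables (0 gives a
#'   negative control whose labels are independent of all features).
#' @param n_redundant number of redundant variables; requires
#'   `n_informative + n_redundant <= n_vars` (and `n_informative > 0`
#'   when positive).
#' @param class_sep half-side of the centroid hypercube; larger separates
#'   the classes more. Default 1.
#' @param n_clusters_per_class Gaussian clusters per class. Default 1.
#' @param shuffle permute samples and columns. Default `TRUE`.
#' @param seed integer seed; generation is fully deterministic given it.
#' @return A list of class `"habic_dataset"`: `x` (matrix with columns
#'   `feat_1..feat_p`, rows `sample_1..sample_n`), `y` (integer 0/1
#'   labels), and `spec` (the generating parameters).
#' @examples
#' d <- generate_classification(n_obs = 40, n_vars = 10, n_informative = 2,
#'                              n_redundant = 2, seed = 1)
#' table(d$y)
#' @export
generate_classification <- function(n_obs = 700L, n_vars = 10000L,
                                    n_informative = 0L, n_redundant = 0L,
                                    class_sep = 1, n_clusters_per_class = 1L,
                                    shuffle = TRUE, seed = 1L) {
  n_obs <- as.integer(n_obs)
  n_vars <- as.integer(n_vars)
  n_informative <- as.integer(n_informative)
  n_redundant <- as.integer(n_redundant)
  if (n_obs < 2L || n_obs %% 2L != 0L)
    stop("n_obs must be an even count >= 2 (classes are exactly balanced)",
         call. = FALSE)
  if (n_informative < 0L || n_redundant < 0L)
    stop("variable counts must be nonnegative", call. = FALSE)
  if (n_informative + n_redundant > n_vars)
    stop(sprintf("n_informative + n_redundant = %d exceeds n_vars = %d",
                 n_informative + n_redundant, n_vars), call. = FALSE)
  if (n_redundant > 0L && n_informative == 0L)
    stop("redundant variables require at least one informative variable",
         call. = FALSE)
  spec <- list(n_obs = n_obs, n_vars = n_vars, n_informative = n_informative,
               n_redundant = n_redundant, class_sep = class_sep,
               n_clusters_per_class = as.integer(n_clusters_per_class),
               shuffle = shuffle, seed = as.integer(seed))

  out <- with_seed(seed, {
    n_clusters <- 2L * spec$n_clusters_per_class
    # equal cluster sizes within each balanced class
    per_class <- n_obs %/% 2L
    sizes <- integer(n_clusters)
    cls <- rep(c(0L, 1L), length.out = n_clusters)   # cluster -> class
    for (cl in 0:1) {
      k <- sum(cls == cl)
      s <- rep(per_class %/% k, k)
      if (per_class %% k > 0L) s[seq_len(per_class %% k)] <- s[seq_len(per_class %% k)] + 1L
      sizes[cls == cl] <- s
    }
    y <- rep(cls, times = sizes)

    if (n_informative > 0L) {
      vert <- hypercube_vertices(n_clusters, n_informative)
      centroids <- (2 * vert - 1) * class_sep
      xinf <- matrix(rnorm(n_obs * n_informative), n_obs, n_informative)
      offset <- 0L
      for (k in seq_len(n_clusters)) {
        rows <- offset + seq_len(sizes[k])
        offset <- offset + sizes[k]
        a <- matrix(runif(n_informative^2, -1, 1), n_informative)
        xinf[rows, ] <- xinf[rows, , drop = FALSE] %*% a
        xinf[rows, ] <- sweep(xinf[rows, , drop = FALSE], 2L,
                              centroids[k, ], "+")
      }
    } else {
      xinf <- matrix(numeric(0), n_obs, 0L)
    }
    xred <- if (n_redundant > 0L) {
      b <- matrix(runif(n_informative * n_redundant, -1, 1), n_informative)
      xinf %*% b
    } else matrix(numeric(0), n_obs, 0L)
    n_noise <- n_vars - n_informative - n_redundant
    xnoise <- matrix(rnorm(n_obs * n_noise), n_obs, n_noise)
    x <- cbind(xinf, xred, xnoise)
    if (shuffle) {
      ro <- sample.int(n_obs)
      co <- sample.int(n_vars)
      x <- x[ro, co, drop = FALSE]
      y <- y[ro]
    }
    list(x = x, y = y)
  })
  dimnames(out$x) <- list(paste0("sample_", seq_len(n_obs)),
                          paste0("feat_", seq_len(n_vars)))
  structure(list(x = out$x, y = out$y, spec = spec),
            class = "habic_dataset")
}

# k distinct 0/1 vertices of the d-dimensional unit hypercube, as rows.
hypercube_vertices <- function(k, d) {
  if (d <= 30L) {
    if (k > 2^d)
      stop(sprintf("cannot place %d clusters on %d hypercube vertices",
                   k, 2^d), call. = FALSE)
    ids <- sample.int(2^d, k) - 1L
    t(vapply(ids, function(v) as.integer(bitwAnd(v %/% 2^(0:(d - 1L)), 1L)),
             integer(d)))
  } else {
    repeat {
      m <- matrix(rbinom(k * d, 1L, 0.5), k, d)
      if (!anyDuplicated(m)) return(m)
    }
  }
}

#' @export
print.habic_dataset <- function(x, ...) {
  s <- x$spec
  cat(sprintf("Synthetic dataset: %d x %d (%d informative, %d redundant, %d noise), seed %d\n",
              s$n_obs, s$n_vars, s$n_informative, s$n_redundant,
              s$n_vars - s$n_informative - s$n_redundant, s$seed))
  print(table(class = x$y))
  invisible(x)
}

#' Benchmark scenario grid
#'
#' The named synthetic scenarios used for benchmarking, all at 700
#' observations by 10000 variables: informative/redundant combinations
#' (100, 400), (100, 800), (100, 1600), (1000, 0), (1000, 400), (5000, 0),
#' (5000, 800), plus the (0, 0) negative control with labels independent
#' of every feature.
#'
#' @return A data frame with columns `name`, `n_obs`, `n_vars`,
#'   `n_informative`, `n_redundant`.
#' @export
scenario_grid <- function() {
  combos <- rbind(
    c(100L, 400L), c(100L, 800L), c(100L, 1600L),
    c(1000L, 0L), c(1000L, 400L),
    c(5000L, 0L), c(5000L, 800L),
    c(0L, 0L))
  data.frame(
    name = c(paste0("inf", combos[1:7, 1L], "_red", combos[1:7, 2L]),
             "negative_control"),
    n_obs = 700L, n_vars = 10000L,
    n_informative = combos[, 1L], n_redundant = combos[, 2L],
    stringsAsFactors = FALSE)
}
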