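# Shared fixtures: brute-force assignment oracle and small data generators.

# Exact minimum assignment cost by enumerating all n! permutations.
brute_force_assignment <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(r) c(v[i], r))))
  }
  min(vapply(perms(seq_len(n)),
             function(p) sum(cost[cbind(seq_len(n), p)]), numeric(1)))
}

# Two well-separated Gaussian blobs; any linear separator reaches accuracy 1.
make_blobs <- function(n_per_class = 20L, p = 2L, sep = 4, seed = 1L,
                       noise_p = 0L) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * p, -sep / 2), n_per_class, p),
             matrix(rnorm(n_per_class * p, sep / 2), n_per_class, p))
  if (noise_p > 0L)
    x <- cbind(x, matrix(rnorm(2L * n_per_class * noise_p), ncol = noise_p))
  list(x = x, y = rep(0:1, each = n_per_class))
}

# Labels independent of all features (negative control).
make_null_data <- function(n = 100L, p = 20L, seed = 1L) {
  set.seed(seed)
  list(x = matrix(rnorm(n * p), n, p), y = rep(0:1, length.out = n))
}

# 1-D toy with one support point per class: X0 = {0}, X1 = {1}.
toy_1d_fit <- function() {
  suppressWarnings(habic(matrix(c(0, 1)), c(0, 1), seed = 1L))
}
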