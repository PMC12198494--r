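#' Minkowski cost matrix between two point clouds
#'
#' Computes the rectangular matrix of pairwise Minkowski-q distances
#' \eqn{c_{ij} = \lVert x_i - y_j \rVert_q} between the rows of `x0` and the
#' rows of `x1`. This is the ground-cost matrix of the discrete optimal
#' transport problem between the two class-conditional empirical
#' distributions; `q = 1` (Manhattan) is the default used throughout the
#' classifier, `q = 2` is Euclidean.
#'
#' @param x0 numeric matrix, `n0` points in rows.
#' @param x1 numeric matrix, `n1` points in rows; must have the same number
#'   of columns as `x0`.
#' @param q Minkowski order, a single number `>= 1`.
#' @return An `n0 x n1` numeric matrix of distances, with the order stored
#'   in attribute `"q"`.
#' @examples
#' minkowski_cost(rbind(c(1, 2)), rbind(c(4, 6)), q = 2)  # 5 (3-4-5 triangle)
#' minkowski_cost(rbind(c(1, 2)), rbind(c(4, 6)), q = 1)  # 7
#' @export
minkowski_cost <- function(x0, x1, q = 1) {
  x0 <- as_feature_matrix(x0, "x0")
  x1 <- as_feature_matrix(x1, "x1")
  if (ncol(x0) != ncol(x1))
    stop(sprintf("dimension mismatch: x0 is %d x %d but x1 is %d x %d",
                 nrow(x0), ncol(x0), nrow(x1), ncol(x1)), call. = FALSE)
  if (length(q) != 1L || !is.finite(q) || q < 1)
    stop("'q' must be a single finite number >= 1", call. = FALSE)
  d <- cross_minkowski_cpp(x0, x1, q)
  attr(d, "q") <- q
  d
}

#' Exact assignment solve with certified Kantorovich potentials
#'
#' Solves the linear sum assignment problem for a square nonnegative cost
#' matrix by an exact O(n^3) primal-dual Hungarian algorithm, returning both
#' the optimal pairing and the dual variables. When the costs are pairwise
#' distances between two balanced samples, the optimal total cost divided by
#' `n` is the 1-Wasserstein distance between the empirical distributions,
#' and the duals `psi`, `phi` are discrete Kantorovich potentials:
#' `psi[i] + phi[j] <= c[i, j]` everywhere, with equality on assigned pairs,
#' and `sum(psi) + sum(phi)` equal to the optimal cost (zero duality gap).
#' These three certificates are verified numerically before returning.
#'
#' Dual optima are not unique; only the certificates above (not particular
#' potential values) are guaranteed. The solve is deterministic for a given
#' cost matrix.
#'
#' @param cost square numeric matrix of nonnegative finite costs, as
#'   produced by [minkowski_cost()] on two equally sized samples. A
#'   non-square matrix is an error: undersample the majority class first
#'   (see [balance_classes()]).
#' @return An object of class `"transport_plan"`: a list with `perm`
#'   (optimal permutation, `perm[i]` is the column assigned to row `i`),
#'   `psi` and `phi` (dual potentials for rows and columns), `total_cost`
#'   (unnormalized optimal cost), `w1` (`total_cost / n`, the 1-Wasserstein
#'   distance between the two empirical measures), `assigned_cost`
#'   (per-pair costs) and `n`.
#' @examples
#' p <- solve_assignment(rbind(c(4, 1), c(2, 3)))
#' p$perm        # 2 1
#' p$total_cost  # 3
#' @export
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  if (!is.numeric(cost) || anyNA(cost))
    stop("cost matrix must be numeric with no NA/NaN entries", call. = FALSE)
  if (nrow(cost) != ncol(cost))
    stop(sprintf(
      "cost matrix must be square, got %d x %d: balance the classes first",
      nrow(cost), ncol(cost)), call. = FALSE)
  n <- nrow(cost)
  r <- lap_hungarian_cpp(cost)
  plan <- structure(
    list(perm = r$perm, psi = r$psi, phi = r$phi,
         total_cost = r$total_cost, w1 = r$total_cost / n,
         assigned_cost = cost[cbind(seq_len(n), r$perm)], n = n),
    class = "transport_plan")
  validate_transport_plan(plan, cost)
  plan
}

#' Verify the dual certificates of a transport plan
#'
#' Checks dual feasibility (`psi[i] + phi[j] <= c[i, j]`), complementary
#' slackness on assigned pairs, and the zero duality gap
#' (`sum(psi) + sum(phi) == total_cost`), at a relative tolerance scaled by
#' the largest cost. Errors with the violated certificate on failure.
#'
#' @param plan a `"transport_plan"`.
#' @param cost the cost matrix the plan was solved from.
#' @param tol absolute tolerance; default `1e-8 * max(1, max(cost))`.
#' @return `TRUE`, invisibly.
#' @export
validate_transport_plan <- function(plan, cost, tol = NULL) {
  stopifnot(inherits(plan, "transport_plan"))
  n <- plan$n
  if (is.null(tol)) tol <- 1e-8 * max(1, max(cost))
  feas <- max(outer(plan$psi, plan$phi, "+") - cost)
  if (feas > tol)
    stop(sprintf("dual infeasibility: max(psi_i + phi_j - c_ij) = %.3e", feas),
         call. = FALSE)
  slack <- max(abs(plan$psi + plan$phi[plan$perm] -
                     cost[cbind(seq_len(n), plan$perm)]))
  if (slack > tol)
    stop(sprintf("complementary slackness violated by %.3e on assigned pairs",
                 slack), call. = FALSE)
  gap <- abs(sum(plan$psi) + sum(plan$phi) - plan$total_cost)
  if (gap > tol * n)
    stop(sprintf("nonzero duality gap: |sum(psi)+sum(phi) - cost| = %.3e", gap),
         call. = FALSE)
  invisible(TRUE)
}

#' @export
print.transport_plan <- function(x, ...) {
  cat(sprintf("Optimal transport plan on %d pairs\n", x$n))
  cat(sprintf("  total cost: %.6g   W1 (cost/n): %.6g\n", x$total_cost, x$w1))
  invisible(x)
}

#' Export a transport plan as TSV (debug aid)
#'
#' Writes one row per assigned pair with columns `i`, `pi_i`, `psi_i`,
#' `phi_pi_i`, `cost_i`.
#'
#' @param plan a `"transport_plan"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_plan_tsv <- function(plan, path) {
  stopifnot(inherits(plan, "transport_plan"))
  d <- data.frame(i = seq_len(plan$n), pi_i = plan$perm, psi_i = plan$psi,
                  phi_pi_i = plan$phi[plan$perm], cost_i = plan$assigned_cost)
  data.table::fwrite(d, path, sep = "\t")
  invisible(path)
}
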