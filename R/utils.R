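#' Moore-Penrose pseudo-inverse with a relative singular-value cutoff
#'
#' All matrix inversions in the decoder go through this routine so that
#' near-singular systems (`X'X` during training, `W W'` during decoding)
#' degrade gracefully instead of failing.  Singular values below
#' `tol * max(singular value)` are treated as zero; when that happens a
#' warning is emitted, because the linear model then has a null space and
#' the returned solution is the minimum-norm one.
#'
#' @param A numeric matrix.
#' @param tol relative singular-value cutoff (default `1e-10`).
#' @param warn emit a warning when singular values are dropped?
#' @return the pseudo-inverse of `A`.
#' @export
pseudo_inverse <- function(A, tol = 1e-10, warn = TRUE) {
  A <- as.matrix(A)
  s <- svd(A)
  keep <- s$d > tol * max(s$d, 0)
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  if (warn && !all(keep)) {
    warning(sprintf("matrix numerically rank-deficient (%d of %d singular values dropped); using pseudo-inverse",
                    sum(!keep), length(keep)))
  }
  s$v[, keep, drop = FALSE] %*% ((1 / s$d[keep]) * t(s$u[, keep, drop = FALSE]))
}

# Least-squares solve of A x = B via the shared pseudo-inverse policy.
pinv_solve <- function(A, B, tol = 1e-10, warn = TRUE) {
  pseudo_inverse(A, tol = tol, warn = warn) %*% B
}

cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for a zero vector")
  sum(a * b) / (na * nb)
}

# Per-item identification accuracy implied by the rank of the target among
# n_candidates (rank 1 = most correlated).  "pairwise" is the fraction of
# distractors beaten, (n - rank)/(n - 1); "full" scores 1 only for rank 1.
rank_accuracy <- function(rank, n_candidates, type = c("pairwise", "full")) {
  type <- match.arg(type)
  stopifnot(all(rank >= 1), all(rank <= n_candidates))
  if (type == "pairwise") (n_candidates - rank) / (n_candidates - 1) else as.numeric(rank == 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_scalar_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != round(x))
    stop(sprintf("'%s' must be a single integer >= %s", name, min))
  as.integer(x)
}
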