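#' @useDynLib riembci, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cov
NULL

# ---- internal helpers -------------------------------------------------------

symmetrize <- function(m) (m + t(m)) / 2

assert_spd <- function(m, arg = deparse(substitute(m)), tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop(sprintf("'%s' must be a square matrix", arg), call. = FALSE)
  if (max(abs(m - t(m))) > tol * max(1, max(abs(m))))
    stop(sprintf("'%s' is not symmetric", arg), call. = FALSE)
  ev <- eigen(symmetrize(m), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop(sprintf("'%s' is not positive-definite (min eigenvalue %.3g)", arg, min(ev)),
         call. = FALSE)
  invisible(TRUE)
}

# Coerce a list of matrices or a d x d x n array to a d x d x n array.
as_cov_array <- function(x) {
  if (is.array(x) && length(dim(x)) == 3L) return(x)
  if (is.matrix(x)) return(array(x, c(dim(x), 1L)))
  if (is.list(x)) {
    d <- dim(x[[1]])
    arr <- array(0, c(d[1], d[2], length(x)))
    for (i in seq_along(x)) arr[, , i] <- x[[i]]
    return(arr)
  }
  stop("expected a matrix, list of matrices, or d x d x n array", call. = FALSE)
}

# ---- covariance estimation --------------------------------------------------

#' Spatial covariance matrix of one EEG epoch
#'
#' Sample covariance (divisor `n - 1`) across channels of a band-filtered
#' epoch, symmetrized. If the result is not positive-definite (e.g., a
#' constant or rank-deficient epoch), a small diagonal jitter proportional to
#' the average channel variance is added to restore positive-definiteness;
#' for an all-zero epoch this yields `jitter * I`.
#'
#' @param epoch numeric matrix, channels x samples, already band-filtered.
#' @param jitter non-negative scalar; diagonal loading used only when the
#'   smallest eigenvalue is not strictly positive. The amount added is
#'   `jitter * trace / channels` (or `jitter` itself when the trace is zero).
#' @return a symmetric positive-definite channels x channels matrix.
#' @examples
#' x <- matrix(rnorm(2 * 500), 2, 500)
#' trial_covariance(x)
#' @export
trial_covariance <- function(epoch, jitter = 1e-10) {
  if (!is.matrix(epoch)) stop("'epoch' must be a channels x samples matrix")
  nc <- nrow(epoch)
  ns <- ncol(epoch)
  if (ns <= nc)
    stop(sprintf("degenerate epoch: %d samples for %d channels (need samples > channels)",
                 ns, nc))
  cc <- symmetrize(stats::cov(t(epoch)))
  ev <- eigen(cc, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    tr <- sum(diag(cc))
    eps <- if (tr > 0) jitter * tr / nc else jitter
    cc <- cc + diag(eps, nc)
  }
  cc
}

# ---- manifold primitives ----------------------------------------------------

#' Affine-invariant Riemannian distance between SPD matrices
#'
#' \eqn{\delta_R(A, B) = \sqrt{\sum_i \log^2 \lambda_i(A^{-1}B)}} where the
#' \eqn{\lambda_i} are the generalized eigenvalues of the pair, computed via
#' Cholesky whitening rather than an explicit inverse. The distance is
#' symmetric and invariant under congruence \eqn{A \to WAW^\top},
#' \eqn{B \to WBW^\top} for any invertible \eqn{W}.
#'
#' @param a,b symmetric positive-definite matrices of equal dimension.
#' @param validate check the inputs for symmetry/positive-definiteness
#'   (disable in tight inner loops).
#' @return non-negative scalar distance.
#' @examples
#' riemannian_distance(diag(2), exp(2) * diag(2))  # 2 * sqrt(2)
#' @export
riemannian_distance <- function(a, b, validate = TRUE) {
  if (validate) {
    assert_spd(a, "a")
    assert_spd(b, "b")
    if (!all(dim(a) == dim(b))) stop("dimension mismatch between 'a' and 'b'")
  }
  riem_dist_cpp(a, b)
}

#' Fréchet (geometric) mean of SPD matrices
#'
#' The matrix minimizing \eqn{\sum_i w_i \, \delta_R^2(G, \Gamma_i)},
#' estimated by fixed-point iteration in the tangent space at the current
#' iterate: \eqn{G \leftarrow G^{1/2} \exp\!\big(\sum_i w_i
#' \log(G^{-1/2} \Gamma_i G^{-1/2})\big) G^{1/2}}, initialized at the
#' (weighted) arithmetic mean, stopped when the tangent-space gradient norm
#' drops below `tol`.
#'
#' @param mats list of SPD matrices or a d x d x n array.
#' @param weights optional non-negative weights; normalized to sum to 1.
#' @param tol convergence tolerance on the Frobenius norm of the tangent mean.
#' @param max_iter maximum number of fixed-point iterations; on
#'   non-convergence the best iterate is returned with a warning.
#' @param init optional SPD warm start (defaults to the arithmetic mean).
#' @return SPD matrix of the common dimension.
#' @examples
#' frechet_mean(list(diag(c(1, 1)), diag(c(4, 4))))  # diag(2, 2)
#' @export
frechet_mean <- function(mats, weights = NULL, tol = 1e-8, max_iter = 50L,
                         init = NULL) {
  x <- as_cov_array(mats)
  n <- dim(x)[3]
  if (n == 0L) stop("empty set of matrices")
  if (is.null(weights)) weights <- rep(1 / n, n)
  if (length(weights) != n) stop("length(weights) must match the number of matrices")
  if (any(weights < 0)) stop("weights must be non-negative")
  weights <- weights / sum(weights)
  if (n == 1L) return(symmetrize(x[, , 1]))
  if (is.null(init)) {
    init <- matrix(0, dim(x)[1], dim(x)[2])
    for (i in seq_len(n)) init <- init + weights[i] * x[, , i]
  }
  res <- frechet_mean_cpp(x, weights, tol, as.integer(max_iter), init)
  if (!res$converged)
    warning(sprintf("Fréchet mean did not converge in %d iterations (gradient norm %.3g)",
                    max_iter, res$grad_norm))
  res$mean
}

#' Geodesic power map between SPD matrices
#'
#' Point at parameter `alpha` on the affine-invariant geodesic from `base`
#' to `target`:
#' \eqn{B^{1/2} (B^{-1/2} T B^{-1/2})^{\alpha} B^{1/2}}. `alpha = 0` returns
#' `base`, `alpha = 1` returns `target`; for commuting inputs this equals
#' \eqn{\exp((1-\alpha)\log B + \alpha \log T)}. This is the mean-update rule
#' of the weighted-average trial-wise engine, the Riemannian analogue of the
#' Euclidean convex sum \eqn{(1-\alpha) B + \alpha T}.
#'
#' @param base,target SPD matrices of equal dimension.
#' @param alpha interpolation weight in \[0, 1\].
#' @return SPD matrix on the geodesic.
#' @export
geodesic_power <- function(base, target, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1)
    stop("'alpha' must be a scalar in [0, 1]")
  assert_spd(base, "base")
  assert_spd(target, "target")
  if (!all(dim(base) == dim(target))) stop("dimension mismatch")
  geodesic_power_cpp(base, target, alpha)
}

# Distances from many covariances to a common reference (internal fast path).
riem_distances <- function(covs, ref) {
  riem_dist_many_cpp(as_cov_array(covs), ref)
}
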