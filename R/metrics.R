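# Block-wise (static) performance metrics on sets of trial covariance
# matrices: inter-/intra-class dispersion, classDistinct, classStability and
# the chronological-subset dispersion Phi*.

#' Inter-class dispersion
#'
#' Riemannian distance between the two class mean covariance matrices.
#'
#' @param mean1,mean2 SPD class mean covariance matrices.
#' @return non-negative scalar.
#' @export
interclass_dispersion <- function(mean1, mean2) {
  riemannian_distance(mean1, mean2)
}

#' Intra-class dispersion
#'
#' Fréchet mean of the class trials and the mean Riemannian distance of the
#' trials to that mean:
#' \eqn{\Phi_c = N_c^{-1} \sum_i \delta_R(\bar\Gamma_c, \Gamma_{c,i})}.
#'
#' @param covs trial covariance matrices of one class (list or d x d x n array).
#' @param ... passed to [frechet_mean()].
#' @return list with elements `mean` (SPD matrix) and `dispersion` (scalar).
#' @export
intraclass_dispersion <- function(covs, ...) {
  x <- as_cov_array(covs)
  if (dim(x)[3] < 1L) stop("at least one trial required")
  m <- frechet_mean(x, ...)
  list(mean = m, dispersion = mean(riem_distances(x, m)))
}

#' classDistinct: inter- to intra-class dispersion ratio
#'
#' \eqn{\delta_R(\bar\Gamma_1, \bar\Gamma_2) / (\Phi_1 + \Phi_2)} — the
#' separability of two task classes on the SPD manifold. Larger values mean
#' the class means are far apart relative to the within-class spread.
#'
#' If all trials in both classes are identical the denominator is zero and a
#' degenerate `Inf` (or `NaN` when the numerator is also zero) is returned
#' with a warning, so batch evaluation can continue.
#'
#' @param covs1,covs2 per-class trial covariances (lists or d x d x n arrays).
#' @return non-negative scalar (possibly `Inf`/`NaN` in the degenerate case).
#' @export
class_distinct <- function(covs1, covs2) {
  s1 <- intraclass_dispersion(covs1)
  s2 <- intraclass_dispersion(covs2)
  class_distinct_from(s1$mean, s2$mean, s1$dispersion, s2$dispersion)
}

# classDistinct from precomputed means/dispersions (engine fast path).
class_distinct_from <- function(mean1, mean2, phi1, phi2) {
  num <- riem_dist_cpp(mean1, mean2)
  den <- phi1 + phi2
  if (den == 0) {
    warning("zero intra-class dispersion in both classes: classDistinct is degenerate")
    return(num / den) # Inf, or NaN when num == 0
  }
  num / den
}

#' classStability: inverse intra-class dispersion
#'
#' \eqn{1 / (1 + \Phi_c)} — the within-class consistency of one task class;
#' 1 when all trials are identical, decreasing toward 0 as the dispersion
#' grows.
#'
#' @param dispersion non-negative intra-class dispersion \eqn{\Phi_c}.
#' @return scalar in (0, 1].
#' @export
class_stability <- function(dispersion) {
  if (any(dispersion < 0)) stop("'dispersion' must be non-negative")
  1 / (1 + dispersion)
}

#' Overall classStability of a two-class session
#'
#' Arithmetic mean of the two per-class stabilities.
#'
#' @param s1,s2 per-class classStability values in (0, 1].
#' @return scalar in (0, 1].
#' @export
overall_class_stability <- function(s1, s2) {
  (s1 + s2) / 2
}

#' Chronological subset indices for the modified dispersion
#'
#' Splits `n` chronologically ordered trials into subsets of `subset_size`.
#' Full subsets are disjoint, consecutive chunks. When `n` is not divisible
#' by `subset_size`: with `allow_overlap_tail = TRUE` the final subset is the
#' most recent `subset_size` trials (sharing up to `subset_size - 1` trials
#' with its predecessor — the within-block rule); otherwise the remainder
#' forms a smaller final subset.
#'
#' @param n number of trials.
#' @param subset_size trials per subset (\eqn{N_t}).
#' @param allow_overlap_tail use the overlapping most-recent tail subset.
#' @return list of integer index vectors.
#' @examples
#' subset_indices(12, 5, allow_overlap_tail = TRUE)  # {1:5, 6:10, 8:12}
#' @export
subset_indices <- function(n, subset_size, allow_overlap_tail = FALSE) {
  if (subset_size < 2L) stop("'subset_size' must be at least 2")
  if (n < subset_size) return(list(seq_len(n)))
  nfull <- n %/% subset_size
  idx <- lapply(seq_len(nfull), function(j) ((j - 1L) * subset_size + 1L):(j * subset_size))
  if (n %% subset_size != 0L) {
    idx[[nfull + 1L]] <- if (allow_overlap_tail) (n - subset_size + 1L):n
                         else (nfull * subset_size + 1L):n
  }
  idx
}

#' Subset-based intra-class dispersion (Phi*)
#'
#' Intra-class dispersion averaged over chronological subsets of
#' `subset_size` trials:
#' \eqn{\Phi^* = N_s^{-1} \sum_j N_t^{-1} \sum_i
#' \delta_R(\bar\Gamma_{T_j}, \Gamma_{T_j,i})},
#' which damps slow signal non-stationarities that would inflate the plain
#' dispersion over a long trial sequence. With a single subset
#' (`subset_size >= n`) it reduces exactly to [intraclass_dispersion()].
#' With fewer than `subset_size` trials, the plain dispersion of the
#' available trials is returned.
#'
#' @param covs chronologically ordered trial covariances of one class.
#' @param subset_size trials per subset (\eqn{N_t}; default 5).
#' @param allow_overlap_tail see [subset_indices()]; used for within-block
#'   post-trial updates.
#' @return non-negative scalar.
#' @export
subset_dispersion <- function(covs, subset_size = 5L, allow_overlap_tail = FALSE) {
  x <- as_cov_array(covs)
  n <- dim(x)[3]
  if (n < 1L) stop("at least one trial required")
  idx <- subset_indices(n, subset_size, allow_overlap_tail)
  per_subset <- vapply(idx, function(ii) {
    m <- frechet_mean(x[, , ii, drop = FALSE])
    mean(riem_distances(x[, , ii, drop = FALSE], m))
  }, numeric(1))
  mean(per_subset)
}
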