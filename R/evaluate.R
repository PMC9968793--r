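# Evaluation battery: how well trial-wise reinforcement sums track
# block-wise metric changes. Correlations (Spearman, repeated-measures),
# bootstrap CIs for correlation differences, ROC/AUC with DeLong's paired
# test, sign-agreement tables with exact McNemar tests, Holm adjustment.

#' Spearman correlation between block-wise deltas and reinforcement sums
#'
#' Rank correlation (ties mid-ranked) of the block-wise metric change
#' against the trial-wise reinforcement sum over a set of transitions.
#'
#' @param delta block-wise metric changes (ground truth).
#' @param sum_ cognate trial-wise reinforcement sums.
#' @return list with `rho` and `p` (two-sided).
#' @export
eval_spearman <- function(delta, sum_) {
  if (length(delta) < 3L) stop("need at least 3 records")
  if (stats::sd(delta) == 0 || stats::sd(sum_) == 0)
    stop("constant input: Spearman correlation undefined")
  ct <- suppressWarnings(stats::cor.test(delta, sum_, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Repeated-measures correlation
#'
#' The common within-subject association between two variables, controlling
#' for between-subject variation via per-subject intercepts (the
#' covariate-adjusted ANCOVA formulation). The coefficient is
#' \eqn{r_{rm} = \mathrm{sign}(b)\sqrt{SS_x / (SS_x + SS_e)}} where `b` is
#' the common slope, `SS_x` the sum of squares removed by the measure and
#' `SS_e` the residual sum of squares; degrees of freedom are
#' `N - k - 1` for `N` observations from `k` subjects. Subjects contributing
#' a single observation are dropped with a message.
#'
#' @param x,y paired observations.
#' @param subject subject identifier per observation.
#' @return list with `r`, `df`, `p`, `ci` (95% via Fisher z), `n_subjects`.
#' @export
rm_corr <- function(x, y, subject) {
  subject <- as.factor(subject)
  keep <- subject %in% names(which(table(subject) >= 2L))
  if (!all(keep)) {
    message(sum(!keep), " observation(s) from single-record subjects dropped")
    x <- x[keep]; y <- y[keep]; subject <- droplevels(subject[keep])
  }
  if (nlevels(subject) < 2L) stop("need at least 2 subjects with >= 2 records")
  m_full <- stats::lm(y ~ subject + x)
  m_null <- stats::lm(y ~ subject)
  ss_e <- sum(stats::residuals(m_full)^2)
  ss_x <- sum(stats::residuals(m_null)^2) - ss_e
  slope <- stats::coef(m_full)[["x"]]
  r <- sign(slope) * sqrt(max(0, ss_x) / (ss_x + ss_e))
  df <- length(y) - nlevels(subject) - 1L
  tval <- r * sqrt(df / max(1e-300, 1 - r^2))
  p <- 2 * stats::pt(-abs(tval), df)
  z <- atanh(min(1 - 1e-12, max(-1 + 1e-12, r)))
  se <- 1 / sqrt(df - 1)
  list(r = r, df = df, p = p, ci = tanh(z + c(-1, 1) * stats::qnorm(0.975) * se),
       n_subjects = nlevels(subject))
}

#' Bootstrap confidence interval for a correlation difference
#'
#' Percentile bootstrap CI for \eqn{r_a - r_b}, the difference between the
#' correlations of two methods' reinforcement sums with the block-wise
#' deltas, scored on the same transitions. Resampling is by grouping unit
#' (session for simulated corpora, subject for multi-subject data), which
#' preserves within-unit dependence. The interval level is
#' Bonferroni-adjusted to `1 - 0.05 / family_size` so a family of such
#' comparisons keeps a 5% family-wise error rate.
#'
#' @param delta_a,sum_a deltas and sums for method a.
#' @param delta_b,sum_b deltas and sums for method b (same transitions).
#' @param unit resampling unit identifier per record.
#' @param n_boot bootstrap replicates (default 1000; < 100 warns).
#' @param family_size number of comparisons in the family (default 1).
#' @param method correlation method (default `"spearman"`).
#' @return list with `diff` (observed \eqn{r_a - r_b}), `ci`, `level`,
#'   `significant` (CI excludes 0).
#' @export
bootstrap_corr_diff <- function(delta_a, sum_a, delta_b, sum_b, unit,
                                n_boot = 1000L, family_size = 1L,
                                method = "spearman") {
  if (n_boot < 100L) warning("fewer than 100 bootstrap samples")
  stopifnot(length(delta_a) == length(sum_a),
            length(delta_b) == length(sum_b),
            length(delta_a) == length(delta_b))
  unit <- as.factor(unit)
  rdiff <- function(ii) {
    suppressWarnings(
      stats::cor(delta_a[ii], sum_a[ii], method = method) -
        stats::cor(delta_b[ii], sum_b[ii], method = method))
  }
  groups <- split(seq_along(unit), unit)
  boot <- vapply(seq_len(n_boot), function(b) {
    gi <- sample(length(groups), replace = TRUE)
    rdiff(unlist(groups[gi], use.names = FALSE))
  }, numeric(1))
  level <- 1 - 0.05 / family_size
  ci <- unname(stats::quantile(boot, c((1 - level) / 2, 1 - (1 - level) / 2),
                               na.rm = TRUE))
  list(diff = rdiff(seq_along(unit)), ci = ci, level = level,
       significant = ci[1] > 0 || ci[2] < 0)
}

#' Empirical ROC curve and AUC for sign discrimination
#'
#' Treats the sign of the block-wise metric change as the ground-truth label
#' and the trial-wise reinforcement sum as the discriminating score. The AUC
#' equals the probability that a positive-transition sum exceeds a
#' negative-transition one, ties counted one half (the Mann–Whitney
#' normalization). Computed with `pROC`.
#'
#' @param delta block-wise metric changes; only their sign is used. Zero
#'   deltas are excluded with a message.
#' @param sum_ reinforcement sums (scores).
#' @return list with `auc` and the underlying `pROC::roc` object.
#' @export
roc_auc <- function(delta, sum_) {
  keep <- delta != 0
  if (!all(keep)) message(sum(!keep), " zero-delta record(s) excluded from ROC")
  truth <- factor(ifelse(delta[keep] > 0, "pos", "neg"), levels = c("neg", "pos"))
  if (nlevels(droplevels(truth)) < 2L)
    stop("one-class ground truth: ROC undefined")
  r <- pROC::roc(truth, sum_[keep], levels = c("neg", "pos"),
                 direction = "<", quiet = TRUE)
  list(auc = as.numeric(pROC::auc(r)), roc = r)
}

#' DeLong's paired test for an AUC difference
#'
#' Two-sided test that two (correlated) ROC curves built on the same
#' transitions have equal AUC, using DeLong's structural-components
#' variance. Identical scores give p = 1 by convention.
#'
#' @param delta block-wise changes (shared ground truth).
#' @param sum_a,sum_b the two methods' reinforcement sums (paired).
#' @return list with `p`, `auc_a`, `auc_b`.
#' @export
delong_test <- function(delta, sum_a, sum_b) {
  stopifnot(length(sum_a) == length(sum_b), length(delta) == length(sum_a))
  ra <- roc_auc(delta, sum_a)
  rb <- roc_auc(delta, sum_b)
  if (isTRUE(all.equal(sum_a, sum_b)))
    return(list(p = 1, auc_a = ra$auc, auc_b = rb$auc))
  tt <- pROC::roc.test(ra$roc, rb$roc, method = "delong", paired = TRUE)
  list(p = tt$p.value, auc_a = ra$auc, auc_b = rb$auc)
}

#' Sign-agreement cross-tabulation
#'
#' 2 x 2 counts of the sign of the block-wise change against the sign of the
#' reinforcement sum (the zero-threshold decision rule a user would apply).
#' Records with a zero delta or zero sum are excluded with a message.
#'
#' @param delta block-wise metric changes.
#' @param sum_ reinforcement sums.
#' @return list with `table` (rows: block-wise sign; columns: sum sign),
#'   `agreement` (diagonal proportion), `n_excluded`.
#' @export
sign_agreement_table <- function(delta, sum_) {
  keep <- delta != 0 & sum_ != 0
  if (!all(keep)) message(sum(!keep), " zero-valued record(s) excluded from sign table")
  d <- factor(ifelse(delta[keep] > 0, "pos", "neg"), levels = c("pos", "neg"))
  s <- factor(ifelse(sum_[keep] > 0, "pos", "neg"), levels = c("pos", "neg"))
  tab <- table(blockwise = d, reinforcement = s)
  list(table = tab, agreement = sum(diag(tab)) / sum(tab),
       n_excluded = sum(!keep))
}

#' Exact McNemar test for paired sign-agreement proportions
#'
#' Compares two methods' per-transition correctness indicators (sum sign
#' agrees with block-wise sign) via an exact two-sided binomial test on the
#' discordant pairs. With no discordant pairs, p = 1.
#'
#' @param correct_a,correct_b logical vectors, paired by transition.
#' @return list with `p`, `b` (a-only correct), `c` (b-only correct).
#' @export
mcnemar_exact <- function(correct_a, correct_b) {
  stopifnot(length(correct_a) == length(correct_b))
  b <- sum(correct_a & !correct_b)
  cc <- sum(!correct_a & correct_b)
  p <- if (b + cc == 0L) 1 else stats::binom.test(b, b + cc, 0.5)$p.value
  list(p = p, b = b, c = cc)
}

#' Holm step-down adjustment of p-values
#'
#' @param p vector of p-values in \[0, 1\].
#' @return adjusted p-values (monotone, each at least the raw value).
#' @export
holm_adjust <- function(p) {
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "holm")
}
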