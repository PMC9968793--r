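test_that("Spearman correlation matches the rank formula", {
  expect_equal(eval_spearman(1:10, (1:10)^3)$rho, 1)
  expect_equal(eval_spearman(1:10, -(1:10))$rho, -1)
  set.seed(2)
  d <- rnorm(8); s <- rnorm(8) # no ties almost surely
  rd <- rank(d); rs <- rank(s)
  oracle <- 1 - 6 * sum((rd - rs)^2) / (8 * (8^2 - 1))
  expect_equal(eval_spearman(d, s)$rho, oracle, tolerance = 1e-10)
  expect_error(eval_spearman(rep(1, 5), rnorm(5)), "constant")
})

test_that("repeated-measures correlation matches the sum-of-squares oracle", {
  # common positive slope, distinct intercepts -> r = 1
  x <- c(1:5, 1:5); y <- c(2 * (1:5) + 10, 2 * (1:5) - 3)
  subj <- rep(c("s1", "s2"), each = 5)
  expect_equal(rm_corr(x, y, subj)$r, 1, tolerance = 1e-10)
  expect_equal(rm_corr(x, y, subj)$df, 7)

  # independent oracle: ANCOVA sums of squares computed from scratch
  set.seed(9)
  x2 <- rnorm(12); y2 <- 0.8 * x2 + rep(rnorm(3, sd = 2), each = 4) + rnorm(12, sd = 0.5)
  subj2 <- rep(c("a", "b", "c"), each = 4)
  res <- rm_corr(x2, y2, subj2)
  # oracle via per-subject centering (equivalent formulation)
  cx <- unlist(lapply(split(x2, subj2), function(v) v - mean(v)))
  cy <- unlist(lapply(split(y2, subj2), function(v) v - mean(v)))
  r_oracle <- sum(cx * cy) / sqrt(sum(cx^2) * sum(cy^2))
  expect_equal(res$r, r_oracle, tolerance = 1e-8)
  expect_equal(res$df, 12 - 3 - 1)

  # slope-zero noise: near-zero correlation on average
  set.seed(10)
  rs <- sapply(1:20, function(i) {
    xx <- rnorm(40); yy <- rnorm(40)
    rm_corr(xx, yy, rep(1:4, each = 10))$r
  })
  expect_lt(abs(mean(rs)), 0.15)

  # single-record subjects dropped with a message
  expect_message(rm_corr(c(x2, 1), c(y2, 1), c(subj2, "solo")), "dropped")
})

test_that("ROC AUC equals the pairwise-comparison oracle", {
  d <- c(1, 1, 1, -1, -1, -1)
  expect_equal(roc_auc(d, c(4, 5, 6, 1, 2, 3))$auc, 1)
  s <- c(0.9, 0.2, 0.7, 0.8, 0.2, 0.1)
  pairwise_auc <- function(delta, sums) {
    pos <- sums[delta > 0]; neg <- sums[delta < 0]
    g <- expand.grid(p = pos, n = neg)
    mean(ifelse(g$p > g$n, 1, ifelse(g$p == g$n, 0.5, 0)))
  }
  expect_equal(roc_auc(d, s)$auc, pairwise_auc(d, s), tolerance = 1e-10)
  set.seed(12)
  d2 <- rep(c(1, -1), each = 20); s2 <- rnorm(40) + 0.5 * d2
  expect_equal(roc_auc(d2, s2)$auc, pairwise_auc(d2, s2), tolerance = 1e-10)
  expect_error(roc_auc(rep(1, 5), rnorm(5)), "one-class")
})

test_that("independence of sign and score gives chance-level AUC over seeds", {
  set.seed(13)
  aucs <- sapply(1:30, function(i)
    roc_auc(rep(c(1, -1), each = 25), rnorm(50))$auc)
  expect_lt(abs(mean(aucs) - 0.5), 0.08)
})

test_that("DeLong's paired test behaves at the extremes", {
  set.seed(14)
  d <- rep(c(1, -1), each = 200)
  good <- d + rnorm(400, sd = 0.5) # AUC near 1
  noise <- rnorm(400)              # AUC near 0.5
  expect_equal(delong_test(d, good, good)$p, 1)
  res <- delong_test(d, good, noise)
  expect_gt(res$auc_a - res$auc_b, 0.3)
  expect_lt(res$p, 0.001)
})

test_that("sign-agreement tables match manual tabulation and transpose under sign flip", {
  d <- c(1, 2, 3, -1, -2, -3, 4, -4)
  s <- c(5, -1, 2, -2, 1, -3, 1, -9)
  tab <- sign_agreement_table(d, s)
  expect_equal(as.vector(tab$table), c(3, 1, 1, 3)) # pos/pos, neg/pos, pos/neg, neg/neg
  expect_equal(tab$agreement, 6 / 8)
  flipped <- sign_agreement_table(d, -s)
  expect_equal(as.vector(flipped$table), c(1, 3, 3, 1))
  expect_message(sign_agreement_table(c(0, 1, -1), c(1, 1, -1)), "excluded")
})

test_that("exact McNemar follows the binomial closed forms", {
  expect_equal(mcnemar_exact(c(TRUE, TRUE), c(TRUE, TRUE))$p, 1)
  a <- rep(TRUE, 10); b <- rep(FALSE, 10)
  expect_equal(mcnemar_exact(a, b)$p, 2 * 0.5^10, tolerance = 1e-12)
  # balanced discordance: p = 1 (two-sided exact binomial at the center)
  a2 <- c(rep(TRUE, 5), rep(FALSE, 5)); b2 <- !a2
  res <- mcnemar_exact(a2, b2)
  expect_equal(res$p, stats::binom.test(5, 10, 0.5)$p.value)
  expect_equal(res$p, 1)
})

test_that("Holm adjustment is the step-down procedure", {
  expect_equal(holm_adjust(0.03), 0.03)
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(rep(0.02, 4)), rep(min(1, 4 * 0.02), 4))
  p <- c(0.001, 0.2, 0.04, 0.9)
  adj <- holm_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
  expect_error(holm_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("bootstrap correlation differences are seeded, centered and powered", {
  set.seed(15)
  delta <- rnorm(60)
  good <- delta + rnorm(60, sd = 0.3)  # strongly correlated
  junk <- rnorm(60)                    # uncorrelated
  unit <- rep(1:20, each = 3)
  self <- bootstrap_corr_diff(delta, good, delta, good, unit, n_boot = 300)
  expect_true(self$ci[1] <= 0 && self$ci[2] >= 0)
  r1 <- riembci:::with_seed(1, bootstrap_corr_diff(delta, good, delta, junk, unit,
                                                   n_boot = 300))
  r2 <- riembci:::with_seed(1, bootstrap_corr_diff(delta, good, delta, junk, unit,
                                                   n_boot = 300))
  expect_identical(r1, r2)
  expect_true(r1$significant)
  expect_gt(r1$diff, 0.3)
  expect_warning(bootstrap_corr_diff(delta, good, delta, junk, unit, n_boot = 50),
                 "100")
})

test_that("full_report is internally consistent and reproducible", {
  set.seed(16)
  n <- 40
  base <- data.frame(session_id = sprintf("s%02d", 1:n), transition = 2)
  delta <- rnorm(n)
  recs <- rbind(
    cbind(base, method = "good", metric = "classDistinct",
          delta = delta, sum = delta + rnorm(n, sd = 0.4)),
    cbind(base, method = "noise", metric = "classDistinct",
          delta = delta, sum = rnorm(n)))
  rep1 <- full_report(recs, n_boot = 200, seed = 3)
  rep2 <- full_report(recs, n_boot = 200, seed = 3)
  expect_identical(rep1, rep2)
  pm <- rep1$per_method[["classDistinct.good"]]
  expect_equal(pm$n, n)
  expect_equal(sum(pm$sign_table), n - sum(delta == 0))
  expect_gt(pm$spearman_rho, rep1$per_method[["classDistinct.noise"]]$spearman_rho)
  pw <- rep1$pairwise$classDistinct$good_vs_noise
  expect_true(all(c("corr_diff", "delong_p_holm", "mcnemar_p_holm") %in% names(pw)))
  expect_gte(pw$delong_p_holm, pw$delong_p)
  # report JSON round-trips
  f <- tempfile(fileext = ".json")
  write_report_json(rep1, f)
  expect_true(file.exists(f))
  expect_silent(jsonlite::read_json(f))
})
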