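make_sep_covs <- function(n_per_class, c1 = diag(c(4, 1, 1.5, 1.5)),
                          c2 = diag(c(1, 4, 1.5, 1.5)),
                          eps = 0.05, seed = 1) {
  set.seed(seed)
  covs <- c(lapply(seq_len(n_per_class), function(i) jitter_spd(c1, eps)),
            lapply(seq_len(n_per_class), function(i) jitter_spd(c2, eps)))
  list(covs = cov_list_to_array(covs),
       labels = factor(rep(c("left", "right"), each = n_per_class)))
}

test_that("CSP filters solve the two-class eigenproblem", {
  # exact diagonal classes: filters align with the coordinate axes
  covs <- cov_list_to_array(list(diag(c(4, 1)), diag(c(4, 1)),
                                 diag(c(1, 4)), diag(c(1, 4))))
  labels <- factor(c("a", "a", "b", "b"))
  mod <- fit_csp(covs, labels, n_filters = 2L)
  for (r in 1:2) {
    w <- abs(mod$filters[r, ]) / max(abs(mod$filters[r, ]))
    expect_equal(sort(w), c(0, 1), tolerance = 1e-8)
  }
  # whitening invariant: W (C1 + C2) W' = I over all filters
  fx <- make_sep_covs(6, eps = 0.2, seed = 3)
  m2 <- fit_csp(fx$covs, fx$labels)
  wcw <- m2$all_filters %*% m2$composite %*% t(m2$all_filters)
  expect_equal(wcw, diag(nrow(wcw)), tolerance = 1e-8)
  # label swap reverses the eigenvalue ordering (same filters, reversed roles)
  m_swap <- fit_csp(fx$covs, factor(fx$labels, levels = rev(levels(fx$labels))))
  expect_equal(sort(m_swap$all_eigenvalues), sort(1 - m2$all_eigenvalues),
               tolerance = 1e-8)
})

test_that("CSP filters are invariant to common channel scaling up to sign", {
  fx <- make_sep_covs(6, eps = 0.2, seed = 4)
  s <- diag(c(2, 0.5, 1, 3))
  covs2 <- fx$covs
  for (i in seq_len(dim(covs2)[3])) covs2[, , i] <- s %*% covs2[, , i] %*% s
  m1 <- fit_csp(fx$covs, fx$labels)
  m2 <- fit_csp(covs2, fx$labels)
  # filtered variances (the features) are identical
  expect_equal(abs(csp_features(m1, fx$covs)), abs(csp_features(m2, covs2)),
               tolerance = 1e-6)
})

test_that("CSP patterns satisfy the forward-model identities", {
  fx <- make_sep_covs(8, eps = 0.2, seed = 5)
  mod <- fit_csp(fx$covs, fx$labels)
  a <- csp_patterns(mod)
  expect_equal(max(abs(a)), 1)
  # W A acts as the identity on filter space (up to the normalization scale)
  wa <- mod$filters %*% a
  expect_equal(wa / wa[1, 1], diag(nrow(wa)), tolerance = 1e-6)
  # orthonormal filters + identity covariance: pattern columns equal filter rows
  q <- qr.Q(qr(matrix(rnorm(4), 2)))
  mod_i <- structure(list(filters = q, composite = diag(2)), class = "csp_model")
  ai <- csp_patterns(mod_i, diag(2))
  expect_equal(ai, t(q) / max(abs(q)), tolerance = 1e-10)
})

test_that("rLDA separates separable features and is symmetric under class swap", {
  set.seed(6)
  x <- cbind(c(rnorm(20, -3), rnorm(20, 3)), rnorm(40))
  y <- factor(rep(c("a", "b"), each = 20))
  mod <- fit_rlda(x, y)
  expect_equal(mean(predict(mod, x) == y), 1)
  mod2 <- fit_rlda(x, factor(y, levels = c("b", "a")))
  expect_equal(mod2$w, -mod$w, tolerance = 1e-10)
  # full shrinkage -> spherical covariance -> boundary normal ∝ mean difference
  z <- x; z[1:20, ] <- sweep(x[1:20, ], 2, colMeans(x[1:20, ]))
  z[21:40, ] <- sweep(x[21:40, ], 2, colMeans(x[21:40, ]))
  sc <- riembci:::shrunk_covariance(z)
  expect_gte(sc$lambda, 0); expect_lte(sc$lambda, 1)
  expect_error(fit_rlda(x, factor(rep("a", 40))), "two classes")
})

test_that("sub-band selection finds the discriminative band deterministically", {
  fx <- make_sep_covs(9, eps = 0.15, seed = 7)
  null_covs <- cov_list_to_array(lapply(seq_len(dim(fx$covs)[3]), function(i)
    jitter_spd(diag(4), 0.15)))
  band_covs <- list("8-11" = null_covs, "9-13" = fx$covs, "17-30" = null_covs)
  sel <- select_subband(band_covs, fx$labels)
  expect_equal(sel$band, "9-13")
  expect_equal(sel$cv_accuracy[["9-13"]], max(sel$cv_accuracy))
  # determinism: identical call, identical result
  expect_identical(sel, select_subband(band_covs, fx$labels))
  # single candidate returned unconditionally
  expect_equal(select_subband(band_covs["8-11"], fx$labels)$band, "8-11")
})

test_that("RWCA is 1 for separable classes, chance for permuted labels, and order-invariant", {
  fx <- make_sep_covs(8, eps = 0.1, seed = 8)
  expect_equal(rwca(fx$covs, fx$labels), 1)
  perm <- sample(length(fx$labels))
  expect_equal(rwca(fx$covs[, , perm], fx$labels[perm]), 1)
  # permuted labels: accuracy near 0.5 on average over seeds
  accs <- sapply(1:8, function(s) {
    set.seed(100 + s)
    rwca(fx$covs, sample(fx$labels))
  })
  expect_gt(mean(accs), 0.25); expect_lt(mean(accs), 0.75)
  expect_error(rwca(fx$covs, factor(rep("a", 16))), "both classes")
})

test_that("classifier reinforcement emits +/-1 with parity-consistent sums", {
  fx <- make_sep_covs(12, eps = 0.15, seed = 9)
  ord <- c(seq(1, 23, 2), seq(2, 24, 2)) # interleave classes across blocks
  covs <- fx$covs[, , ord]; labels <- fx$labels[ord]
  prep <- make_prep(covs, labels, rep(1:2, each = 12),
                    band_covs = list("8-30" = covs))
  tr <- classifier_reinforcement(prep)
  expect_true(all(tr$trace$signal %in% c(-1, 1)))
  expect_equal(nrow(tr$trace), 12)
  expect_equal(tr$sums$sum %% 2, 12 %% 2)
  expect_lte(abs(tr$sums$sum), 12)
  # separable classes: the trained model predicts the held-out block well
  expect_gt(tr$sums$sum, 0)
})
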