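test_that("running engine equals static recomputation at every trial", {
  prep <- sim_cov_prep(n_blocks = 2, per_class = 8, seed = 7)
  tr <- run_session(prep, engine_config("running"))
  for (m in c("classDistinct", "classStability")) {
    engine <- subset(tr$trace, metric == m)$post_value
    expect_equal(engine, static_trace(prep, m), tolerance = 1e-7)
  }
  # trace covers exactly the trials of blocks 2..N, both metrics
  expect_equal(nrow(tr$trace), 2 * sum(prep$blocks != 1))
  # reference equals the static block-1 metrics
  i1 <- which(as.integer(prep$labels) == 1 & prep$blocks == 1)
  i2 <- which(as.integer(prep$labels) == 2 & prep$blocks == 1)
  bm <- block_metrics(prep$cov[, , i1, drop = FALSE], prep$cov[, , i2, drop = FALSE])
  expect_equal(unique(subset(tr$trace, metric == "classDistinct")$reference),
               bm$class_distinct, tolerance = 1e-10)
})

test_that("sliding engine equals running when the queue spans the corpus", {
  prep <- sim_cov_prep(n_blocks = 2, per_class = 8, seed = 9)
  tr_r <- run_session(prep, engine_config("running"))
  tr_s <- run_session(prep, engine_config("sliding_window", queue_length = 1000L))
  expect_equal(tr_s$trace$post_value, tr_r$trace$post_value, tolerance = 1e-7)
  expect_equal(tr_s$sums$sum, tr_r$sums$sum, tolerance = 1e-6)
})

test_that("sliding queue follows FIFO eviction", {
  # distinguishable trials: scaled identities encode their own index
  n <- 12
  covs <- lapply(1:n, function(i) exp(i / 4) * diag(2))
  labs <- rep(c("a", "b"), n / 2)
  prep <- make_prep(covs, labs, rep(1:2, each = n / 2))
  q <- 3L
  tr <- run_session(prep, engine_config("sliding_window", queue_length = q,
                                        subset_size = 2L))
  # after the final trial, queue of class b = the last q class-b trials;
  # its Fréchet mean of scaled identities is the geometric mean -> recover it
  # from the post-trial classStability via the engine's own dispersion:
  labsi <- as.integer(prep$labels)
  bidx <- which(labsi == 2); last_b <- tail(bidx, q)
  aidx <- which(labsi == 1); last_a <- tail(aidx, q)
  bm <- block_metrics(prep$cov[, , last_a, drop = FALSE],
                      prep$cov[, , last_b, drop = FALSE])
  got <- tail(subset(tr$trace, metric == "classDistinct")$post_value, 1)
  expect_equal(got, bm$class_distinct, tolerance = 1e-7)
})

test_that("weighted engine: degenerate weights freeze the previous block", {
  prep <- sim_cov_prep(n_blocks = 2, per_class = 8, seed = 11)
  tr0 <- run_session(prep, engine_config("weighted_average", alpha1 = 0,
                                         alpha2 = 0))
  expect_true(all(abs(tr0$trace$signal) < 1e-9))
})

test_that("weighted engine with alpha = 1 and block-only queue is the static current-block metric", {
  prep <- sim_cov_prep(n_blocks = 2, per_class = 8, seed = 13)
  nt <- 5L
  tr1 <- run_session(prep, engine_config("weighted_average", alpha1 = 1,
                                         alpha2 = 1, queue_length = 100L,
                                         subset_size = nt, seed_queues = FALSE))
  labs <- as.integer(prep$labels)
  cur <- which(prep$blocks == 2)
  # oracle at the last trial of block 2: both classes complete
  i1 <- cur[labs[cur] == 1]; i2 <- cur[labs[cur] == 2]
  m1 <- frechet_mean(prep$cov[, , i1, drop = FALSE])
  m2 <- frechet_mean(prep$cov[, , i2, drop = FALSE])
  p1 <- subset_dispersion(prep$cov[, , i1, drop = FALSE], nt, allow_overlap_tail = TRUE)
  p2 <- subset_dispersion(prep$cov[, , i2, drop = FALSE], nt, allow_overlap_tail = TRUE)
  last <- tail(subset(tr1$trace, metric == "classDistinct"), 1)
  expect_equal(last$post_value,
               riemannian_distance(m1, m2) / (p1 + p2), tolerance = 1e-7)
  last_s <- tail(subset(tr1$trace, metric == "classStability"), 1)
  expect_equal(last_s$post_value,
               mean(c(1 / (1 + p1), 1 / (1 + p2))), tolerance = 1e-7)
})

test_that("weighted engine mean update matches the commuting closed form", {
  # diagonal fixtures commute: geodesic power = element-wise log interpolation
  n <- 20
  covs <- c(rep(list(diag(c(1, 2))), 10), rep(list(diag(c(4, 8))), 10))
  labs <- rep(rep(c("a", "b"), 5), 2)
  prep <- make_prep(covs, labs, rep(1:2, each = 10))
  a1 <- 0.9
  tr <- run_session(prep, engine_config("weighted_average", alpha1 = a1,
                                        queue_length = 5L, subset_size = 5L))
  # prev mean (class a) = diag(1,2); queue mean after block 2 = diag(4,8)
  expected <- diag(exp((1 - a1) * log(c(1, 2)) + a1 * log(c(4, 8))))
  # the engine's post-trial classDistinct at the last trial uses these means;
  # dispersions are all zero -> degenerate ratio, so instead verify via
  # geodesic_power directly (unit check of the update rule used inside):
  expect_equal(geodesic_power(diag(c(1, 2)), diag(c(4, 8)), a1), expected,
               tolerance = 1e-9)
  # and the engine's stability signal is finite and positive-referenced
  expect_true(all(is.finite(subset(tr$trace, metric == "classStability")$signal)))
})

test_that("weighted engine is continuous in the update weights", {
  prep <- sim_cov_prep(n_blocks = 2, per_class = 6, seed = 17)
  t1 <- run_session(prep, engine_config("weighted_average", alpha1 = 0.5, alpha2 = 0.5))
  t2 <- run_session(prep, engine_config("weighted_average", alpha1 = 0.5 + 1e-6,
                                        alpha2 = 0.5 + 1e-6))
  expect_lt(max(abs(t1$trace$post_value - t2$trace$post_value)), 1e-4)
})

test_that("engines are invariant under common full-rank spatial remixing", {
  prep <- sim_cov_prep(n_blocks = 2, per_class = 6, seed = 19)
  set.seed(20)
  w <- matrix(rnorm(9), 3)
  arr <- prep$cov
  for (i in seq_len(dim(arr)[3])) arr[, , i] <- w %*% arr[, , i] %*% t(w)
  prep2 <- prep; prep2$cov <- arr
  for (v in c("running", "sliding_window", "weighted_average")) {
    a <- run_session(prep, engine_config(v))
    b <- run_session(prep2, engine_config(v))
    expect_equal(a$trace$post_value, b$trace$post_value, tolerance = 1e-5)
  }
})

test_that("reinforcement signals and block sums follow the definition", {
  expect_equal(reinforcement_signal(0.5, 0.5), 0)
  expect_equal(reinforcement_signal(0.5, 0.3), 0.2)
  prep <- sim_cov_prep(n_blocks = 3, per_class = 6, seed = 23)
  tr <- run_session(prep, engine_config("running"))
  # block sums equal the independent accumulation of per-trial signals
  for (k in unique(tr$sums$block)) {
    for (m in unique(tr$sums$metric)) {
      rows <- subset(tr$trace, block == k & metric == m)
      expect_equal(sum(rows$post_value - rows$reference),
                   subset(tr$sums, block == k & metric == m)$sum,
                   tolerance = 1e-10)
    }
  }
  expect_error(run_session(make_prep(list(diag(2), diag(2)), c("a", "b"), c(1, 1)),
                           engine_config("running")),
               "single-block")
})

test_that("a session of identical trials yields near-zero running signals", {
  covs <- rep(list(diag(3)), 24)
  prep <- make_prep(covs, rep(c("a", "b"), 12), rep(1:2, each = 12))
  tr <- suppressWarnings(run_session(prep, engine_config("running")))
  stab <- subset(tr$trace, metric == "classStability")
  expect_true(all(abs(stab$signal) < 1e-9))
})
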