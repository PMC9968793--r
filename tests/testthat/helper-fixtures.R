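# Shared fixtures: random SPD matrices, perturbed covariance "classes", and
# a covariance-level session builder that bypasses signal generation.

rand_spd <- function(d, scale = 1) {
  a <- matrix(rnorm(d * d), d)
  scale * (crossprod(a) / d + diag(0.5, d))
}

# SPD perturbation of a base covariance via a near-identity congruence.
jitter_spd <- function(base, eps = 0.1) {
  d <- nrow(base)
  w <- diag(d) + eps * matrix(rnorm(d * d), d)
  w %*% base %*% t(w)
}

# Symmetric matrix functions (independent R-side oracle).
sym_pow_r <- function(s, p) {
  e <- eigen((s + t(s)) / 2, symmetric = TRUE)
  e$vectors %*% diag(e$values^p, nrow(s)) %*% t(e$vectors)
}
sym_log_r <- function(s) {
  e <- eigen((s + t(s)) / 2, symmetric = TRUE)
  e$vectors %*% diag(log(e$values), nrow(s)) %*% t(e$vectors)
}

# Tangent-space gradient norm of the Fréchet objective at G (oracle).
frechet_grad_norm <- function(g, covs) {
  gi <- sym_pow_r(g, -0.5)
  s <- Reduce(`+`, lapply(covs, function(x) sym_log_r(gi %*% x %*% gi)))
  norm(s / length(covs), "F")
}

cov_list_to_array <- function(covs) {
  d <- nrow(covs[[1]])
  arr <- array(0, c(d, d, length(covs)))
  for (i in seq_along(covs)) arr[, , i] <- covs[[i]]
  arr
}

# Covariance-level session: two base covariances per class, per-block scale
# drift optional. Returns a bci_prep-compatible object.
make_prep <- function(covs, labels, blocks, band_covs = list()) {
  arr <- if (is.list(covs)) cov_list_to_array(covs) else covs
  structure(list(cov = arr, band_covs = band_covs,
                 labels = factor(labels), blocks = as.integer(blocks),
                 fs = 250, channels = paste0("ch", seq_len(dim(arr)[1])),
                 meta = list()),
            class = "bci_prep")
}

# Two-class, multi-block covariance fixture with cluster separation `sep`.
sim_cov_prep <- function(n_blocks = 2, per_class = 10, d = 3, sep = 1,
                         eps = 0.15, seed = 1) {
  set.seed(seed)
  base1 <- diag(d)
  base2 <- diag(seq(1, 1 + sep, length.out = d))
  covs <- list(); labels <- c(); blocks <- c()
  for (k in seq_len(n_blocks)) {
    lab <- sample(rep(c("a", "b"), per_class))
    for (l in lab) {
      covs[[length(covs) + 1L]] <-
        jitter_spd(if (l == "a") base1 else base2, eps)
    }
    labels <- c(labels, lab)
    blocks <- c(blocks, rep(k, 2 * per_class))
  }
  make_prep(covs, labels, blocks)
}

# Static recomputation oracle for the running engine: Eqs on the union set
# of all trials up to and including each emitted trial.
static_trace <- function(prep, metric = "classDistinct") {
  labs <- as.integer(prep$labels)
  ub <- sort(unique(prep$blocks))
  vals <- c()
  for (t in seq_along(labs)) {
    if (prep$blocks[t] == ub[1]) next
    i1 <- which(labs[1:t] == 1); i2 <- which(labs[1:t] == 2)
    bm <- block_metrics(prep$cov[, , i1, drop = FALSE],
                        prep$cov[, , i2, drop = FALSE])
    vals <- c(vals, if (metric == "classDistinct") bm$class_distinct
                    else bm$class_stability)
  }
  vals
}
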