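# CSP + shrinkage-regularized LDA baseline: run-wise classification accuracy
# (RWCA), the +/-1 classifier reinforcement signal with temporal sub-band
# selection, and spatial-pattern computation.

#' Fit common spatial patterns (CSP) filters
#'
#' Generalized-eigenvector spatial filters of the two class (arithmetic)
#' mean covariances: rows of the filter matrix `W` jointly diagonalize the
#' class covariances and whiten their sum (`W (C1 + C2) W' = I`). The
#' `n_filters` retained filters are split evenly between the two extremes of
#' the eigenvalue spectrum (most class-1- and most class-2-discriminative).
#'
#' @param covs trial covariances (list or d x d x n array).
#' @param labels two-level factor of class labels, one per trial.
#' @param n_filters number of retained filters (default 4: 2 + 2).
#' @param jitter diagonal loading applied if the composite covariance is
#'   rank-deficient.
#' @return an object of class `csp_model`: `filters` (n_filters x channels),
#'   `eigenvalues`, `composite` (C1 + C2), `classes`.
#' @export
fit_csp <- function(covs, labels, n_filters = 4L, jitter = 1e-10) {
  x <- as_cov_array(covs)
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) stop("exactly two classes required")
  if (any(table(labels) < 2L)) stop("need at least 2 trials per class")
  d <- dim(x)[1]
  if (n_filters > d) stop("more filters than channels")
  cmean <- function(lv) {
    ii <- which(labels == lv)
    m <- matrix(0, d, d)
    for (i in ii) m <- m + x[, , i]
    symmetrize(m / length(ii))
  }
  c1 <- cmean(levels(labels)[1])
  c2 <- cmean(levels(labels)[2])
  comp <- c1 + c2
  ev <- eigen(comp, symmetric = TRUE)
  if (min(ev$values) <= jitter * sum(diag(comp)) / d) {
    comp <- comp + diag(jitter * sum(diag(comp)) / d + 1e-300, d)
    ev <- eigen(comp, symmetric = TRUE)
  }
  # whitening P: P comp P' = I
  p <- diag(1 / sqrt(ev$values)) %*% t(ev$vectors)
  e2 <- eigen(symmetrize(p %*% c1 %*% t(p)), symmetric = TRUE)
  w_all <- t(e2$vectors) %*% p          # rows ordered by decreasing eigenvalue
  half <- n_filters %/% 2L
  sel <- c(seq_len(half), d - seq_len(n_filters - half) + 1L)
  structure(list(filters = w_all[sel, , drop = FALSE],
                 eigenvalues = e2$values[sel],
                 all_filters = w_all, all_eigenvalues = e2$values,
                 composite = comp, classes = levels(labels)),
            class = "csp_model")
}

#' CSP log-variance features
#'
#' The standard CSP feature vector of a trial: the log of the variance of
#' each spatially filtered signal, i.e. `log diag(W C W')` for trial
#' covariance `C`.
#'
#' @param model a [fit_csp()] model.
#' @param covs trial covariances.
#' @return trials x n_filters numeric matrix.
#' @export
csp_features <- function(model, covs) {
  x <- as_cov_array(covs)
  w <- model$filters
  t(apply(x, 3, function(cc) log(diag(w %*% cc %*% t(w)))))
}

#' CSP spatial patterns
#'
#' Forward-model patterns corresponding to the extraction filters:
#' `A = S W' (W S W')^{-1}` with `S` the composite covariance, scaled so the
#' largest absolute entry is 1. Patterns (not filters) are the
#' physiologically interpretable quantity to visualize.
#'
#' @param model a [fit_csp()] model.
#' @param composite covariance used for the transform (defaults to the
#'   model's `C1 + C2`).
#' @return channels x n_filters pattern matrix, max absolute entry 1.
#' @export
csp_patterns <- function(model, composite = model$composite) {
  w <- model$filters
  a <- composite %*% t(w) %*% solve(symmetrize(w %*% composite %*% t(w)))
  a / max(abs(a))
}

# Ledoit-Wolf / Schafer-Strimmer analytic shrinkage of a pooled covariance
# toward nu * I, from class-mean-centered rows z (n x p).
shrunk_covariance <- function(z) {
  n <- nrow(z); p <- ncol(z)
  s <- crossprod(z) / n
  nu <- mean(diag(s))
  target <- diag(nu, p)
  num <- 0
  for (i in seq_len(n)) {
    zi <- tcrossprod(z[i, ])
    num <- num + sum((zi - s)^2)
  }
  num <- num * n / (n - 1)^3
  den <- sum((s - target)^2)
  lambda <- if (den > 0) min(1, max(0, num / den)) else 1
  list(sigma = (1 - lambda) * (s * n / (n - 1)) + lambda * target,
       lambda = lambda)
}

#' Fit a shrinkage-regularized linear discriminant (rLDA)
#'
#' Two-class LDA whose pooled within-class covariance is shrunk toward a
#' scaled identity with an analytically chosen (Ledoit–Wolf-style) intensity,
#' making the fit well-posed when features outnumber trials. The decision
#' function is `sign(w'x + b)`, positive for the second class level.
#'
#' @param x trials x features numeric matrix.
#' @param y two-level factor, one label per row of `x`.
#' @return an object of class `rlda_model`: `w`, `b`, `lambda`, `classes`.
#' @export
fit_rlda <- function(x, y) {
  y <- as.factor(y)
  if (nlevels(y) != 2L) stop("exactly two classes required")
  if (any(table(y) < 2L)) stop("need at least 2 samples per class")
  x <- as.matrix(x)
  m1 <- colMeans(x[y == levels(y)[1], , drop = FALSE])
  m2 <- colMeans(x[y == levels(y)[2], , drop = FALSE])
  z <- x
  z[y == levels(y)[1], ] <- sweep(x[y == levels(y)[1], , drop = FALSE], 2, m1)
  z[y == levels(y)[2], ] <- sweep(x[y == levels(y)[2], , drop = FALSE], 2, m2)
  sc <- shrunk_covariance(z)
  w <- solve(sc$sigma, m2 - m1)
  b <- -sum(w * (m1 + m2)) / 2
  structure(list(w = w, b = b, lambda = sc$lambda, classes = levels(y)),
            class = "rlda_model")
}

#' @param object an `rlda_model`.
#' @param newdata trials x features matrix.
#' @param ... unused.
#' @return factor of predicted class labels.
#' @rdname fit_rlda
#' @export
predict.rlda_model <- function(object, newdata, ...) {
  s <- as.matrix(newdata) %*% object$w + object$b
  factor(ifelse(s > 0, object$classes[2], object$classes[1]),
         levels = object$classes)
}

# Deterministic stratified fold assignment (round-robin within class).
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (lv in levels(y)) {
    ii <- which(y == lv)
    fold[ii] <- ((seq_along(ii) - 1L) %% k) + 1L
  }
  fold
}

# CSP + rLDA accuracy for one train/test split of covariance sets.
csp_rlda_accuracy <- function(covs, labels, train, test, n_filters = 4L) {
  mod <- fit_csp(covs[, , train, drop = FALSE], labels[train], n_filters)
  fx_train <- csp_features(mod, covs[, , train, drop = FALSE])
  lda <- fit_rlda(fx_train, labels[train])
  pred <- predict(lda, csp_features(mod, covs[, , test, drop = FALSE]))
  mean(pred == labels[test])
}

#' Select the best temporal sub-band by cross-validation
#'
#' Stratified 3-fold cross-validation of a CSP + rLDA pipeline on the
#' training trials, one run per candidate passband; the band with the
#' highest mean CV accuracy is selected, ties broken toward the widest band.
#' Fold assignment is deterministic (round-robin within class), so the
#' selection is reproducible.
#'
#' @param band_covs named list of per-band trial covariance arrays
#'   (as produced by [prepare_session()]).
#' @param labels two-level factor, one label per trial.
#' @param k number of CV folds (default 3).
#' @param n_filters CSP filters (default 4).
#' @return list with `band` (selected name), `cv_accuracy` (named vector).
#' @export
select_subband <- function(band_covs, labels, k = 3L, n_filters = 4L) {
  labels <- as.factor(labels)
  if (any(table(labels) < k)) stop("too few trials per class for the CV folds")
  fold <- stratified_folds(labels, k)
  acc <- vapply(band_covs, function(covs) {
    mean(vapply(seq_len(k), function(f)
      csp_rlda_accuracy(covs, labels, which(fold != f), which(fold == f),
                        n_filters), numeric(1)))
  }, numeric(1))
  widths <- vapply(strsplit(names(band_covs), "-"), function(p)
    diff(as.numeric(p)), numeric(1))
  ord <- order(-acc, -widths)
  list(band = names(band_covs)[ord[1]], cv_accuracy = acc)
}

#' Run-wise classification accuracy (RWCA)
#'
#' Leave-one-trial-out cross-validated accuracy of the CSP(4) + rLDA
#' pipeline within a single block: the pipeline is refit on the remaining
#' trials for every held-out trial.
#'
#' @param covs trial covariances of one block.
#' @param labels two-level factor, one label per trial (both classes must be
#'   present).
#' @param n_filters CSP filters (default 4).
#' @return accuracy in \[0, 1\].
#' @export
rwca <- function(covs, labels, n_filters = 4L) {
  x <- as_cov_array(covs)
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) != 2L) stop("block must contain both classes")
  n <- dim(x)[3]
  hits <- vapply(seq_len(n), function(i)
    csp_rlda_accuracy(x, labels, setdiff(seq_len(n), i), i, n_filters),
    numeric(1))
  mean(hits)
}

#' Classifier-based trial-wise reinforcement
#'
#' For every block `k >= 2`, a CSP + rLDA classifier is trained on all trials
#' of blocks `1..k-1` — with the temporal sub-band chosen by stratified
#' 3-fold cross-validation on that training set — and predicts each trial of
#' block `k`. Each trial yields +1 (correct prediction, reward) or -1
#' (incorrect, punishment); the per-block sum lies in `[-n, n]` for an
#' n-trial block.
#'
#' @param prep a [prepare_session()] result with sub-band covariances.
#' @param n_filters CSP filters (default 4).
#' @param session_id identifier copied into the trace.
#' @return an object of class `reinforcement_trace` with
#'   `metric = "classifier"`; the trace also records the predicted and true
#'   labels and the selected band per block.
#' @export
classifier_reinforcement <- function(prep, n_filters = 4L, session_id = NULL) {
  stopifnot(inherits(prep, "bci_prep"))
  if (length(prep$band_covs) == 0L)
    stop("prepare_session() must be run with subbands enabled")
  session_id <- session_id %||% (prep$meta$type %||% "session")
  ub <- sort(unique(prep$blocks))
  if (length(ub) < 2L) stop("single-block session: no training block exists")
  rows <- list()
  for (bi in 2:length(ub)) {
    k <- ub[bi]
    train <- which(prep$blocks %in% ub[seq_len(bi - 1L)])
    test <- which(prep$blocks == k)
    sb <- select_subband(lapply(prep$band_covs, function(a)
      a[, , train, drop = FALSE]), prep$labels[train], n_filters = n_filters)
    covs <- prep$band_covs[[sb$band]]
    mod <- fit_csp(covs[, , train, drop = FALSE], prep$labels[train], n_filters)
    lda <- fit_rlda(csp_features(mod, covs[, , train, drop = FALSE]),
                    prep$labels[train])
    pred <- predict(lda, csp_features(mod, covs[, , test, drop = FALSE]))
    correct <- pred == prep$labels[test]
    rows[[bi - 1L]] <- data.frame(
      session_id = session_id, variant = "classifier", metric = "classifier",
      block = k, trial = test, class = as.character(prep$labels[test]),
      predicted = as.character(pred), band = sb$band,
      post_value = NA_real_, reference = NA_real_,
      signal = ifelse(correct, 1, -1), stringsAsFactors = FALSE)
  }
  trace <- do.call(rbind, rows)
  sums <- stats::aggregate(signal ~ session_id + variant + metric + block,
                           data = trace, FUN = sum)
  names(sums)[names(sums) == "signal"] <- "sum"
  structure(list(trace = trace, sums = sums,
                 config = list(variant = "classifier", n_filters = n_filters)),
            class = "reinforcement_trace")
}
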