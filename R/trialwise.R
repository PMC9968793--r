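# Trial-wise metric engines: after every trial of blocks 2..N, update
# classDistinct / classStability (running, sliding-window or weighted-average
# variant) and emit a reinforcement signal relative to the previous block's
# static value.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Engine configuration for trial-wise metric updates
#'
#' @param variant `"running"` (recompute on all trials so far),
#'   `"sliding_window"` (recompute on fixed-length per-class queues of the
#'   most recent trials), or `"weighted_average"` (geodesic mean update with
#'   weight `alpha1` and subset-dispersion update with weight `alpha2`).
#' @param alpha1 weight of the recent-queue mean in the geodesic mean update
#'   (default 0.9; 0 freezes the previous-block mean, 1 uses only the queue).
#' @param alpha2 weight of the current-block subset dispersion in the
#'   dispersion update (default 0.9).
#' @param queue_length per-class queue length for the sliding-window and
#'   weighted-average variants (default 20, one block's class count).
#' @param subset_size trials per chronological subset for the modified
#'   dispersion \eqn{\Phi^*} (default 5).
#' @param seed_queues seed queues with the most recent previous trials at
#'   each block start (default). `FALSE` clears the queues at each block
#'   start so they hold current-block trials only.
#' @return an object of class `engine_config`.
#' @export
engine_config <- function(variant = c("running", "sliding_window", "weighted_average"),
                          alpha1 = 0.9, alpha2 = 0.9, queue_length = 20L,
                          subset_size = 5L, seed_queues = TRUE) {
  variant <- match.arg(variant)
  if (alpha1 < 0 || alpha1 > 1 || alpha2 < 0 || alpha2 > 1)
    stop("'alpha1' and 'alpha2' must lie in [0, 1]")
  if (queue_length < 1L) stop("'queue_length' must be positive")
  if (queue_length < subset_size)
    stop("'queue_length' must be at least 'subset_size'")
  structure(list(variant = variant, alpha1 = alpha1, alpha2 = alpha2,
                 queue_length = as.integer(queue_length),
                 subset_size = as.integer(subset_size),
                 seed_queues = seed_queues),
            class = "engine_config")
}

#' Trial-wise reinforcement signal
#'
#' The post-trial metric value minus the metric value at the start of the
#' block (the previous block's static value) — positive while the metric
#' exceeds the previous block's level. The block reference, rather than the
#' value after the previous trial, emphasizes gradual trends over volatile
#' trial-to-trial changes.
#'
#' @param post_trial_metric metric value after incorporating the new trial.
#' @param block_reference static metric value of the previous block.
#' @return signed scalar (vectorized).
#' @export
reinforcement_signal <- function(post_trial_metric, block_reference) {
  post_trial_metric - block_reference
}

#' Static block metrics for two trial sets
#'
#' classDistinct and per-class/overall classStability computed on two
#' per-class covariance sets, using the plain intra-class dispersion or,
#' when `subset_size` is given, the chronological subset dispersion
#' \eqn{\Phi^*} (disjoint subsets).
#'
#' @param covs1,covs2 per-class trial covariances (chronological order).
#' @param subset_size `NULL` for the plain dispersion, or \eqn{N_t} for
#'   \eqn{\Phi^*}.
#' @return list with `mean1`, `mean2`, `phi1`, `phi2`, `class_distinct`,
#'   `stability1`, `stability2`, `class_stability` (two-class average).
#' @export
block_metrics <- function(covs1, covs2, subset_size = NULL) {
  x1 <- as_cov_array(covs1); x2 <- as_cov_array(covs2)
  m1 <- frechet_mean(x1); m2 <- frechet_mean(x2)
  if (is.null(subset_size)) {
    p1 <- mean(riem_distances(x1, m1))
    p2 <- mean(riem_distances(x2, m2))
  } else {
    p1 <- subset_dispersion(x1, subset_size)
    p2 <- subset_dispersion(x2, subset_size)
  }
  s1 <- class_stability(p1); s2 <- class_stability(p2)
  list(mean1 = m1, mean2 = m2, phi1 = p1, phi2 = p2,
       class_distinct = class_distinct_from(m1, m2, p1, p2),
       stability1 = s1, stability2 = s2,
       class_stability = overall_class_stability(s1, s2))
}

#' Run a trial-wise metric engine over a session
#'
#' Replays the session trial by trial. Block 1 is warm-up only (no
#' reinforcement is emitted, as no previous-block reference exists). For
#' every trial of blocks 2..N the configured engine updates the class means
#' and dispersions, computes the post-trial classDistinct and (two-class
#' average) classStability, and emits the reinforcement signal relative to
#' the previous block's static value — the plain block metrics for the
#' running and sliding-window variants, the \eqn{\Phi^*}-based ones for the
#' weighted-average variant.
#'
#' @param prep a [prepare_session()] result.
#' @param cfg an [engine_config()].
#' @param session_id identifier copied into the trace (default from the
#'   session metadata, if any).
#' @return an object of class `reinforcement_trace`: list with `trace`
#'   (one row per trial and metric: `session_id`, `variant`, `metric`,
#'   `block`, `trial`, `class`, `post_value`, `reference`, `signal`) and
#'   `sums` (per-block reinforcement sums per metric).
#' @export
run_session <- function(prep, cfg = engine_config(), session_id = NULL) {
  stopifnot(inherits(prep, "bci_prep"), inherits(cfg, "engine_config"))
  session_id <- session_id %||% (prep$meta$type %||% "session")
  covs <- prep$cov
  labs <- as.integer(prep$labels)
  blocks <- prep$blocks
  ub <- sort(unique(blocks))
  if (length(ub) < 2L) stop("single-block session: no reference block exists")
  n <- dim(covs)[3]
  nt <- cfg$subset_size

  rows <- list()
  emit <- function(block, trial, cls, post_d, post_s, refs) {
    rows[[length(rows) + 1L]] <<- data.frame(
      session_id = session_id, variant = cfg$variant,
      metric = c("classDistinct", "classStability"),
      block = block, trial = trial, class = levels(prep$labels)[cls],
      post_value = c(post_d, post_s),
      reference = c(refs$distinct, refs$stability),
      signal = c(post_d - refs$distinct, post_s - refs$stability),
      stringsAsFactors = FALSE)
  }

  # per-class engine state
  state <- list(
    idx = list(`1` = integer(), `2` = integer()),     # running: all trials
    queue = list(`1` = integer(), `2` = integer()),   # sliding/weighted queue
    mean = list(`1` = NULL, `2` = NULL),
    disp = c(0, 0),
    gamma = list(`1` = NULL, `2` = NULL),             # weighted queue means
    prev_mean = list(`1` = NULL, `2` = NULL),
    prev_phi = c(NA_real_, NA_real_),
    cur = list(`1` = integer(), `2` = integer()))
  refs <- NULL

  class_stats <- function(ii, warm = NULL) {
    xs <- covs[, , ii, drop = FALSE]
    m <- frechet_mean(xs, init = warm)
    list(mean = m, disp = mean(riem_distances(xs, m)))
  }

  for (t in seq_len(n)) {
    k <- blocks[t]
    cls <- labs[t]
    first_of_block <- (t == 1L || blocks[t - 1L] != k)

    if (first_of_block && k != ub[1]) {
      # previous-block static references and weighted per-block state
      prev_i <- lapply(1:2, function(c) which(blocks == ub[match(k, ub) - 1L] & labs == c))
      if (cfg$variant == "weighted_average") {
        bm <- block_metrics(covs[, , prev_i[[1]], drop = FALSE],
                            covs[, , prev_i[[2]], drop = FALSE],
                            subset_size = nt)
        state$prev_mean <- list(`1` = bm$mean1, `2` = bm$mean2)
        state$prev_phi <- c(bm$phi1, bm$phi2)
        state$cur <- list(`1` = integer(), `2` = integer())
        if (!cfg$seed_queues) {
          state$queue <- list(`1` = integer(), `2` = integer())
          state$gamma <- list(`1` = NULL, `2` = NULL)
        }
      } else {
        bm <- block_metrics(covs[, , prev_i[[1]], drop = FALSE],
                            covs[, , prev_i[[2]], drop = FALSE])
      }
      refs <- list(distinct = bm$class_distinct, stability = bm$class_stability)
    }

    if (cfg$variant == "running") {
      state$idx[[cls]] <- c(state$idx[[cls]], t)
      cs <- class_stats(state$idx[[cls]], warm = state$mean[[cls]])
      state$mean[[cls]] <- cs$mean
      state$disp[cls] <- cs$disp
      if (k != ub[1]) {
        post_d <- class_distinct_from(state$mean[[1]], state$mean[[2]],
                                      state$disp[1], state$disp[2])
        post_s <- overall_class_stability(class_stability(state$disp[1]),
                                          class_stability(state$disp[2]))
        emit(k, t, cls, post_d, post_s, refs)
      }
    } else if (cfg$variant == "sliding_window") {
      q <- c(state$queue[[cls]], t)
      if (length(q) > cfg$queue_length) q <- q[-1L]  # evict oldest (FIFO)
      state$queue[[cls]] <- q
      cs <- class_stats(q, warm = state$mean[[cls]])
      state$mean[[cls]] <- cs$mean
      state$disp[cls] <- cs$disp
      if (k != ub[1]) {
        if (any(lengths(state$queue) < 2L))
          stop("sliding-window queue underflow: fewer than 2 trials in a class")
        post_d <- class_distinct_from(state$mean[[1]], state$mean[[2]],
                                      state$disp[1], state$disp[2])
        post_s <- overall_class_stability(class_stability(state$disp[1]),
                                          class_stability(state$disp[2]))
        emit(k, t, cls, post_d, post_s, refs)
      }
    } else { # weighted_average
      if (k == ub[1]) {
        # warm-up: maintain the queue only
        q <- c(state$queue[[cls]], t)
        if (length(q) > cfg$queue_length) q <- q[-1L]
        state$queue[[cls]] <- q
        next
      }
      q <- c(state$queue[[cls]], t)
      if (length(q) > cfg$queue_length) q <- q[-1L]
      state$queue[[cls]] <- q
      state$cur[[cls]] <- c(state$cur[[cls]], t)
      state$gamma[[cls]] <- frechet_mean(covs[, , q, drop = FALSE],
                                         init = state$gamma[[cls]])
      post_mean <- list(NULL, NULL)
      post_disp <- c(NA_real_, NA_real_)
      for (c2 in 1:2) {
        g <- state$gamma[[c2]]
        post_mean[[c2]] <- if (is.null(g)) state$prev_mean[[c2]]
                           else geodesic_power_cpp(state$prev_mean[[c2]], g, cfg$alpha1)
        nc <- length(state$cur[[c2]])
        if (nc >= 2L) {
          phi_cur <- subset_dispersion(covs[, , state$cur[[c2]], drop = FALSE],
                                       nt, allow_overlap_tail = TRUE)
          post_disp[c2] <- (1 - cfg$alpha2) * state$prev_phi[c2] + cfg$alpha2 * phi_cur
        } else {
          post_disp[c2] <- state$prev_phi[c2]  # alpha2 update deferred
        }
      }
      post_d <- class_distinct_from(post_mean[[1]], post_mean[[2]],
                                    post_disp[1], post_disp[2])
      post_s <- overall_class_stability(class_stability(post_disp[1]),
                                        class_stability(post_disp[2]))
      emit(k, t, cls, post_d, post_s, refs)
    }
  }

  trace <- do.call(rbind, rows)
  sums <- stats::aggregate(signal ~ session_id + variant + metric + block,
                           data = trace, FUN = sum)
  names(sums)[names(sums) == "signal"] <- "sum"
  structure(list(trace = trace, sums = sums, config = cfg),
            class = "reinforcement_trace")
}

#' @export
print.reinforcement_trace <- function(x, ...) {
  cat(sprintf("<reinforcement_trace> variant %s: %d signals over blocks %s\n",
              x$config$variant, nrow(x$trace),
              paste(sort(unique(x$trace$block)), collapse = " ")))
  print(x$sums)
  invisible(x)
}
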