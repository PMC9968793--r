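# Session-level orchestration: block-wise summaries, the per-transition
# evaluation records pairing block-wise metric changes with trial-wise
# reinforcement sums, corpus evaluation and the machine-readable report.

#' Block-wise performance summary of a session
#'
#' Static metrics per block: classDistinct, per-class and overall
#' classStability, and (optionally) the leave-one-trial-out CSP-rLDA
#' run-wise classification accuracy (RWCA).
#'
#' @param prep a [prepare_session()] result.
#' @param with_rwca compute RWCA per block (default TRUE).
#' @return data frame, one row per block: `session_id`, `block`,
#'   `classDistinct`, `classStability_c1`, `classStability_c2`,
#'   `classStability`, `rwca`.
#' @export
block_summaries <- function(prep, with_rwca = TRUE) {
  stopifnot(inherits(prep, "bci_prep"))
  sid <- prep$meta$type %||% "session"
  ub <- sort(unique(prep$blocks))
  out <- lapply(ub, function(k) {
    ii <- which(prep$blocks == k)
    lv <- levels(prep$labels)
    bm <- block_metrics(prep$cov[, , ii[prep$labels[ii] == lv[1]], drop = FALSE],
                        prep$cov[, , ii[prep$labels[ii] == lv[2]], drop = FALSE])
    data.frame(session_id = sid, block = k,
               classDistinct = bm$class_distinct,
               classStability_c1 = bm$stability1,
               classStability_c2 = bm$stability2,
               classStability = bm$class_stability,
               rwca = if (with_rwca)
                 rwca(prep$cov[, , ii, drop = FALSE], prep$labels[ii])
               else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Evaluation records for one session
#'
#' Pairs, per block transition and method, the block-wise metric change
#' (ground truth) with the trial-wise reinforcement sum (predictor). The
#' metric engines are scored against their cognate metric family; the
#' classifier's +/-1 sums are scored against both families.
#'
#' @param prep a [prepare_session()] result.
#' @param methods subset of
#'   `c("running", "sliding_window", "weighted_average", "classifier")`.
#' @param alpha1,alpha2,queue_length,subset_size engine parameters, see
#'   [engine_config()].
#' @param session_id identifier for the records.
#' @return data frame: `session_id`, `transition` (block index k of the
#'   k-1 to k change), `method`, `metric`, `delta`, `sum`.
#' @export
session_records <- function(prep,
                            methods = c("running", "sliding_window",
                                        "weighted_average", "classifier"),
                            alpha1 = 0.9, alpha2 = 0.9, queue_length = 20L,
                            subset_size = 5L, session_id = NULL) {
  session_id <- session_id %||% (prep$meta$type %||% "session")
  summ <- block_summaries(prep, with_rwca = FALSE)
  ub <- sort(unique(prep$blocks))
  deltas <- data.frame(
    transition = ub[-1],
    classDistinct = diff(summ$classDistinct),
    classStability = diff(summ$classStability))
  rows <- list()
  for (m in methods) {
    if (m == "classifier") {
      tr <- classifier_reinforcement(prep, session_id = session_id)
      for (fam in c("classDistinct", "classStability")) {
        k <- match(tr$sums$block, deltas$transition)
        rows[[length(rows) + 1L]] <- data.frame(
          session_id = session_id, transition = tr$sums$block,
          method = "classifier", metric = fam,
          delta = deltas[[fam]][k], sum = tr$sums$sum,
          stringsAsFactors = FALSE)
      }
    } else {
      cfg <- engine_config(m, alpha1 = alpha1, alpha2 = alpha2,
                           queue_length = queue_length,
                           subset_size = subset_size)
      tr <- run_session(prep, cfg, session_id = session_id)
      k <- match(tr$sums$block, deltas$transition)
      rows[[length(rows) + 1L]] <- data.frame(
        session_id = session_id, transition = tr$sums$block,
        method = m, metric = tr$sums$metric,
        delta = ifelse(tr$sums$metric == "classDistinct",
                       deltas$classDistinct[k], deltas$classStability[k]),
        sum = tr$sums$sum, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Evaluate a corpus of simulated sessions
#'
#' Generates each session of a corpus manifest, preprocesses it and collects
#' its evaluation records. Sessions are materialized one at a time, so
#' memory stays flat in the corpus size.
#'
#' @param manifest a [sim_corpus_manifest()] data frame.
#' @param model a [sim_source_model()].
#' @param progress print a dot per session.
#' @inheritParams session_records
#' @return data frame of records (see [session_records()]) with a `type`
#'   column from the manifest.
#' @export
evaluate_corpus <- function(manifest, model = sim_source_model(),
                            methods = c("running", "sliding_window",
                                        "weighted_average", "classifier"),
                            alpha1 = 0.9, alpha2 = 0.9, queue_length = 20L,
                            subset_size = 5L, progress = FALSE) {
  out <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    ses <- sim_session(manifest$type[i], manifest$seed[i], model)
    prep <- prepare_session(ses, subbands = "classifier" %in% methods)
    rec <- session_records(prep, methods = methods, alpha1 = alpha1,
                           alpha2 = alpha2, queue_length = queue_length,
                           subset_size = subset_size,
                           session_id = manifest$session_id[i])
    rec$type <- manifest$type[i]
    out[[i]] <- rec
    if (progress) cat(".", if (i %% 50 == 0) "\n")
  }
  if (progress) cat("\n")
  do.call(rbind, out)
}

#' Full evaluation report
#'
#' Composes the complete statistical battery from a records table: per
#' method and metric family the Spearman correlation, AUC and sign-agreement
#' table; pairwise method comparisons via bootstrap correlation-difference
#' CIs (Bonferroni level within each family), DeLong's paired AUC tests and
#' exact McNemar tests on sign agreement, the latter two Holm-adjusted
#' within each family.
#'
#' @param records data frame from [session_records()] / [evaluate_corpus()].
#' @param n_boot bootstrap replicates for correlation differences.
#' @param seed seed for the bootstrap resampling.
#' @param pairwise compute the pairwise comparison battery (default TRUE).
#' @return a list (JSON-serializable via [write_report_json()]) with
#'   elements `per_method` and (optionally) `pairwise`.
#' @export
full_report <- function(records, n_boot = 1000L, seed = 1L, pairwise = TRUE) {
  metrics <- unique(records$metric)
  methods <- unique(records$method)
  per_method <- list()
  for (fam in metrics) {
    for (m in methods) {
      r <- records[records$metric == fam & records$method == m, ]
      if (nrow(r) < 3L) next
      sp <- eval_spearman(r$delta, r$sum)
      au <- roc_auc(r$delta, r$sum)
      sg <- sign_agreement_table(r$delta, r$sum)
      per_method[[paste(fam, m, sep = ".")]] <- list(
        metric = fam, method = m, n = nrow(r),
        spearman_rho = sp$rho, spearman_p = sp$p,
        auc = au$auc, sign_agreement = sg$agreement,
        sign_table = as.vector(sg$table),
        negative_sum_share = mean(r$sum < 0))
    }
  }
  out <- list(per_method = per_method)
  if (pairwise && length(methods) > 1L) {
    pairs <- utils::combn(methods, 2, simplify = FALSE)
    family_size <- length(pairs)
    pw <- list()
    for (fam in metrics) {
      delong_p <- c(); mcnemar_p <- c(); entries <- list()
      for (pr in pairs) {
        a <- records[records$metric == fam & records$method == pr[1], ]
        b <- records[records$metric == fam & records$method == pr[2], ]
        key <- paste(a$session_id, a$transition)
        b <- b[match(key, paste(b$session_id, b$transition)), ]
        bc <- with_seed(seed, bootstrap_corr_diff(
          a$delta, a$sum, b$delta, b$sum, unit = a$session_id,
          n_boot = n_boot, family_size = family_size))
        dl <- delong_test(a$delta, a$sum, b$sum)
        mc <- mcnemar_exact(sign(a$sum) == sign(a$delta),
                            sign(b$sum) == sign(b$delta))
        id <- paste(pr, collapse = "_vs_")
        entries[[id]] <- list(
          pair = pr, corr_diff = bc$diff, corr_diff_ci = bc$ci,
          corr_diff_significant = bc$significant,
          auc_a = dl$auc_a, auc_b = dl$auc_b, delong_p = dl$p,
          mcnemar_p = mc$p)
        delong_p[id] <- dl$p
        mcnemar_p[id] <- mc$p
      }
      adj_d <- holm_adjust(delong_p)
      adj_m <- holm_adjust(mcnemar_p)
      for (id in names(entries)) {
        entries[[id]]$delong_p_holm <- unname(adj_d[id])
        entries[[id]]$mcnemar_p_holm <- unname(adj_m[id])
      }
      pw[[fam]] <- entries
    }
    out$pairwise <- pw
  }
  out
}

#' Write an evaluation report as JSON
#'
#' @param report a [full_report()] list.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a reinforcement trace and its block sums as CSV
#'
#' @param trace a `reinforcement_trace` (from [run_session()] or
#'   [classifier_reinforcement()]).
#' @param trace_path,sums_path output CSV paths (`sums_path` optional).
#' @return `trace_path`, invisibly.
#' @export
write_trace_csv <- function(trace, trace_path, sums_path = NULL) {
  utils::write.csv(trace$trace, trace_path, row.names = FALSE)
  if (!is.null(sums_path)) utils::write.csv(trace$sums, sums_path, row.names = FALSE)
  invisible(trace_path)
}
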