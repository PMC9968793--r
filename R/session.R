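# Session container: multichannel EEG trials with class labels and block
# structure, plus the preprocessed (covariance-level) representation the
# metrics operate on.

#' Construct a BCI session container
#'
#' Bundles a trial array with its labels, block indices, sampling rate and
#' channel names. Trials are stored as a `trials x channels x samples` array.
#'
#' @param trials numeric array, trials x channels x samples.
#' @param labels class labels, coercible to a two-level factor
#'   (e.g., `"left"`/`"right"`).
#' @param blocks integer block (run) index per trial, non-decreasing.
#' @param fs sampling rate in Hz.
#' @param channels character vector of channel names (montage order).
#' @param meta optional list of free-form metadata (e.g., simulation type).
#' @return an object of class `bci_session`.
#' @export
bci_session <- function(trials, labels, blocks, fs, channels = NULL, meta = list()) {
  if (!is.array(trials) || length(dim(trials)) != 3L)
    stop("'trials' must be a trials x channels x samples array")
  n <- dim(trials)[1]
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) stop("exactly two classes are supported")
  if (length(labels) != n || length(blocks) != n)
    stop("'labels' and 'blocks' must have one entry per trial")
  blocks <- as.integer(blocks)
  if (is.unsorted(blocks)) stop("'blocks' must be non-decreasing (chronological order)")
  if (is.null(channels)) channels <- paste0("ch", seq_len(dim(trials)[2]))
  if (length(channels) != dim(trials)[2])
    stop("'channels' must name every channel")
  structure(list(trials = trials, labels = labels, blocks = blocks,
                 fs = fs, channels = channels, meta = meta),
            class = "bci_session")
}

#' @export
print.bci_session <- function(x, ...) {
  d <- dim(x$trials)
  cat(sprintf("<bci_session> %d trials, %d channels, %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  cat(sprintf("  classes: %s | blocks: %s\n",
              paste(levels(x$labels), collapse = "/"),
              paste(sort(unique(x$blocks)), collapse = " ")))
  if (length(x$meta)) cat("  meta:", paste(names(x$meta), collapse = ", "), "\n")
  invisible(x)
}

#' Candidate temporal sub-bands for classifier training
#'
#' The five passbands screened by cross-validation when training the
#' classifier baseline: 8–11, 9–13, 11–19, 17–30 and 8–30 Hz.
#'
#' @return named list of `c(low, high)` passbands in Hz.
#' @export
classifier_subbands <- function() {
  list("8-11" = c(8, 11), "9-13" = c(9, 13), "11-19" = c(11, 19),
       "17-30" = c(17, 30), "8-30" = c(8, 30))
}

#' Preprocess a session into trial covariance matrices
#'
#' Applies the standard pipeline: zero-phase band-pass filtering of each full
#' trial, extraction of the central epoch, and per-trial spatial covariance
#' estimation. Optionally repeats the filtering for each candidate classifier
#' sub-band so the classifier baseline can select its band without access to
#' the raw signals.
#'
#' @param session a [bci_session()].
#' @param passband main analysis passband in Hz (default 8–30).
#' @param epoch_seconds duration of the central epoch used for covariance
#'   estimation (default 2 s).
#' @param filter_order Butterworth design order (default 4).
#' @param subbands `TRUE` to precompute covariances for
#'   [classifier_subbands()], `FALSE` to skip, or a named list of passbands.
#' @return an object of class `bci_prep` holding `cov` (d x d x n array for
#'   the main band), `band_covs` (per-sub-band arrays), `labels`, `blocks`,
#'   `fs`, `channels`.
#' @export
prepare_session <- function(session, passband = c(8, 30), epoch_seconds = 2,
                            filter_order = 4, subbands = TRUE) {
  stopifnot(inherits(session, "bci_session"))
  if (isTRUE(subbands)) subbands <- classifier_subbands()
  if (isFALSE(subbands)) subbands <- list()
  main_key <- paste0(passband[1], "-", passband[2])

  bands <- subbands
  if (!main_key %in% names(bands)) bands[[main_key]] <- passband

  d <- dim(session$trials)[2]
  n <- dim(session$trials)[1]
  band_covs <- list()
  for (bn in names(bands)) {
    filtered <- bandpass_filter(session$trials, session$fs,
                                bands[[bn]][1], bands[[bn]][2],
                                order = filter_order)
    epochs <- epoch_center(filtered, session$fs, epoch_seconds)
    covs <- array(0, c(d, d, n))
    for (i in seq_len(n)) covs[, , i] <- trial_covariance(epochs[i, , ])
    band_covs[[bn]] <- covs
  }
  structure(list(cov = band_covs[[main_key]],
                 band_covs = band_covs[names(subbands)],
                 labels = session$labels, blocks = session$blocks,
                 fs = session$fs, channels = session$channels,
                 meta = session$meta),
            class = "bci_prep")
}

#' @export
print.bci_prep <- function(x, ...) {
  cat(sprintf("<bci_prep> %d trial covariances (%d x %d), blocks: %s\n",
              dim(x$cov)[3], dim(x$cov)[1], dim(x$cov)[2],
              paste(sort(unique(x$blocks)), collapse = " ")))
  invisible(x)
}

# Internal: covariance slices of one class (optionally restricted to blocks).
class_cov <- function(prep, class_level, trials = NULL) {
  sel <- prep$labels == class_level
  if (!is.null(trials)) sel <- sel & seq_along(prep$labels) %in% trials
  prep$cov[, , which(sel), drop = FALSE]
}
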