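# Filtering, epoching, decimation and Riemannian potato-field artifact
# rejection.

#' Zero-phase Butterworth band filtering
#'
#' Designs an order-`order` Butterworth band-pass (or band-stop) filter and
#' applies it forward and backward (`signal::filtfilt`), giving zero phase
#' shift. Accepts a single-channel vector, a channels x samples matrix, or a
#' trials x channels x samples array.
#'
#' @param x numeric vector, matrix, or 3-d array.
#' @param fs sampling rate in Hz.
#' @param low,high band edges in Hz; `high` must be below the Nyquist rate.
#' @param type `"pass"` (default) or `"stop"`.
#' @param order Butterworth design order (default 4).
#' @return filtered object of the same shape as `x`.
#' @export
bandpass_filter <- function(x, fs, low, high, type = c("pass", "stop"), order = 4) {
  type <- match.arg(type)
  if (!(low > 0 && low < high)) stop("need 0 < low < high")
  if (high >= fs / 2) stop("'high' must be below the Nyquist frequency")
  flt <- signal::butter(order, c(low, high) / (fs / 2), type = type)
  f1 <- function(v) as.vector(filtfilt_cpp(flt$b, flt$a, v))
  if (is.vector(x)) return(f1(x))
  if (is.matrix(x)) return(t(apply(x, 1, f1)))
  if (is.array(x) && length(dim(x)) == 3L) {
    out <- x
    for (i in seq_len(dim(x)[1]))
      for (j in seq_len(dim(x)[2]))
        out[i, j, ] <- f1(x[i, j, ])
    return(out)
  }
  stop("'x' must be a vector, matrix or 3-d array")
}

#' Extract the central epoch of each trial
#'
#' Returns the window of `seconds` duration centered on the trial midpoint
#' (e.g., the middle two seconds of a four-second trial). Indices are
#' computed 0-based, half-open: a 4 s trial at 250 Hz with a 2 s window
#' keeps samples 250..749 (R indices 251:750).
#'
#' @param x channels x samples matrix or trials x channels x samples array.
#' @param fs sampling rate in Hz.
#' @param seconds window duration; must not exceed the trial duration.
#' @return object of the same kind as `x` with `seconds * fs` samples.
#' @export
epoch_center <- function(x, fs, seconds) {
  ns <- if (is.matrix(x)) ncol(x) else dim(x)[3]
  w <- round(seconds * fs)
  if (w > ns) stop("window longer than the trial")
  start0 <- (ns - w) %/% 2L # 0-based start
  idx <- (start0 + 1L):(start0 + w)
  if (is.matrix(x)) x[, idx, drop = FALSE] else x[, , idx, drop = FALSE]
}

#' Anti-aliased integer-ratio downsampling
#'
#' Decimates each channel by the integer factor `from_rate / to_rate` after
#' low-pass filtering (via `signal::decimate`).
#'
#' @param x vector, channels x samples matrix, or trials x channels x samples
#'   array.
#' @param from_rate,to_rate original and target sampling rates in Hz;
#'   the ratio must be an integer.
#' @return decimated object of the same kind as `x`.
#' @export
downsample <- function(x, from_rate, to_rate) {
  q <- from_rate / to_rate
  if (abs(q - round(q)) > 1e-9 || q < 1)
    stop("from_rate must be an integer multiple of to_rate")
  q <- as.integer(round(q))
  if (q == 1L) return(x)
  f1 <- function(v) signal::decimate(v, q, ftype = "fir")
  if (is.vector(x)) return(f1(x))
  if (is.matrix(x)) return(t(apply(x, 1, f1)))
  out_len <- length(f1(x[1, 1, ]))
  out <- array(0, c(dim(x)[1], dim(x)[2], out_len))
  for (i in seq_len(dim(x)[1]))
    for (j in seq_len(dim(x)[2]))
      out[i, j, ] <- f1(x[i, j, ])
  out
}

#' Riemannian potato-field specification
#'
#' The default field comprises five electrode contact-loss detectors on
#' channel pairs (F3-C3, P3-Pz, Fz-F4, Cz-C4, C4-P4), band-passed 1–20 Hz,
#' and three general artifact detectors on channel quadruples
#' (F3-C3-P3-Pz, Fz-F4-Cz-C4, P4-Pz-Fz-F4), band-stopped 8–38 Hz. Each
#' potato flags a trial whose covariance lies more than `z_threshold`
#' standard deviations (in Riemannian distance) from the calibration mean.
#'
#' @param pairs list of 2-channel character vectors (contact-loss detectors).
#' @param quads list of 4-channel character vectors (general detectors).
#' @param pair_band,quad_band passbands in Hz for the two detector families.
#' @param quad_type filter type for the general detectors (`"stop"` default).
#' @param z_threshold rejection z-score threshold (default 2.5).
#' @return an object of class `potato_field_spec`.
#' @export
potato_field_spec <- function(
    pairs = list(c("F3", "C3"), c("P3", "Pz"), c("Fz", "F4"),
                 c("Cz", "C4"), c("C4", "P4")),
    quads = list(c("F3", "C3", "P3", "Pz"), c("Fz", "F4", "Cz", "C4"),
                 c("P4", "Pz", "Fz", "F4")),
    pair_band = c(1, 20), quad_band = c(8, 38), quad_type = "stop",
    z_threshold = 2.5) {
  structure(list(pairs = pairs, quads = quads, pair_band = pair_band,
                 quad_band = quad_band, quad_type = quad_type,
                 z_threshold = z_threshold),
            class = "potato_field_spec")
}

#' Offline potato-field artifact rejection
#'
#' Calibrates every potato on the subject's entire trial set (single pass):
#' per potato, the filtered channel-subset covariances of all trials, their
#' Fréchet mean as reference, and the mean/sd of the Riemannian distances to
#' it. A trial's z-score per potato is
#' `(distance - mean distance) / sd distance`; a trial is rejected when ANY
#' potato flags it above `z_threshold`. Deterministic given the inputs.
#'
#' @param session a [bci_session()]; channel names must cover the spec.
#' @param spec a [potato_field_spec()].
#' @return list with `keep` (indices of retained trials), `rejected`
#'   (indices removed) and `report` (data frame: trial, potato, z, flagged).
#' @export
potato_field_reject <- function(session, spec = potato_field_spec()) {
  stopifnot(inherits(session, "bci_session"))
  groups <- c(lapply(spec$pairs, function(p) list(ch = p, band = spec$pair_band, type = "pass")),
              lapply(spec$quads, function(p) list(ch = p, band = spec$quad_band, type = spec$quad_type)))
  n <- dim(session$trials)[1]
  report <- list()
  flagged <- rep(FALSE, n)
  for (g in seq_along(groups)) {
    grp <- groups[[g]]
    ci <- match(grp$ch, session$channels)
    if (anyNA(ci))
      stop(sprintf("potato channels missing from montage: %s",
                   paste(grp$ch[is.na(ci)], collapse = ", ")))
    sub <- session$trials[, ci, , drop = FALSE]
    filt <- bandpass_filter(sub, session$fs, grp$band[1], grp$band[2], type = grp$type)
    covs <- array(0, c(length(ci), length(ci), n))
    for (i in seq_len(n)) covs[, , i] <- trial_covariance(filt[i, , ])
    ref <- frechet_mean(covs)
    dists <- riem_distances(covs, ref)
    sdd <- stats::sd(dists)
    z <- if (sdd > 0) (dists - mean(dists)) / sdd else rep(0, n)
    flag <- z > spec$z_threshold
    flagged <- flagged | flag
    report[[g]] <- data.frame(trial = seq_len(n),
                              potato = paste(grp$ch, collapse = "-"),
                              z = z, flagged = flag)
  }
  list(keep = which(!flagged), rejected = which(flagged),
       report = do.call(rbind, report))
}
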