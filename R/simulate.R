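# Synthetic two-class SMR-EEG session generator. Emulates the covariance
# structure of left/right hand motor-imagery EEG under three user-performance
# levels (low / moderate / high) and seven two-block session types, using a
# 9-channel linear mixing model with sensorimotor-rhythm sources over the
# left and right motor cortices.

SESSION_TYPES <- c("LM", "LH", "ML", "MH", "HL", "HM", "NC")
LEVELS <- c("low", "moderate", "high")

# Approximate 10-20 scalp coordinates for the 9-channel montage.
montage_positions <- function() {
  rbind(Fz = c(0, 0.40), F4 = c(0.35, 0.40), C4 = c(0.40, 0),
        Cz = c(0, 0),    P4 = c(0.35, -0.40), Pz = c(0, -0.40),
        P3 = c(-0.35, -0.40), C3 = c(-0.40, 0), F3 = c(-0.35, 0.40))
}

#' Source model for the SMR session simulator
#'
#' Two band-limited sensorimotor-rhythm (SMR) sources located over the left
#' (C3) and right (C4) motor cortices project to the 9-channel montage
#' through Gaussian spatial profiles; background activity is modelled as a
#' broadly projecting common 1/f source, per-channel 1/f noise and white
#' sensor noise. Event-related desynchronization (ERD) is an amplitude
#' attenuation of the SMR source on the desynchronizing hemisphere.
#'
#' Amplitudes were calibrated once so that high-performance blocks yield a
#' leave-one-trial-out CSP-rLDA accuracy (RWCA) in roughly 0.8–0.95, and are
#' fixed thereafter.
#'
#' @param fs sampling rate in Hz (default 250).
#' @param trial_seconds trial duration in seconds (default 4).
#' @param smr_amp baseline SMR source amplitude.
#' @param erd_gain multiplicative amplitude factor applied to a
#'   desynchronized source (1 = no ERD, smaller = deeper ERD; default 0.5).
#' @param amp_jitter log-sd of the lognormal per-trial, per-source SMR
#'   amplitude fluctuation (0 = constant amplitude).
#' @param block_jitter log-sd of the lognormal block-level drift applied to
#'   the SMR and background-noise amplitudes — the slow covariate shift
#'   between recording blocks that is characteristic of EEG sessions
#'   (0 = stationary blocks).
#' @param noise_channel_amp per-channel 1/f noise amplitude.
#' @param noise_common_amp shared broad-field 1/f noise amplitude.
#' @param sensor_amp white sensor-noise amplitude.
#' @param spatial_sigma width of the Gaussian source projection profiles.
#' @return an object of class `sim_source_model`.
#' @export
sim_source_model <- function(fs = 250, trial_seconds = 4, smr_amp = 2.0,
                             erd_gain = 0.5, amp_jitter = 0.3,
                             block_jitter = 0.25, noise_channel_amp = 1.0,
                             noise_common_amp = 0.8, sensor_amp = 0.4,
                             spatial_sigma = 0.30) {
  pos <- montage_positions()
  profile <- function(src) {
    d2 <- rowSums(sweep(pos, 2, src)^2)
    exp(-d2 / (2 * spatial_sigma^2))
  }
  structure(list(fs = fs, trial_seconds = trial_seconds,
                 channels = rownames(pos),
                 mix_left = profile(pos["C3", ]),   # left-cortex SMR source
                 mix_right = profile(pos["C4", ]),  # right-cortex SMR source
                 mix_common = rep(1, nrow(pos)),
                 smr_amp = smr_amp, erd_gain = erd_gain,
                 amp_jitter = amp_jitter, block_jitter = block_jitter,
                 noise_channel_amp = noise_channel_amp,
                 noise_common_amp = noise_common_amp,
                 sensor_amp = sensor_amp),
            class = "sim_source_model")
}

# 1/f ("pink") noise via spectral shaping, unit variance.
pink_noise <- function(n) {
  x <- stats::fft(stats::rnorm(n))
  k <- seq_len(n) - 1
  f <- pmin(k, n - k)
  f[1] <- 1
  x <- x / sqrt(f)
  v <- Re(stats::fft(x, inverse = TRUE)) / n
  v / stats::sd(v)
}

# Band-limited oscillatory source: alpha-band carrier plus beta harmonic.
smr_source <- function(n, fs) {
  alpha <- bandpass_filter(stats::rnorm(n), fs, 8, 13, order = 4)
  beta <- bandpass_filter(stats::rnorm(n), fs, 16, 26, order = 4)
  s <- alpha / stats::sd(alpha) + 0.3 * beta / stats::sd(beta)
  s / stats::sd(s)
}

# Which hemisphere desynchronizes for a given level/task; `coin` resolves the
# moderate level's inconsistent right-hand trials (TRUE = contralateral).
erd_sides <- function(level, task, coin = TRUE) {
  switch(level,
    low = "right",
    moderate = if (task == "left") "right" else if (coin) "left" else "right",
    high = if (task == "left") "right" else "left",
    stop("unknown level: ", level))
}

#' Generate one simulated motor-imagery trial
#'
#' SMR source amplitudes are scaled according to the performance level's
#' lateralization rule: the source on the desynchronizing hemisphere is
#' attenuated by the model's `erd_gain`. At the low level both tasks
#' desynchronize the right motor cortex; at the moderate level the left-hand
#' task is consistent while the right-hand task is contralateral only with
#' probability one half; at the high level both tasks produce a clean
#' contralateral ERD.
#'
#' @param level `"low"`, `"moderate"` or `"high"`.
#' @param task `"left"` or `"right"` hand motor imagery.
#' @param model a [sim_source_model()].
#' @param coin for the moderate level's right-hand trials: `TRUE` for a
#'   contralateral (correct) ERD, `FALSE` for an ipsilateral one, `NA` to
#'   draw Bernoulli(0.5).
#' @return channels x samples matrix.
#' @export
generate_trial <- function(level, task, model = sim_source_model(), coin = NA) {
  level <- match.arg(level, LEVELS)
  task <- match.arg(task, c("left", "right"))
  if (is.na(coin)) coin <- stats::runif(1) < 0.5
  side <- erd_sides(level, task, coin)
  n <- round(model$fs * model$trial_seconds)
  jit <- exp(stats::rnorm(2, sd = model$amp_jitter)) # per-source SMR fluctuation
  gl <- (if (side == "left") model$erd_gain else 1) * jit[1]
  gr <- (if (side == "right") model$erd_gain else 1) * jit[2]
  x <- outer(model$mix_left, gl * model$smr_amp * smr_source(n, model$fs)) +
       outer(model$mix_right, gr * model$smr_amp * smr_source(n, model$fs)) +
       outer(model$mix_common, model$noise_common_amp * pink_noise(n))
  for (ch in seq_len(nrow(x)))
    x[ch, ] <- x[ch, ] + model$noise_channel_amp * pink_noise(n)
  x + model$sensor_amp * matrix(stats::rnorm(length(x)), nrow(x))
}

# One block of interleaved balanced trials at a given level. Block-level
# lognormal drift of the SMR and background amplitudes emulates the slow
# covariate shift between recording blocks.
generate_block <- function(level, model, n_trials = 40L, exact_half = TRUE) {
  drift <- exp(stats::rnorm(2, sd = model$block_jitter))
  model$smr_amp <- model$smr_amp * drift[1]
  model$noise_common_amp <- model$noise_common_amp * drift[2]
  per_class <- n_trials %/% 2L
  labels <- sample(rep(c("left", "right"), per_class))
  coins <- rep(NA, n_trials)
  if (exact_half && level == "moderate") {
    ri <- which(labels == "right")
    good <- sample(ri, length(ri) %/% 2L)
    coins[ri] <- FALSE
    coins[good] <- TRUE
  }
  arr <- array(0, c(n_trials, length(model$channels),
                    round(model$fs * model$trial_seconds)))
  for (i in seq_len(n_trials))
    arr[i, , ] <- generate_trial(level, labels[i], model, coin = coins[i])
  list(trials = arr, labels = labels)
}

with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Generate a simulated two-block BCI session
#'
#' Session types follow the two-letter level codes (block 1, block 2):
#' `LM`, `LH`, `ML`, `MH`, `HL`, `HM`, plus `NC` ("no change"), for which a
#' single level is drawn uniformly and used for both blocks. Each block
#' holds `n_trials` trials (half per class, interleaved in seeded random
#' order). The same seed reproduces the session bit for bit.
#'
#' @param type one of `"LM","LH","ML","MH","HL","HM","NC"`.
#' @param seed integer seed for the session's private RNG stream.
#' @param model a [sim_source_model()].
#' @param n_trials trials per block (default 40; 20 per class).
#' @param exact_half resolve the moderate level's "half the trials" rule as
#'   exactly half per block (default) rather than Bernoulli(0.5) per trial.
#' @return a [bci_session()] with `meta$type`, `meta$levels`, `meta$seed`.
#' @export
sim_session <- function(type, seed, model = sim_source_model(),
                        n_trials = 40L, exact_half = TRUE) {
  type <- match.arg(type, SESSION_TYPES)
  with_seed(seed, {
    lv <- if (type == "NC") rep(sample(LEVELS, 1L), 2L)
          else c(low = "low", moderate = "moderate", high = "high")[
            match(strsplit(type, "")[[1]], c("L", "M", "H"))]
    lv <- unname(lv)
    b1 <- generate_block(lv[1], model, n_trials, exact_half)
    b2 <- generate_block(lv[2], model, n_trials, exact_half)
    trials <- array(0, c(2L * n_trials, dim(b1$trials)[2], dim(b1$trials)[3]))
    trials[seq_len(n_trials), , ] <- b1$trials
    trials[n_trials + seq_len(n_trials), , ] <- b2$trials
    bci_session(trials,
                labels = c(b1$labels, b2$labels),
                blocks = rep(1:2, each = n_trials),
                fs = model$fs, channels = model$channels,
                meta = list(type = type, levels = lv, seed = seed))
  })
}

#' Manifest for a corpus of simulated sessions
#'
#' Derives one reproducible seed per session from a base seed: `n_per_type`
#' sessions of each changing type (`LM`, `LH`, `ML`, `MH`, `HL`, `HM`) plus
#' `n_per_type` no-change (`NC`) sessions — seven groups in total.
#'
#' @param n_per_type sessions per type.
#' @param seed base seed.
#' @param types session types to include (default all seven).
#' @return data frame with columns `session_id`, `type`, `seed`.
#' @export
sim_corpus_manifest <- function(n_per_type, seed, types = SESSION_TYPES) {
  types <- match.arg(types, SESSION_TYPES, several.ok = TRUE)
  n <- n_per_type * length(types)
  with_seed(seed, {
    data.frame(session_id = sprintf("S%03d", seq_len(n)),
               type = rep(types, each = n_per_type),
               seed = sample.int(.Machine$integer.max - 1L, n),
               stringsAsFactors = FALSE)
  })
}

#' Generate a corpus of simulated sessions
#'
#' Materializes every session listed in a corpus manifest. For large corpora
#' prefer iterating over [sim_corpus_manifest()] with [sim_session()] (as
#' [evaluate_corpus()] does) to avoid holding all raw signals in memory.
#'
#' @inheritParams sim_corpus_manifest
#' @param model a [sim_source_model()].
#' @return list with `sessions` (list of [bci_session()]) and `manifest`.
#' @export
sim_corpus <- function(n_per_type, seed, types = SESSION_TYPES,
                       model = sim_source_model()) {
  manifest <- sim_corpus_manifest(n_per_type, seed, types)
  sessions <- lapply(seq_len(nrow(manifest)), function(i)
    sim_session(manifest$type[i], manifest$seed[i], model))
  names(sessions) <- manifest$session_id
  list(sessions = sessions, manifest = manifest)
}
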