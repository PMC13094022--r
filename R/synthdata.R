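#' Temporal envelope constructors
#'
#' Envelopes describe how a planted class effect waxes and wanes over the
#' epoch. Three families are provided:
#'
#' * `envelope_boxcar(window)` — constant 1 inside `window` (ms), 0 outside.
#' * `envelope_ramp(window)` — linear rise from 0 at `window[1]` to 1 at
#'   `window[2]`, 0 outside.
#' * `envelope_fig6(peak_time, decay_rate, onset)` — zero before `onset`,
#'   linear rise to 1 at `peak_time`, then exponential decay at
#'   `decay_rate` (1/ms). With earlier peaks paired to faster decays this
#'   family produces the early-strong/fast-decay versus late-weak/persistent
#'   response profiles that yield full retrograde but diminishing anterograde
#'   generalization when decoded.
#'
#' @param window length-2 ms pair.
#' @param peak_time,decay_rate,onset fig6-curve parameters (ms, 1/ms, ms).
#' @return An object of class `tf_envelope`.
#' @export
envelope_boxcar <- function(window) {
  stopifnot(length(window) == 2L, window[1] < window[2])
  structure(list(type = "boxcar", window = as.numeric(window)),
            class = "tf_envelope")
}

#' @rdname envelope_boxcar
#' @export
envelope_ramp <- function(window) {
  stopifnot(length(window) == 2L, window[1] < window[2])
  structure(list(type = "ramp", window = as.numeric(window)),
            class = "tf_envelope")
}

#' @rdname envelope_boxcar
#' @export
envelope_fig6 <- function(peak_time, decay_rate, onset = 0) {
  stopifnot(onset <= peak_time, decay_rate >= 0)
  structure(list(type = "fig6", peak_time = peak_time,
                 decay_rate = decay_rate, onset = onset),
            class = "tf_envelope")
}

#' Evaluate an envelope on a time grid
#'
#' @param env a `tf_envelope`.
#' @param t numeric vector of times in ms.
#' @return numeric vector of non-negative envelope values.
#' @export
eval_envelope <- function(env, t) {
  stopifnot(inherits(env, "tf_envelope"))
  switch(env$type,
    boxcar = as.numeric(t >= env$window[1] & t <= env$window[2]),
    ramp = {
      v <- (t - env$window[1]) / diff(env$window)
      v[t < env$window[1] | t > env$window[2]] <- 0
      v
    },
    fig6 = fig6_envelope(t, env$peak_time, env$decay_rate, env$onset),
    stop("unknown envelope type: ", env$type))
}

#' Early-strong/fast-decay response envelope
#'
#' Unimodal curve: zero before `onset`, linear rise to 1 at `peak_time`,
#' exponential decay afterwards. The linear rise keeps every electrode
#' informative soon after onset, so late-peaking responses still carry
#' signal at early timepoints. In the limit `decay_rate -> 0` the envelope
#' is non-decreasing after onset (a static code). For two envelopes with
#' `peak_1 < peak_2` and `decay_1 > decay_2`, curve 1 crosses below curve 2
#' at some time after `peak_1`.
#'
#' @param t time grid in ms.
#' @param peak_time time of the maximum, ms.
#' @param decay_rate exponential decay constant after the peak, 1/ms.
#' @param onset response onset, ms; must not exceed `peak_time`.
#' @return envelope values in `[0, 1]`.
#' @export
fig6_envelope <- function(t, peak_time, decay_rate, onset = 0) {
  if (onset > peak_time) stop("onset must not exceed peak_time")
  if (decay_rate < 0) stop("decay_rate must be non-negative")
  v <- numeric(length(t))
  rise <- t >= onset & t <= peak_time
  if (peak_time > onset) {
    v[rise] <- (t[rise] - onset) / (peak_time - onset)
  } else {
    v[rise] <- 1
  }
  fall <- t > peak_time
  v[fall] <- exp(-decay_rate * (t[fall] - peak_time))
  v
}

#' Specify a planted class effect
#'
#' A band-limited oscillation added to a set of electrodes whose amplitude at
#' time t is `envelope(t) * amplitude_by_class[class]`. A sign schedule can
#' flip which class receives the larger amplitude over stated intervals,
#' planting a dynamically changing (sign-reversing) code.
#'
#' @param electrodes integer indices of the carrying electrodes.
#' @param freq_band length-2 Hz pair; per trial the carrier frequency is
#'   drawn uniformly within the band.
#' @param amplitude_by_class length-2 numeric `(animate, inanimate)` in the
#'   units of the background noise SD.
#' @param envelope a `tf_envelope`.
#' @param sign_schedule optional data.frame with columns `start`, `end` (ms)
#'   and `sign` (+1 keeps, -1 swaps the class amplitudes); intervals must not
#'   overlap. `NULL` means the code direction is constant.
#' @param phase `"random"` (uniform per trial; phase carries no class
#'   information, so phase decoding fails by construction) or `"locked"`
#'   (phase 0 for animate, pi for inanimate trials, planting a phase code).
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(electrodes, freq_band, amplitude_by_class,
                        envelope, sign_schedule = NULL, phase = "random") {
  stopifnot(length(freq_band) == 2L, freq_band[1] > 0,
            freq_band[1] <= freq_band[2],
            length(amplitude_by_class) == 2L,
            inherits(envelope, "tf_envelope"))
  phase <- match.arg(phase, c("random", "locked"))
  if (!is.null(sign_schedule)) {
    sign_schedule <- as.data.frame(sign_schedule)
    stopifnot(all(c("start", "end", "sign") %in% names(sign_schedule)),
              all(sign_schedule$sign %in% c(-1, 1)))
    o <- order(sign_schedule$start)
    sign_schedule <- sign_schedule[o, , drop = FALSE]
    if (nrow(sign_schedule) > 1L &&
        any(sign_schedule$start[-1L] <
            sign_schedule$end[-nrow(sign_schedule)]))
      stop("sign_schedule intervals must not overlap")
  }
  structure(
    list(electrodes = as.integer(electrodes),
         freq_band = as.numeric(freq_band),
         amplitude_by_class = as.numeric(amplitude_by_class),
         envelope = envelope, sign_schedule = sign_schedule, phase = phase),
    class = "effect_spec")
}

#' Synthetic recording configuration
#'
#' Defaults mirror the study design the generator emulates: 100 stimuli
#' (50 per class), four runs (each stimulus shown once per run), 1000 Hz
#' sampling, epochs -1000..3000 ms, and a 1/f background.
#'
#' @param n_channels number of electrodes.
#' @param n_stimuli_per_class stimuli per class (animate / inanimate).
#' @param n_runs repetitions of each stimulus (one per run).
#' @param fs sampling rate, Hz.
#' @param epoch_window length-2 ms pair, start < 0 < end; samples cover
#'   `[start, end)`.
#' @param noise_exponent spectral slope alpha of the 1/f^alpha background.
#' @param noise_scale background SD in arbitrary units.
#' @param effects list of [effect_spec()] objects.
#' @param seed integer; fully determines the output.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_channels = 16, n_stimuli_per_class = 50,
                         n_runs = 4, fs = 1000,
                         epoch_window = c(-1000, 3000),
                         noise_exponent = 1, noise_scale = 1,
                         effects = list(), seed = 1) {
  stopifnot(n_channels >= 1, n_stimuli_per_class >= 1, n_runs >= 1, fs > 0,
            length(epoch_window) == 2L,
            epoch_window[1] < 0, epoch_window[2] > 0,
            noise_exponent >= 0, noise_scale > 0)
  for (e in effects) {
    stopifnot(inherits(e, "effect_spec"))
    if (e$freq_band[2] >= fs / 2)
      stop(sprintf(
        "effect band %g-%g Hz reaches the Nyquist frequency (%g Hz)",
        e$freq_band[1], e$freq_band[2], fs / 2))
    if (any(e$electrodes < 1L | e$electrodes > n_channels))
      stop("effect electrodes outside 1..n_channels")
  }
  structure(
    list(n_channels = n_channels,
         n_stimuli_per_class = n_stimuli_per_class, n_runs = n_runs,
         fs = fs, epoch_window = as.numeric(epoch_window),
         noise_exponent = noise_exponent, noise_scale = noise_scale,
         effects = effects, seed = as.integer(seed)),
    class = "synth_config")
}

#' 1/f^alpha background noise
#'
#' White Gaussian noise spectrally shaped so that the periodogram slope in
#' log-log space is approximately `-exponent`; each channel independent.
#' Output is zero-mean with SD `scale`.
#'
#' @param n_channels,n_samples dimensions of the output matrix.
#' @param exponent spectral slope alpha (>= 0; 0 gives white noise).
#' @param seed integer RNG seed; the same seed reproduces the same array.
#' @param scale target SD per channel.
#' @return numeric matrix, channels x samples.
#' @export
make_background_noise <- function(n_channels, n_samples, exponent, seed,
                                  scale = 1) {
  if (n_samples < 2L) stop("n_samples must be at least 2")
  if (exponent < 0) stop("exponent must be non-negative")
  set.seed(seed)
  w <- matrix(stats::rnorm(n_channels * n_samples), n_channels, n_samples)
  if (exponent > 0) {
    k <- c(0, seq_len(n_samples - 1L))
    k <- pmin(k, n_samples - k)          # two-sided bin index
    g <- c(0, k[-1L]^(-exponent / 2))    # kill DC, shape the rest
    sh <- Re(stats::mvfft(stats::mvfft(t(w)) * g, inverse = TRUE))
    w <- t(sh) / n_samples
  }
  w <- w - rowMeans(w)
  sds <- apply(w, 1L, stats::sd)
  sds[sds == 0] <- 1
  w * (scale / sds)
}

sign_regime <- function(schedule, times) {
  s <- rep(1, length(times))
  if (is.null(schedule)) return(s)
  for (i in seq_len(nrow(schedule))) {
    in_iv <- times >= schedule$start[i] & times < schedule$end[i]
    s[in_iv] <- schedule$sign[i]
  }
  s
}

#' Generate a synthetic epoched recording with planted codes
#'
#' Produces 1/f background noise plus, for each [effect_spec()], a
#' band-limited sinusoid (carrier frequency drawn uniformly in the band per
#' trial and electrode, uniform random phase unless locked) whose amplitude
#' at time t is `envelope(t) * amplitude_by_class[class]`, with the class
#' assignment swapped wherever the sign schedule says so.
#'
#' @param config a [synth_config()].
#' @return list with elements `recording` (an [epoched_recording()]) and
#'   `truth` (a `ground_truth` record of labels, effect electrodes, envelope
#'   samples and sign schedules).
#' @export
generate_recording <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  fs <- config$fs
  times <- seq(config$epoch_window[1], config$epoch_window[2] - 1000 / fs,
               by = 1000 / fs)
  nsamp <- length(times)
  n_stim <- 2L * config$n_stimuli_per_class
  labels <- data.frame(
    stimulus_id = seq_len(n_stim),
    class = rep(c(0L, 1L), each = config$n_stimuli_per_class))
  trials <- do.call(rbind, lapply(seq_len(config$n_runs), function(r) {
    ord <- sample.int(n_stim)
    data.frame(stimulus_id = ord, class = labels$class[ord], run = r,
               good = TRUE)
  }))
  ntr <- nrow(trials)
  noise_seed <- (as.numeric(config$seed) * 2654435) %% 2147483647
  volt <- array(
    make_background_noise(config$n_channels * ntr, nsamp,
                          config$noise_exponent, seed = noise_seed,
                          scale = config$noise_scale),
    dim = c(config$n_channels, ntr, nsamp))
  volt <- aperm(volt, c(1L, 3L, 2L))
  set.seed(config$seed + 1L)
  t_sec <- times / 1000
  truth_effects <- vector("list", length(config$effects))
  for (k in seq_along(config$effects)) {
    eff <- config$effects[[k]]
    env <- eval_envelope(eff$envelope, times)
    reg <- sign_regime(eff$sign_schedule, times)
    amp <- eff$amplitude_by_class
    # amplitude timecourse per class, regime -1 swaps the two classes
    amp_c0 <- env * ifelse(reg > 0, amp[1], amp[2])
    amp_c1 <- env * ifelse(reg > 0, amp[2], amp[1])
    amp_mat <- cbind(amp_c0, amp_c1)          # nsamp x 2
    for (e in eff$electrodes) {
      f <- stats::runif(ntr, eff$freq_band[1], eff$freq_band[2])
      ph <- if (eff$phase == "locked") pi * trials$class else
        stats::runif(ntr, 0, 2 * pi)
      carrier <- sin(outer(t_sec, 2 * pi * f) +
                       matrix(ph, nsamp, ntr, byrow = TRUE))
      volt[e, , ] <- volt[e, , ] + carrier * amp_mat[, trials$class + 1L]
    }
    truth_effects[[k]] <- list(
      electrodes = eff$electrodes, freq_band = eff$freq_band,
      amplitude_by_class = amp, envelope = env,
      sign_schedule = eff$sign_schedule, phase = eff$phase)
  }
  rec <- epoched_recording(volt, times, fs, trials)
  truth <- structure(list(labels = labels, effects = truth_effects,
                          times = times),
                     class = "ground_truth")
  list(recording = rec, truth = truth)
}

#' Simulate a cohort of independent subjects
#'
#' Each subject gets the same configuration with a subject-specific seed
#' derived from `config$seed`, mirroring a group of patients recorded under
#' one protocol.
#'
#' @param config a [synth_config()].
#' @param n_subjects number of subjects.
#' @return list of `generate_recording()` results, one per subject.
#' @export
simulate_cohort <- function(config, n_subjects) {
  lapply(seq_len(n_subjects), function(s) {
    cfg <- config
    cfg$seed <- (as.numeric(config$seed) * 1009 + s * 7919) %% 2147483647
    generate_recording(cfg)
  })
}
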