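#' Baseline-correct an epoched recording
#'
#' For each channel, subtracts the mean voltage over the baseline window,
#' computed across window samples and all good trials, from every sample of
#' every trial (the canonical pre-stimulus baseline correction).
#'
#' @param rec an [epoched_recording()].
#' @param window length-2 ms pair inside the epoch; default -200..-1 ms.
#' @return the corrected recording.
#' @export
baseline_correct <- function(rec, window = c(-200, -1)) {
  stopifnot(inherits(rec, "epoched_recording"), length(window) == 2L)
  idx <- which(rec$times >= window[1] & rec$times <= window[2])
  if (length(idx) == 0L) stop("baseline window contains no samples")
  good <- which(rec$trials$good)
  if (length(good) == 0L) stop("no good trials to compute the baseline")
  base <- apply(rec$voltage[, idx, good, drop = FALSE], 1L, mean)
  rec$voltage <- rec$voltage - base   # recycles along the channel dimension
  rec
}

#' Common average reference
#'
#' Subtracts the across-channel mean at every (sample, trial), so the sum
#' over channels is zero everywhere. Idempotent.
#'
#' @param rec an [epoched_recording()].
#' @return the re-referenced recording.
#' @export
common_average_reference <- function(rec) {
  stopifnot(inherits(rec, "epoched_recording"))
  if (n_channels(rec) < 2L)
    stop("common average reference needs at least 2 channels")
  m <- colMeans(rec$voltage)            # samples x trials
  rec$voltage <- sweep(rec$voltage, c(2L, 3L), m)
  rec
}

#' Halve the sampling rate by boxcar averaging
#'
#' Output sample k is the mean of input samples 2k-1 and 2k; with an odd
#' number of samples the final sample is dropped first.
#'
#' @param rec an [epoched_recording()].
#' @return recording at half the sampling rate.
#' @export
boxcar_downsample <- function(rec) {
  stopifnot(inherits(rec, "epoched_recording"))
  ns <- n_samples(rec)
  keep <- ns - ns %% 2L
  v <- rec$voltage[, seq_len(keep), , drop = FALSE]
  odd <- seq(1L, keep, by = 2L)
  out <- (v[, odd, , drop = FALSE] + v[, odd + 1L, , drop = FALSE]) / 2
  rec$voltage <- out
  rec$times <- (rec$times[odd] + rec$times[odd + 1L]) / 2
  rec$fs <- rec$fs / 2
  rec
}

#' Flag trials with extreme values
#'
#' Per channel, the mean and SD are computed over timepoints and trials
#' pooled; any trial containing a sample outside mean +/- `k_sd` SD on any
#' channel has its `good` flag cleared. Nothing is deleted. Channels with
#' zero SD are skipped with a warning.
#'
#' @param rec an [epoched_recording()].
#' @param k_sd rejection threshold in SD units; default 10.
#' @return recording with updated `good` flags.
#' @export
reject_extreme_trials <- function(rec, k_sd = 10) {
  stopifnot(inherits(rec, "epoched_recording"), k_sd >= 0)
  if (n_trials(rec) < 2L) stop("need at least 2 trials")
  bad <- rep(FALSE, n_trials(rec))
  for (ch in seq_len(n_channels(rec))) {
    x <- rec$voltage[ch, , ]
    m <- mean(x); s <- stats::sd(as.vector(x))
    if (s == 0) {
      warning(sprintf("channel %d has zero SD; skipped", ch))
      next
    }
    extreme <- abs(x - m) > k_sd * s    # samples x trials
    bad <- bad | apply(extreme, 2L, any)
  }
  rec$trials$good <- rec$trials$good & !bad
  rec
}

#' Average repeated presentations of each stimulus
#'
#' Collapses the trial axis to one pseudo-trial per stimulus, averaging the
#' good trials for that stimulus. Stimuli with no good trials are kept in
#' place (all-zero waveform) and flagged `missing` so that downstream median
#' interpolation knows about them.
#'
#' @param rec an [epoched_recording()].
#' @return an `epoched_recording` with attribute `averaged = TRUE`, one
#'   pseudo-trial per stimulus in `stimulus_id` order; its trial table gains
#'   `n_good` and `missing` columns.
#' @export
average_repetitions <- function(rec) {
  stopifnot(inherits(rec, "epoched_recording"))
  map <- unique(rec$trials[, c("stimulus_id", "class")])
  map <- map[order(map$stimulus_id), , drop = FALSE]
  out <- array(0, dim = c(n_channels(rec), n_samples(rec), nrow(map)))
  n_good <- integer(nrow(map))
  for (i in seq_len(nrow(map))) {
    sel <- which(rec$trials$stimulus_id == map$stimulus_id[i] &
                   rec$trials$good)
    n_good[i] <- length(sel)
    if (length(sel) > 0L)
      out[, , i] <- rowMeans(rec$voltage[, , sel, drop = FALSE], dims = 2L)
  }
  trials <- data.frame(stimulus_id = map$stimulus_id, class = map$class,
                       run = NA_integer_, good = n_good > 0L,
                       n_good = n_good, missing = n_good == 0L)
  res <- epoched_recording(out, rec$times, rec$fs, trials, rec$channels)
  attr(res, "averaged") <- TRUE
  res
}
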