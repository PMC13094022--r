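#' Epoched multi-channel recording
#'
#' Container for one subject's epoched voltage data: a channels x samples x
#' trials array plus the trial and channel tables that index it. Trials carry
#' a `good` flag so that artifact rejection can mark trials without deleting
#' data (downstream interpolation needs to know which stimuli went missing).
#'
#' @param voltage numeric array, channels x samples x trials (arbitrary
#'   units).
#' @param times numeric vector of sample times in ms, strictly increasing and
#'   uniformly spaced at `1000 / fs`.
#' @param fs sampling rate in Hz.
#' @param trials data.frame with one row per trial: `stimulus_id` (integer),
#'   `class` (0 = animate, 1 = inanimate), `run` (integer), `good` (logical,
#'   optional; defaults to `TRUE`).
#' @param channels data.frame with one row per channel: `name` plus optional
#'   `x`, `y`, `z` coordinates. Defaults to generated names.
#'
#' @return An object of class `epoched_recording`.
#' @export
epoched_recording <- function(voltage, times, fs, trials, channels = NULL) {
  stopifnot(is.array(voltage), length(dim(voltage)) == 3L)
  d <- dim(voltage)
  if (length(times) != d[2L])
    stop("length(times) must equal the number of samples")
  dt <- diff(times)
  if (any(dt <= 0) || max(abs(dt - 1000 / fs)) > 1e-6)
    stop("times must increase uniformly at 1000/fs ms")
  trials <- as.data.frame(trials)
  if (nrow(trials) != d[3L])
    stop("trials table must have one row per trial")
  if (!all(c("stimulus_id", "class") %in% names(trials)))
    stop("trials table needs stimulus_id and class columns")
  if (!all(trials$class %in% c(0L, 1L)))
    stop("class must be coded 0 (animate) or 1 (inanimate)")
  map <- unique(trials[, c("stimulus_id", "class")])
  if (anyDuplicated(map$stimulus_id))
    stop("every stimulus_id must map to exactly one class")
  if (is.null(trials$good)) trials$good <- TRUE
  if (is.null(trials$run)) trials$run <- 1L
  if (is.null(channels))
    channels <- data.frame(name = sprintf("ch%02d", seq_len(d[1L])))
  channels <- as.data.frame(channels)
  if (nrow(channels) != d[1L])
    stop("channels table must have one row per channel")
  structure(
    list(voltage = voltage, times = as.numeric(times), fs = fs,
         trials = trials, channels = channels),
    class = "epoched_recording")
}

#' @export
print.epoched_recording <- function(x, ...) {
  d <- dim(x$voltage)
  cat(sprintf(
    "<epoched_recording> %d channels x %d samples x %d trials\n", d[1L],
    d[2L], d[3L]))
  cat(sprintf("  fs %g Hz, epoch %g..%g ms, %d good trials\n", x$fs,
              x$times[1L], x$times[length(x$times)], sum(x$trials$good)))
  if (isTRUE(attr(x, "averaged")))
    cat("  repetition-averaged (one pseudo-trial per stimulus)\n")
  invisible(x)
}

#' Recording dimensions
#'
#' @param rec an `epoched_recording`.
#' @return integer count of channels, samples or trials.
#' @export
n_channels <- function(rec) dim(rec$voltage)[1L]

#' @rdname n_channels
#' @export
n_samples  <- function(rec) dim(rec$voltage)[2L]

#' @rdname n_channels
#' @export
n_trials   <- function(rec) dim(rec$voltage)[3L]

#' Is a recording repetition-averaged?
#'
#' @param rec an `epoched_recording`.
#' @return `TRUE` if `rec` holds one pseudo-trial per stimulus.
#' @export
is_averaged <- function(rec) isTRUE(attr(rec, "averaged"))

sample_index <- function(rec, t_ms) {
  i <- round((t_ms - rec$times[1L]) * rec$fs / 1000) + 1L
  if (any(i < 1L | i > n_samples(rec)))
    stop("requested time outside the epoch")
  i
}
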