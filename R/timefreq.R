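#' Logarithmic frequency grid with interpolated wavelet cycles
#'
#' Frequencies are log-spaced inclusive of both ends:
#' `f[k] = f_min * (f_max/f_min)^(k/(n_steps-1))`. Wavelet cycle counts are
#' interpolated linearly in log-frequency between `cycles[1]` at `f_min` and
#' `cycles[2]` at `f_max` (the grid itself is log-spaced, so the cycle count
#' rises by a fixed amount per grid step). Defaults reproduce the 4-200 Hz,
#' 60-step grid with 5 cycles at 4 Hz rising to 15 at 200 Hz.
#'
#' @param f_min,f_max grid endpoints, Hz.
#' @param n_steps number of frequencies (>= 2).
#' @param cycles length-2 cycle counts at the two endpoints.
#' @return An object of class `frequency_grid` with elements `frequencies`
#'   and `cycles`.
#' @export
build_grid <- function(f_min = 4, f_max = 200, n_steps = 60,
                       cycles = c(5, 15)) {
  if (f_min <= 0) stop("f_min must be positive")
  if (f_max <= f_min) stop("f_max must exceed f_min")
  if (n_steps < 2) stop("n_steps must be at least 2")
  k <- seq(0, 1, length.out = n_steps)
  freqs <- f_min * (f_max / f_min)^k
  cyc <- cycles[1] + (cycles[2] - cycles[1]) * k
  structure(list(f_min = f_min, f_max = f_max, n_steps = n_steps,
                 frequencies = freqs, cycles = cyc),
            class = "frequency_grid")
}

default_band_edges <- function() {
  list(theta = c(4, 8), alpha = c(8, 13), beta = c(13, 30),
       gamma = c(30, 60), high_gamma = c(60, 200))
}

#' Partition a frequency grid into named bands
#'
#' Bands are half-open `[low, high)` except the last, which includes its
#' upper edge; on the default 60-step grid this uniquely reproduces the
#' canonical counts theta 11, alpha 7, beta 13, gamma 10, high gamma 19.
#' Every grid frequency must fall in exactly one band.
#'
#' @param grid a [build_grid()] result.
#' @param edges named list of length-2 Hz pairs in increasing order.
#' @return An object of class `band_partition` with `assignment` (factor per
#'   grid frequency) and `counts`.
#' @export
partition_bands <- function(grid, edges = default_band_edges()) {
  stopifnot(inherits(grid, "frequency_grid"), length(edges) >= 1)
  nm <- names(edges)
  lows <- vapply(edges, `[`, numeric(1), 1L)
  highs <- vapply(edges, `[`, numeric(1), 2L)
  if (is.unsorted(lows)) stop("band edges must be ordered")
  assign_one <- function(f) {
    hit <- which(f >= lows & (f < highs |
                                (seq_along(edges) == length(edges) &
                                   f <= highs)))
    if (length(hit) != 1L)
      stop(sprintf("grid frequency %.4g Hz not assigned to exactly one band",
                   f))
    nm[hit]
  }
  a <- vapply(grid$frequencies, assign_one, character(1))
  assignment <- factor(a, levels = nm)
  structure(list(edges = edges, assignment = assignment,
                 counts = table(assignment)),
            class = "band_partition")
}

#' Frequency indices of a band
#'
#' @param partition a [partition_bands()] result.
#' @param band a band name or `"all"`.
#' @return integer indices into the grid frequencies.
#' @export
band_indices <- function(partition, band) {
  if (identical(band, "all")) return(seq_along(partition$assignment))
  if (!band %in% levels(partition$assignment))
    stop("unknown band name: ", band)
  which(partition$assignment == band)
}

morlet_kernel <- function(f, cycles, fs) {
  sigma_t <- cycles / (2 * pi * f)
  h <- ceiling(3.5 * sigma_t * fs)
  t <- (-h:h) / fs
  w <- exp(2i * pi * f * t) * exp(-t^2 / (2 * sigma_t^2))
  w / sqrt(sum(Mod(w)^2))   # unit total energy
}

#' Complex Morlet wavelet transform of an epoched recording
#'
#' Convolves every channel and trial with complex Morlet wavelets (cycle
#' counts from the grid) by FFT, and samples the coefficients at the
#' requested output times. Output times whose wavelet support extends past
#' the epoch are flagged in `edge_flags` (frequencies x times).
#'
#' @param rec an [epoched_recording()].
#' @param grid a [build_grid()] result with `f_max < fs/2`.
#' @param times_out output time grid in ms (within the epoch); default
#'   0..1650 ms in 10 ms steps.
#' @return An object of class `tf_coefficients`: complex array channels x
#'   frequencies x times x trials plus bookkeeping.
#' @export
morlet_transform <- function(rec, grid,
                             times_out = seq(0, 1650, by = 10)) {
  stopifnot(inherits(rec, "epoched_recording"),
            inherits(grid, "frequency_grid"))
  if (grid$f_max >= rec$fs / 2)
    stop("grid f_max must be below the Nyquist frequency")
  out_idx <- sample_index(rec, times_out)
  ns <- n_samples(rec); ntr <- n_trials(rec); nch <- n_channels(rec)
  nf <- grid$n_steps
  kernels <- lapply(seq_len(nf), function(i) {
    k <- morlet_kernel(grid$frequencies[i], grid$cycles[i], rec$fs)
    if (length(k) > ns)
      stop(sprintf("wavelet at %.3g Hz (%d samples) is longer than the epoch",
                   grid$frequencies[i], length(k)))
    k
  })
  half <- vapply(kernels, function(k) (length(k) - 1L) %/% 2L, integer(1))
  nfft <- stats::nextn(ns + 2L * max(half), factors = 2L)
  # kernel spectra, centre of kernel aligned to lag zero (circular layout)
  kspec <- vapply(seq_len(nf), function(i) {
    k <- kernels[[i]]; h <- half[i]
    padded <- complex(length.out = nfft)
    padded[seq_len(h + 1L)] <- k[(h + 1L):length(k)]
    padded[(nfft - h + 1L):nfft] <- k[seq_len(h)]
    stats::fft(padded)
  }, complex(nfft))
  coef <- array(complex(1), dim = c(nch, nf, length(out_idx), ntr))
  for (ch in seq_len(nch)) {
    x <- matrix(0, nfft, ntr)
    x[seq_len(ns), ] <- rec$voltage[ch, , ]
    xf <- stats::mvfft(x)
    for (i in seq_len(nf)) {
      conv <- stats::mvfft(xf * kspec[, i], inverse = TRUE) / nfft
      coef[ch, i, , ] <- conv[out_idx, ]
    }
  }
  edge_flags <- vapply(seq_len(nf), function(i) {
    out_idx - half[i] < 1L | out_idx + half[i] > ns
  }, logical(length(out_idx)))
  edge_flags <- matrix(edge_flags, nrow = length(out_idx))
  structure(
    list(coef = coef, times = as.numeric(times_out), grid = grid,
         trials = rec$trials, channels = rec$channels,
         averaged = is_averaged(rec),
         edge_flags = t(edge_flags)),   # frequencies x times
    class = "tf_coefficients")
}

new_tf_tensor <- function(values, times, kind, grid, stimuli, missing_ids,
                          channels) {
  structure(list(values = values, times = times, kind = kind, grid = grid,
                 stimuli = stimuli, missing = missing_ids,
                 channels = channels),
            class = "tf_tensor")
}

#' @export
print.tf_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<tf_tensor:%s> %d electrodes x %d freqs x %d times x %d stimuli\n",
              x$kind, d[1], d[2], d[3], d[4]))
  if (length(x$missing)) cat("  missing stimuli:",
                             paste(x$missing, collapse = ", "), "\n")
  invisible(x)
}

#' Decibel-normalized power per stimulus
#'
#' Raw power is `|coefficient|^2`. The baseline `B(e, f)` is the mean raw
#' power over the baseline samples and all good trials (raw, not
#' repetition-averaged). Power is averaged over repeated presentations of
#' each stimulus first, then normalized as `10 * log10(P / B)`. Stimuli with
#' no good trials come out as `NA` and are listed in `missing` for
#' [interpolate_missing()].
#'
#' @param coeffs a [morlet_transform()] result whose time grid contains the
#'   baseline window.
#' @param baseline_window length-2 ms pair; default -300..-100 ms (the gap
#'   before onset absorbs temporal leakage of trial activity into the
#'   baseline during convolution).
#' @return a `tf_tensor` of kind `"power"` (dB), electrodes x frequencies x
#'   times x stimuli.
#' @export
power_db <- function(coeffs, baseline_window = c(-300, -100)) {
  stopifnot(inherits(coeffs, "tf_coefficients"))
  bidx <- which(coeffs$times >= baseline_window[1] &
                  coeffs$times <= baseline_window[2])
  if (length(bidx) == 0L)
    stop("baseline window not covered by the transformed times")
  p <- Mod(coeffs$coef)^2
  good <- which(coeffs$trials$good)
  if (length(good) == 0L) stop("no good trials")
  b <- apply(p[, , bidx, good, drop = FALSE], c(1L, 2L), mean)
  if (any(b == 0)) stop("zero baseline power: degenerate input")
  map <- unique(coeffs$trials[, c("stimulus_id", "class")])
  map <- map[order(map$stimulus_id), , drop = FALSE]
  d <- dim(p)
  avg <- array(NA_real_, dim = c(d[1L], d[2L], d[3L], nrow(map)))
  missing_ids <- integer(0)
  for (i in seq_len(nrow(map))) {
    sel <- which(coeffs$trials$stimulus_id == map$stimulus_id[i] &
                   coeffs$trials$good)
    if (length(sel) == 0L) {
      missing_ids <- c(missing_ids, map$stimulus_id[i])
    } else {
      avg[, , , i] <- rowMeans(p[, , , sel, drop = FALSE], dims = 3L)
    }
  }
  db <- 10 * log10(sweep(avg, c(1L, 2L), b, `/`))
  new_tf_tensor(db, coeffs$times, "power", coeffs$grid, map, missing_ids,
                coeffs$channels)
}

#' Interpolate missing stimuli with the median across stimuli
#'
#' Each missing stimulus's cell (electrode, frequency, time) is replaced by
#' the median over non-missing stimuli at that cell.
#'
#' @param tensor a `tf_tensor` (power).
#' @return the tensor with no missing stimuli.
#' @export
interpolate_missing <- function(tensor) {
  stopifnot(inherits(tensor, "tf_tensor"))
  if (length(tensor$missing) == 0L) return(tensor)
  present <- which(!tensor$stimuli$stimulus_id %in% tensor$missing)
  if (length(present) == 0L) stop("all stimuli missing; cannot interpolate")
  med <- apply(tensor$values[, , , present, drop = FALSE], c(1L, 2L, 3L),
               stats::median)
  for (id in tensor$missing) {
    i <- which(tensor$stimuli$stimulus_id == id)
    tensor$values[, , , i] <- med
  }
  tensor$missing <- integer(0)
  tensor
}

#' Phase per stimulus from a repetition-averaged recording
#'
#' Phase values cannot be averaged across repetitions, so trials must be
#' repetition-averaged before the transform; this function enforces that.
#' Phase is the argument of the complex coefficient, in (-pi, pi]. Cells
#' with zero-magnitude coefficients (undefined phase) become `NA`.
#'
#' @param rec a repetition-averaged [epoched_recording()] (see
#'   [average_repetitions()]).
#' @param grid a [build_grid()] result.
#' @param times_out output time grid, ms.
#' @return a `tf_tensor` of kind `"phase"`.
#' @export
extract_phase <- function(rec, grid, times_out = seq(0, 1650, by = 10)) {
  if (!is_averaged(rec))
    stop("extract_phase requires a repetition-averaged recording")
  coeffs <- morlet_transform(rec, grid, times_out)
  ph <- Arg(coeffs$coef)
  ph[Mod(coeffs$coef) == 0] <- NA_real_
  ph[ph <= -pi] <- pi   # map -pi to pi so the range is (-pi, pi]
  map <- coeffs$trials[, c("stimulus_id", "class")]
  missing_ids <- if (!is.null(coeffs$trials$missing))
    coeffs$trials$stimulus_id[coeffs$trials$missing] else integer(0)
  new_tf_tensor(ph, coeffs$times, "phase", grid, map, missing_ids,
                coeffs$channels)
}

#' Power pipeline convenience wrapper
#'
#' Runs [morlet_transform()] on a time grid extended to cover the baseline
#' window, applies [power_db()] and [interpolate_missing()], and returns the
#' tensor restricted to `times_out`.
#'
#' @inheritParams morlet_transform
#' @inheritParams power_db
#' @return a `tf_tensor` of kind `"power"` on `times_out`.
#' @export
extract_power <- function(rec, grid, times_out = seq(0, 1650, by = 10),
                          baseline_window = c(-300, -100)) {
  step <- if (length(times_out) > 1L) diff(times_out[1:2]) else 10
  base_times <- seq(baseline_window[1], baseline_window[2], by = step)
  all_times <- sort(unique(c(base_times, times_out)))
  coeffs <- morlet_transform(rec, grid, all_times)
  tens <- interpolate_missing(power_db(coeffs, baseline_window))
  keep <- match(times_out, tens$times)
  tens$values <- tens$values[, , keep, , drop = FALSE]
  tens$times <- times_out
  tens
}
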