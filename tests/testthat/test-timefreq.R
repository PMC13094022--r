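test_that("the default grid reproduces the canonical frequencies and cycles", {
  g <- build_grid(4, 200, 60)
  expect_equal(g$frequencies[1], 4)
  expect_equal(g$frequencies[60], 200)
  # closed form for the second step: 4 * 50^(1/59)
  expect_equal(g$frequencies[2], 4 * 50^(1 / 59), tolerance = 1e-12)
  expect_true(all(diff(g$frequencies) > 0))
  expect_equal(g$cycles[1], 5)
  expect_equal(g$cycles[60], 15)
  expect_error(build_grid(4, 4, 2), "exceed")
  expect_error(build_grid(0, 200, 60), "positive")
})

test_that("the band partition reproduces the printed counts and covers the grid", {
  g <- build_grid(4, 200, 60)
  p <- partition_bands(g)
  expect_equal(unname(c(p$counts)), c(11, 7, 13, 10, 19))
  expect_equal(sum(p$counts), 60)
  expect_equal(levels(p$assignment),
               c("theta", "alpha", "beta", "gamma", "high_gamma"))
  # half-open edges: 30 Hz would belong to gamma, not beta
  g2 <- build_grid(15, 60, 4)   # contains 30 Hz exactly? 15*4^(k/3): 15,23.8,37.8,60
  expect_error(partition_bands(g, edges = list(low = c(4, 50))),
               "not assigned")
  expect_error(band_indices(p, "delta"), "unknown band")
  expect_length(band_indices(p, "all"), 60)
})

test_that("Morlet power peaks at the stimulus frequency and falls off sharply", {
  fs <- 1000
  times <- seq(-1000, 1999, 1)
  sig <- cos(2 * pi * 32 * times / 1000)
  volt <- array(rep(sig, 2), dim = c(1, length(times), 2))
  rec <- epoched_recording(volt, times, fs,
                           data.frame(stimulus_id = 1:2, class = c(0L, 1L),
                                      run = 1, good = TRUE))
  g <- build_grid()
  co <- morlet_transform(rec, g, times_out = seq(0, 1000, 100))
  pw <- rowMeans(Mod(co$coef[1, , , 1])^2)
  nearest <- which.min(abs(g$frequencies - 32))
  expect_equal(which.max(pw), nearest)
  expect_gt(10 * log10(pw[nearest] / pw[1]), 20)
  expect_gt(10 * log10(pw[nearest] / pw[60]), 20)
  # phase ~ 0 at a cosine peak (t = 0)
  expect_equal(Arg(co$coef[1, nearest, 1, 1]), 0, tolerance = 1e-6)
  # zero signal -> zero power
  rec0 <- rec; rec0$voltage[] <- 0
  co0 <- morlet_transform(rec0, g, times_out = c(0, 500))
  expect_true(all(Mod(co0$coef) == 0))
})

test_that("transform guards reject unusable grids", {
  rec <- flat_recording(n_channels = 1, n_samples = 100, n_trials = 2,
                        fs = 100)
  g <- build_grid(4, 60, 5)
  expect_error(morlet_transform(rec, g, times_out = c(0, 100)), "Nyquist")
  g2 <- build_grid(0.5, 40, 5)
  expect_error(morlet_transform(rec, g2, times_out = c(0, 100)),
               "longer than the epoch")
})

test_that("dB normalization is 10*log10 relative to the baseline power", {
  # white-noise-like stationarity: identical baseline and trial statistics
  # give ~0 dB; doubling power gives +3.01 dB
  fs <- 500
  times <- seq(-500, 499, by = 2)
  set.seed(8)
  n_tr <- 6
  volt <- array(rnorm(1 * length(times) * n_tr),
                dim = c(1, length(times), n_tr))
  rec <- epoched_recording(volt, times, fs,
                           data.frame(stimulus_id = rep(1:3, 2),
                                      class = rep(c(0L, 1L, 0L), 2),
                                      run = rep(1:2, each = 3),
                                      good = TRUE))
  g <- build_grid(8, 100, 6)
  co <- morlet_transform(rec, g, times_out = seq(-400, 400, 50))
  tens <- power_db(co, baseline_window = c(-400, -100))
  expect_equal(tens$kind, "power")
  expect_lt(abs(mean(tens$values)), 1)
  # doubling the voltage quadruples power: +10*log10(4) dB exactly
  co2 <- co
  sel <- co2$times >= 0
  co2$coef[, , sel, ] <- co2$coef[, , sel, ] * sqrt(2)
  tens2 <- power_db(co2, baseline_window = c(-400, -100))
  diffs <- tens2$values[, , sel, , drop = FALSE] -
    tens$values[, , sel, , drop = FALSE]
  expect_equal(max(abs(diffs - 10 * log10(2))), 0, tolerance = 1e-9)
})

test_that("power is averaged over repetitions before normalization", {
  fs <- 500
  times <- seq(-500, 499, by = 2)
  volt <- array(1, dim = c(1, length(times), 4))
  rec <- epoched_recording(volt, times, fs,
                           data.frame(stimulus_id = c(1L, 1L, 2L, 2L),
                                      class = c(0L, 0L, 1L, 1L),
                                      run = c(1, 2, 1, 2), good = TRUE))
  set.seed(2)
  rec$voltage[] <- rnorm(length(rec$voltage))
  g <- build_grid(8, 100, 4)
  co <- morlet_transform(rec, g, times_out = seq(-400, 400, 100))
  tens <- power_db(co, c(-400, -100))
  expect_equal(dim(tens$values)[4], 2)   # stimuli, not trials
  # manual check of one cell
  p <- Mod(co$coef)^2
  b <- mean(p[1, 2, co$times <= -100, ])
  manual <- 10 * log10(mean(p[1, 2, 5, rec$trials$stimulus_id == 1]) / b)
  expect_equal(tens$values[1, 2, 5, 1], manual, tolerance = 1e-12)
})

test_that("median interpolation fills missing stimuli robustly", {
  vals <- array(0, dim = c(1, 1, 1, 4))
  vals[1, 1, 1, ] <- c(1, 2, 100, 0)   # stimulus 4 missing
  tens <- structure(
    list(values = vals, times = 0, kind = "power",
         grid = build_grid(4, 8, 2),
         stimuli = data.frame(stimulus_id = 1:4,
                              class = c(0L, 0L, 1L, 1L)),
         missing = 4L, channels = data.frame(name = "e1")),
    class = "tf_tensor")
  out <- interpolate_missing(tens)
  expect_equal(out$values[1, 1, 1, 4], 2)   # median of 1, 2, 100
  expect_length(out$missing, 0)
  # no missing stimuli -> unchanged
  tens2 <- tens; tens2$missing <- integer(0)
  expect_identical(interpolate_missing(tens2)$values, tens2$values)
  # single non-missing stimulus -> copied
  tens3 <- tens; tens3$missing <- c(2L, 3L, 4L)
  out3 <- interpolate_missing(tens3)
  expect_true(all(out3$values[1, 1, 1, 2:4] == 1))
  tens4 <- tens; tens4$missing <- 1:4
  expect_error(interpolate_missing(tens4), "all stimuli missing")
})

test_that("phase extraction demands repetition-averaged input and stays in (-pi, pi]", {
  cfg <- synth_config(n_channels = 2, n_stimuli_per_class = 3, n_runs = 2,
                      fs = 500, epoch_window = c(-600, 1000), seed = 4)
  rec <- generate_recording(cfg)$recording
  expect_error(extract_phase(rec, build_grid(8, 100, 4), c(0, 100)),
               "repetition-averaged")
  avg <- average_repetitions(rec)
  ph <- extract_phase(avg, build_grid(8, 100, 4), seq(0, 500, 100))
  expect_equal(ph$kind, "phase")
  expect_true(all(ph$values > -pi & ph$values <= pi, na.rm = TRUE))
})

test_that("antiphase signals differ by pi", {
  fs <- 500
  times <- seq(-500, 499, by = 2)
  f0 <- 20
  base <- cos(2 * pi * f0 * times / 1000)
  volt <- array(c(base, -base), dim = c(1, length(times), 2))
  rec <- epoched_recording(volt, times, fs,
                           data.frame(stimulus_id = 1:2, class = 0:1,
                                      run = 1, good = TRUE,
                                      missing = FALSE))
  attr(rec, "averaged") <- TRUE
  g <- build_grid(8, 100, 8)
  ph <- extract_phase(rec, g, times_out = c(0, 100))
  near <- which.min(abs(g$frequencies - f0))
  d <- abs(ph$values[1, near, 1, 1] - ph$values[1, near, 1, 2])
  expect_equal(min(d, 2 * pi - d), pi, tolerance = 1e-6)
})

test_that("white-noise power is flat in dB after self-normalization", {
  # 4 repetitions per stimulus keep the chi-square log bias of the dB
  # estimate near -0.6 dB; the mean normalized spectrum should be flat at
  # roughly that level with no frequency trend
  set.seed(6)
  fs <- 500
  times <- seq(-1000, 1999, by = 2)
  n_tr <- 32
  volt <- array(rnorm(2 * length(times) * n_tr),
                dim = c(2, length(times), n_tr))
  rec <- epoched_recording(volt, times, fs,
                           data.frame(stimulus_id = rep(1:8, 4),
                                      class = rep(rep(c(0L, 1L), each = 4),
                                                  4),
                                      run = rep(1:4, each = 8),
                                      good = TRUE))
  g <- build_grid(4, 100, 10)
  tens <- extract_power(rec, g, times_out = seq(0, 1500, 100),
                        baseline_window = c(-300, -100))
  expect_lt(abs(mean(tens$values)), 1)
  per_freq <- apply(tens$values, 2, mean)
  expect_lt(max(abs(per_freq)), 2)
})

test_that("wavelet power grows with signal variance", {
  fs <- 500
  times <- seq(-500, 499, by = 2)
  set.seed(10)
  base <- rnorm(length(times))
  tot <- sapply(c(1, 2, 4), function(s) {
    volt <- array(base * s, dim = c(1, length(times), 1))
    rec <- epoched_recording(volt, times, fs,
                             data.frame(stimulus_id = 1L, class = 0L,
                                        run = 1, good = TRUE))
    co <- morlet_transform(rec, build_grid(8, 100, 6),
                           times_out = seq(-200, 400, 100))
    sum(Mod(co$coef)^2)
  })
  expect_true(all(diff(tot) > 0))
})
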