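# Independent oracles used to validate the implementation. These never call
# the package's fitting code paths.

# Proximal-gradient (FISTA) solver for the standardized LASSO-logistic
# objective: mean logistic deviance + lambda * sum |beta|, intercept
# unpenalized, features standardized with population (1/n) SDs and
# coefficients mapped back to the original scale.
fista_lasso_logistic <- function(X, y, lambda, iters = 200000, tol = 1e-15,
                                 init = NULL) {
  n <- nrow(X)
  m <- colMeans(X)
  s <- sqrt(colMeans(scale(X, center = m, scale = FALSE)^2))
  s[s == 0] <- 1
  Xs <- scale(X, center = m, scale = s)
  A <- cbind(1, Xs)
  L <- max(eigen(crossprod(A) / n, symmetric = TRUE,
                 only.values = TRUE)$values) / 4
  b <- if (is.null(init)) rep(0, ncol(A)) else init
  z <- b; tk <- 1
  obj <- function(b) {
    eta <- drop(A %*% b)
    mean(log(1 + exp(eta)) - y * eta) + lambda * sum(abs(b[-1]))
  }
  last <- Inf
  for (it in seq_len(iters)) {
    eta <- drop(A %*% z)
    gr <- drop(crossprod(A, stats::plogis(eta) - y)) / n
    bn <- z - gr / L
    bn[-1] <- sign(bn[-1]) * pmax(abs(bn[-1]) - lambda / L, 0)
    tn <- (1 + sqrt(1 + 4 * tk^2)) / 2
    z <- bn + ((tk - 1) / tn) * (bn - b)
    b <- bn; tk <- tn
    if (it %% 2000 == 0) {
      o <- obj(b)
      if (abs(last - o) < tol * max(1, abs(o))) break
      last <- o
    }
  }
  beta <- b[-1] / s
  list(intercept = b[1] - sum(beta * m), beta = beta, state = b)
}

# Literal Benjamini-Hochberg step-up: adjusted p = min over j >= rank(i) of
# m * p_(j) / j, capped at 1.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- rev(cummin(rev(m * p[o] / seq_len(m))))
  adj <- numeric(m)
  adj[o] <- pmin(adj_sorted, 1)
  adj
}

# Small flat recording with controllable values, for preprocessing tests.
flat_recording <- function(n_channels = 2, n_samples = 10, n_trials = 4,
                           fs = 1000, value = 0) {
  times <- seq(-n_samples / 2, n_samples / 2 - 1) * 1000 / fs
  n_stim <- max(1L, n_trials %/% 2L)
  trials <- data.frame(
    stimulus_id = rep_len(seq_len(n_stim), n_trials),
    class = rep_len(c(0L, 1L), n_trials),
    run = rep(seq_len(max(1L, n_trials %/% n_stim)), each = n_stim,
              length.out = n_trials),
    good = TRUE)
  # class must be a function of stimulus_id
  trials$class <- trials$stimulus_id %% 2L
  epoched_recording(array(value, dim = c(n_channels, n_samples, n_trials)),
                    times, fs, trials)
}

# Shared small scenario: planted gamma-band effect on known electrodes.
planted_gamma_config <- function(seed, amplitude = c(3, 1),
                                 electrodes = 1:5, band = c(32, 48),
                                 n_channels = 16, n_per_class = 20,
                                 window = c(200, 1400)) {
  synth_config(
    n_channels = n_channels, n_stimuli_per_class = n_per_class, n_runs = 4,
    epoch_window = c(-500, 2000),
    effects = list(effect_spec(electrodes, band, amplitude,
                               envelope_boxcar(window))),
    seed = seed)
}

preprocess_default <- function(rec) {
  common_average_reference(baseline_correct(rec))
}

quiet_glmnet <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("fewer than 8|dangerous", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}
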