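test_that("the lambda grid is log-spaced, descending, 0.2 to 0.002", {
  g <- lambda_grid()
  expect_length(g, 100)
  expect_equal(g[1], 0.2)
  expect_equal(g[100], 0.002)
  expect_true(all(diff(g) < 0))
  # log-spacing: constant ratio between neighbours
  r <- g[-1] / g[-100]
  expect_equal(max(r) - min(r), 0, tolerance = 1e-12)
  expect_equal(lambda_grid(1, hi = 0.1), 0.1)
})

make_power_tensor <- function(n_elec = 10, n_stim = 12, seed = 1) {
  g <- build_grid(4, 200, 60)
  set.seed(seed)
  vals <- array(rnorm(n_elec * 60 * 3 * n_stim),
                dim = c(n_elec, 60, 3, n_stim))
  structure(
    list(values = vals, times = c(0, 100, 200), kind = "power", grid = g,
         stimuli = data.frame(stimulus_id = seq_len(n_stim),
                              class = rep(c(0L, 1L), n_stim / 2)),
         missing = integer(0),
         channels = data.frame(name = sprintf("e%02d", seq_len(n_elec)))),
    class = "tf_tensor")
}

test_that("feature matrices have the documented column counts", {
  tens <- make_power_tensor()
  part <- partition_bands(tens$grid)
  all_f <- build_features(tens, 100, band = "all")
  expect_equal(ncol(all_f$X), 600)            # 10 electrodes x 60 freqs
  theta <- build_features(tens, 100, band = "theta", partition = part)
  expect_equal(ncol(theta$X), 110)            # 10 x 11 theta frequencies
  expect_error(build_features(tens, 100, band = "delta", partition = part),
               "unknown band")
  expect_error(build_features(tens, 55, band = "all"), "time grid")
  # voltage: 51 samples inclusive at 1000 Hz for a 50 ms window
  cfg <- synth_config(n_channels = 10, n_stimuli_per_class = 3, n_runs = 2,
                      fs = 1000, epoch_window = c(-200, 600), seed = 9)
  avg <- average_repetitions(generate_recording(cfg)$recording)
  vf <- build_features(avg, 200)
  expect_equal(ncol(vf$X), 510)
  expect_equal(sum(vf$feature_index$offset_ms == 0), 10)
})

test_that("feature columns map back to the right tensor cells", {
  tens <- make_power_tensor(n_elec = 3, n_stim = 4)
  fm <- build_features(tens, 200, band = "all")
  fi <- fm$feature_index
  for (col in c(1, 61, 180)) {
    e <- fi$electrode_idx[col]
    f <- which(tens$grid$frequencies == fi$frequency[col])
    expect_equal(fm$X[, col], tens$values[e, f, 3, ])
  }
})

test_that("above the critical penalty the model is the balanced null model", {
  set.seed(2)
  X <- matrix(rnorm(40 * 6), 40, 6)
  y <- rep(c(0L, 1L), 20)
  m <- fit_lasso_logistic(X, y, 5)
  expect_true(all(m$coefficients == 0))
  expect_equal(m$intercept, 0, tolerance = 1e-8)   # logit of 0.5
  # predicted class 1 for all (prob ties at 0.5), accuracy 0.5 on balance
  pr <- predict_classes(m, X)
  expect_equal(mean(pr$class == y), 0.5)
})

test_that("tiny penalties fit separable toy data perfectly", {
  X <- cbind(c(-2, -1.5, -1, 1, 1.5, 2, -1.2, 1.2),
             c(0.1, -0.2, 0.3, 0.2, -0.1, 0.3, 0, 0))
  y <- c(0L, 0L, 0L, 1L, 1L, 1L, 0L, 1L)
  m <- quiet_glmnet(fit_lasso_logistic(X, y, 1e-4))
  pr <- predict_classes(m, X)
  expect_equal(pr$class, y)
  expect_error(fit_lasso_logistic(X, rep(0L, 8), 0.1), "both classes")
})

test_that("coefficients match the proximal-gradient oracle across the grid", {
  set.seed(42)
  n <- 30; p <- 8
  X <- matrix(rnorm(n * p), n, p)
  X[, 1] <- X[, 1] + rep(c(-0.8, 0.8), 15)
  y <- rep(c(0L, 1L), 15)
  for (lam in lambda_grid()[c(1, 20, 45, 70, 100)]) {
    m <- fit_lasso_logistic(X, y, lam)
    o <- fista_lasso_logistic(X, y, lam)
    expect_lt(max(abs(m$coefficients - o$beta)), 1e-4)
    expect_lt(abs(m$intercept - o$intercept), 1e-4)
  }
  # fixed small instance at lambda = 0.05 (6 stimuli, 2 features)
  set.seed(7)
  X6 <- matrix(rnorm(12), 6, 2); y6 <- c(0L, 1L, 0L, 1L, 1L, 0L)
  m6 <- quiet_glmnet(fit_lasso_logistic(X6, y6, 0.05))
  o6 <- fista_lasso_logistic(X6, y6, 0.05)
  expect_lt(max(abs(m6$coefficients - o6$beta)), 1e-4)
})

test_that("stratified folds balance classes and are seed-determined", {
  y <- rep(c(0L, 1L), each = 50)
  f <- make_stratified_folds(y, 10, seed = 3)
  for (k in 1:10) {
    expect_equal(sum(f == k & y == 0), 5)
    expect_equal(sum(f == k & y == 1), 5)
  }
  expect_identical(f, make_stratified_folds(y, 10, seed = 3))
  expect_false(identical(f, make_stratified_folds(y, 10, seed = 4)))
})

test_that("lambda selection prefers sparse models on noise and finds real signal", {
  set.seed(5)
  n <- 60
  y <- rep(c(0L, 1L), n / 2)
  noise <- matrix(rnorm(n * 20), n, 20)
  sel <- select_lambda(noise, y, inner_folds = 5, seed = 1)
  expect_gte(sel$lambda, stats::median(lambda_grid()))
  # one perfectly predictive feature gets a nonzero coefficient
  X <- cbind(ifelse(y == 1, 1, -1) + rnorm(n, 0, 0.1),
             matrix(rnorm(n * 5), n, 5))
  sel2 <- select_lambda(X, y, inner_folds = 5, seed = 1)
  m <- fit_lasso_logistic(X, y, sel2$lambda)
  expect_true(m$coefficients[1] != 0)
  # grid of length 1 returns that lambda
  expect_equal(select_lambda(X, y, grid = 0.07, inner_folds = 5,
                             seed = 1)$lambda, 0.07)
})

noise_series <- function(n_stim, n_feat, n_times, seed) {
  set.seed(seed)
  y <- rep(c(0L, 1L), n_stim / 2)
  mats <- lapply(seq_len(n_times), function(i)
    structure(list(X = matrix(rnorm(n_stim * n_feat), n_stim, n_feat),
                   y = y,
                   feature_index = data.frame(column = seq_len(n_feat),
                                              electrode = "e1",
                                              electrode_idx = 1L,
                                              frequency = seq_len(n_feat)),
                   timepoint = i * 100, band = "all"),
              class = "feature_matrix"))
  structure(list(matrices = mats, times = seq_len(n_times) * 100, y = y,
                 feature_index = mats[[1]]$feature_index, band = "all"),
            class = "feature_series")
}

test_that("outer CV holds out balanced stimuli and fills a consistent matrix", {
  ser <- noise_series(20, 5, 3, seed = 11)
  res <- quiet_glmnet(outer_cv_decode(ser, folds = 5, seed = 2,
                                      inner_folds = 4))
  for (k in 1:5) {
    expect_equal(sum(res$fold == k), 4)
    expect_equal(sum(res$fold == k & ser$y == 0), 2)
  }
  expect_equal(dim(res$accuracy), c(3, 3, 5))
  expect_true(all(res$accuracy >= 0 & res$accuracy <= 1))
  # diagonal equals the separately reported timecourse
  diag_mean <- sapply(1:3, function(i) mean(res$accuracy[i, i, ]))
  expect_equal(res$timecourse, diag_mean)
  # determinism under a fixed seed
  res2 <- quiet_glmnet(outer_cv_decode(ser, folds = 5, seed = 2,
                                       inner_folds = 4))
  expect_identical(res$accuracy, res2$accuracy)
  expect_identical(res$lambda, res2$lambda)
  expect_error(outer_cv_decode(noise_series(6, 3, 2, 1), folds = 5),
               "stratified")
})

test_that("the default outer CV partition is 10 folds of 5 + 5 over 100 stimuli", {
  y <- rep(c(0L, 1L), each = 50)
  fold <- make_stratified_folds(y, 10, seed = 1)
  held <- table(fold)
  expect_true(all(held == 10))
  for (k in 1:10) {
    expect_equal(sum(fold == k & y == 0), 5)
    expect_equal(sum(fold == k & y == 1), 5)
  }
})

test_that("at the sparsest grid penalty nearly all noise coefficients are zero", {
  set.seed(21)
  X <- matrix(rnorm(50 * 40), 50, 40)
  y <- rep(c(0L, 1L), 25)
  m <- fit_lasso_logistic(X, y, lambda_grid()[1])
  expect_gte(mean(m$coefficients == 0), 0.9)
  # zero-variance feature never selected
  X2 <- cbind(X, 1)
  m2 <- fit_lasso_logistic(X2, y, 0.01)
  expect_equal(m2$coefficients[41], 0)
})

test_that("full-data models exist at every timepoint and are never scored", {
  ser <- noise_series(20, 4, 3, seed = 13)
  mods <- quiet_glmnet(fit_full_models(ser, inner_folds = 4, seed = 1))
  expect_length(mods, 3)
  expect_equal(vapply(mods, function(m) m$timepoint, numeric(1)),
               c(100, 200, 300))
  expect_s3_class(mods[[1]], "classifier_model")
  expect_identical(attr(mods, "feature_index"), ser$feature_index)
})

test_that("label shuffling drives decoding to chance", {
  # planted signal decodes well; shuffling the labels destroys it
  set.seed(31)
  n <- 40
  y <- rep(c(0L, 1L), n / 2)
  X <- cbind(ifelse(y == 1, 1.5, -1.5) + rnorm(n, 0, 0.5),
             matrix(rnorm(n * 6), n, 6))
  make_ser <- function(lab) {
    structure(list(
      matrices = list(structure(list(
        X = X, y = lab,
        feature_index = data.frame(column = 1:7, electrode = "e1",
                                   electrode_idx = 1L, frequency = 1:7),
        timepoint = 0, band = "all"), class = "feature_matrix")),
      times = 0, y = lab,
      feature_index = data.frame(column = 1:7), band = "all"),
      class = "feature_series")
  }
  real <- quiet_glmnet(outer_cv_decode(make_ser(y), folds = 5, seed = 1,
                                       inner_folds = 4))
  expect_gt(real$timecourse, 0.85)
  # shuffled labels against the fixed feature matrix
  accs <- replicate(10, {
    ys <- sample(y)
    quiet_glmnet(outer_cv_decode(make_ser(ys), folds = 5, seed = 1,
                                 inner_folds = 4))$timecourse
  })
  ci <- mean(accs) + c(-1, 1) * qt(0.975, 9) * sd(accs) / sqrt(10)
  expect_gte(0.5, ci[1])
  expect_lte(0.5, ci[2])
})
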