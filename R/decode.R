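#' Regularization grid
#'
#' Log-spaced lambda values, descending (warm starts run from the sparse end
#' toward dense models). The default grid of 100 values from 0.2 down to
#' 0.002 is the canonical search range for this analysis.
#'
#' @param n number of values.
#' @param hi,lo grid endpoints (all positive, `hi > lo`).
#' @return numeric vector, strictly decreasing.
#' @export
lambda_grid <- function(n = 100, hi = 0.2, lo = 0.002) {
  stopifnot(n >= 1, lo > 0, hi >= lo)
  if (n == 1L) return(hi)
  exp(seq(log(hi), log(lo), length.out = n))
}

#' Build a stimuli x features matrix at one timepoint
#'
#' For power or phase tensors, columns are all selected frequencies for each
#' electrode at the requested timepoint (electrode-major order). For
#' voltage, columns are the samples of a window centred on the timepoint
#' (inclusive at both ends: 51 samples for a 50 ms window at 1000 Hz) for
#' each electrode.
#'
#' @param x a `tf_tensor` (power/phase) or a repetition-averaged
#'   [epoched_recording()] (voltage features).
#' @param timepoint analysis time in ms (must be on the tensor's grid).
#' @param band band name, `"all"` (tensor input), or ignored for voltage.
#' @param partition a [partition_bands()] result; required for named bands.
#' @param voltage_window window width in ms for voltage features.
#' @return An object of class `feature_matrix` with elements `X`, `y`,
#'   `feature_index`, `timepoint`.
#' @export
build_features <- function(x, timepoint, band = "all", partition = NULL,
                           voltage_window = 50) {
  if (inherits(x, "tf_tensor")) {
    ti <- match(timepoint, x$times)
    if (is.na(ti)) stop("timepoint not on the tensor's time grid")
    fidx <- if (identical(band, "all")) seq_len(x$grid$n_steps) else {
      if (is.null(partition))
        stop("a band partition is required for band = '", band, "'")
      band_indices(partition, band)
    }
    vals <- x$values[, fidx, ti, , drop = FALSE]   # e x f x 1 x s
    d <- dim(vals)
    X <- t(matrix(aperm(vals, c(2L, 1L, 4L, 3L)), d[1L] * d[2L], d[4L]))
    elec <- rep(seq_len(d[1L]), each = d[2L])
    feature_index <- data.frame(
      column = seq_len(ncol(X)),
      electrode = x$channels$name[elec],
      electrode_idx = elec,
      frequency = rep(x$grid$frequencies[fidx], d[1L]))
    y <- x$stimuli$class
  } else if (inherits(x, "epoched_recording")) {
    if (!is_averaged(x))
      stop("voltage features require a repetition-averaged recording")
    half <- voltage_window / 2
    idx <- which(x$times >= timepoint - half - 1e-9 &
                   x$times <= timepoint + half + 1e-9)
    if (length(idx) == 0L) stop("voltage window outside the epoch")
    vals <- x$voltage[, idx, , drop = FALSE]       # e x w x s
    d <- dim(vals)
    X <- t(matrix(aperm(vals, c(2L, 1L, 3L)), d[1L] * d[2L], d[3L]))
    elec <- rep(seq_len(d[1L]), each = d[2L])
    feature_index <- data.frame(
      column = seq_len(ncol(X)),
      electrode = x$channels$name[elec],
      electrode_idx = elec,
      offset_ms = rep(x$times[idx] - timepoint, d[1L]))
    y <- x$trials$class
  } else stop("x must be a tf_tensor or an epoched_recording")
  if (anyNA(X)) stop("feature matrix contains missing values; interpolate first")
  structure(list(X = X, y = as.integer(y), feature_index = feature_index,
                 timepoint = timepoint, band = band),
            class = "feature_matrix")
}

#' Feature matrices at every timepoint
#'
#' @inheritParams build_features
#' @param times analysis times; defaults to the tensor's own grid.
#' @return An object of class `feature_series`: list of [build_features()]
#'   results sharing `y`, plus the time grid.
#' @export
build_feature_series <- function(x, times = NULL, band = "all",
                                 partition = NULL, voltage_window = 50) {
  if (is.null(times))
    times <- if (inherits(x, "tf_tensor")) x$times else
      stop("times must be given for voltage features")
  mats <- lapply(times, build_features, x = x, band = band,
                 partition = partition, voltage_window = voltage_window)
  structure(list(matrices = mats, times = as.numeric(times),
                 y = mats[[1L]]$y, feature_index = mats[[1L]]$feature_index,
                 band = band),
            class = "feature_series")
}

glmnet_path <- function(X, y, lambdas, thresh = 1e-14) {
  glmnet::glmnet(X, factor(y, levels = c(0, 1)), family = "binomial",
                 alpha = 1, lambda = lambdas, standardize = TRUE,
                 thresh = thresh, maxit = 1e6)
}

#' Fit a LASSO-regularized logistic classifier at one penalty
#'
#' Minimizes the mean logistic deviance plus `lambda * sum(|beta|)` with an
#' unpenalized intercept. Features are standardized internally; coefficients
#' are reported on the original scale. The fit runs down a descending lambda
#' path ending at the requested value (warm starts), and the exact
#' coefficients at that value are returned. Convergence is tightened well
#' beyond the fitting backend's default so that coefficients agree with an
#' independent solver to 1e-4 even at the dense end of the path, where the
#' objective is flat.
#'
#' @param X numeric matrix, stimuli x features.
#' @param y 0/1 class labels (both classes must be present).
#' @param lambda a single penalty value, or a descending path whose last
#'   element is the target.
#' @return An object of class `classifier_model`: `coefficients`,
#'   `intercept`, `lambda`.
#' @export
fit_lasso_logistic <- function(X, y, lambda) {
  if (length(unique(y)) < 2L) stop("both classes must be present in y")
  target <- lambda[length(lambda)]
  path <- if (length(lambda) > 1L) lambda else
    sort(unique(c(lambda_grid(30, hi = max(0.5, target * 100), lo = target),
                  target)), decreasing = TRUE)
  fit <- glmnet_path(X, y, path)
  j <- which.min(abs(fit$lambda - target))
  structure(list(coefficients = as.numeric(fit$beta[, j]),
                 intercept = as.numeric(fit$a0[j]),
                 lambda = target),
            class = "classifier_model")
}

#' Predicted class probabilities and labels
#'
#' Predicted class is 1 when the predicted probability is at least 0.5.
#'
#' @param model a `classifier_model`.
#' @param X feature matrix on the original scale.
#' @return list with `prob` and `class`.
#' @export
predict_classes <- function(model, X) {
  eta <- drop(X %*% model$coefficients) + model$intercept
  prob <- stats::plogis(eta)
  list(prob = prob, class = as.integer(prob >= 0.5))
}

#' Stratified fold assignment
#'
#' Deals shuffled members of each class across folds so that every fold is
#' as class-balanced as possible (with 100 balanced stimuli and 10 folds,
#' every fold holds exactly 5 + 5).
#'
#' @param y 0/1 labels.
#' @param k number of folds.
#' @param seed RNG seed.
#' @return integer fold id per observation.
#' @export
make_stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Select the penalty by inner cross-validation
#'
#' Stratified inner CV on the training data; the criterion is the mean
#' squared error between the predicted probability and the 0/1 label,
#' pooled over held-out observations. Ties are broken toward the larger
#' (sparser) lambda. If a fold ends up single-class (possible only when a
#' class has fewer members than folds) the split is redrawn with the next
#' seed and a message is emitted.
#'
#' @param X,y training data.
#' @param grid descending lambda values, see [lambda_grid()].
#' @param inner_folds number of inner folds (capped at the smaller class
#'   size).
#' @param seed RNG seed for the inner split.
#' @return list with `lambda` (the selection), `mse` per grid value, `grid`.
#' @export
select_lambda <- function(X, y, grid = lambda_grid(), inner_folds = 10,
                          seed = 1) {
  if (length(grid) == 1L)
    return(list(lambda = grid, mse = NA_real_, grid = grid))
  k <- min(inner_folds, min(table(y)))
  fold <- make_stratified_folds(y, k, seed)
  tries <- 0L
  while (any(vapply(seq_len(k), function(f)
    length(unique(y[fold != f])) < 2L, logical(1)))) {
    tries <- tries + 1L
    if (tries > 25L) stop("could not build two-class inner folds")
    message("degenerate inner fold; resplitting with next seed")
    fold <- make_stratified_folds(y, k, seed + tries)
  }
  se <- matrix(NA_real_, length(y), length(grid))
  for (f in seq_len(k)) {
    tr <- fold != f
    # selection is robust to looser convergence than the final fit needs
    fit <- glmnet_path(X[tr, , drop = FALSE], y[tr], grid, thresh = 1e-7)
    prob <- stats::predict(fit, X[!tr, , drop = FALSE], type = "response")
    # glmnet may stop early on degenerate paths; align by lambda
    j <- match(round(fit$lambda, 12), round(grid, 12))
    se[!tr, j[!is.na(j)]] <- (prob[, !is.na(j), drop = FALSE] -
                                y[!tr])^2
  }
  mse <- colMeans(se)
  mse[is.na(mse)] <- Inf
  best <- which.min(mse)   # first minimum = largest lambda on ties
  list(lambda = grid[best], mse = mse, grid = grid)
}

#' Outer cross-validated decoding with temporal generalization
#'
#' For each outer fold and each training timepoint: select the penalty on
#' the training stimuli by inner CV, fit, and score the held-out stimuli —
#' at the training timepoint only (`generalize = FALSE`, the accuracy
#' timecourse) or at every test timepoint (`generalize = TRUE`, the full
#' train x test generalization matrix). The fold partition is fixed across
#' timepoints, so the same stimuli are held out everywhere.
#'
#' @param series a [build_feature_series()] result.
#' @param folds number of outer folds.
#' @param seed RNG seed (controls the outer split and, derived from it, the
#'   inner splits).
#' @param generalize compute the full generalization matrix?
#' @param grid lambda search grid.
#' @param inner_folds inner CV folds.
#' @return An object of class `generalization_result`: `accuracy` (train x
#'   test x fold), `timecourse` (mean over folds of the diagonal), `times`,
#'   `fold` assignment, `lambda` (timepoint x fold).
#' @export
outer_cv_decode <- function(series, folds = 10, seed = 1, generalize = TRUE,
                            grid = lambda_grid(), inner_folds = 10) {
  stopifnot(inherits(series, "feature_series"))
  y <- series$y
  if (min(table(y)) < folds)
    stop("labels cannot be stratified into this many folds")
  fold <- make_stratified_folds(y, folds, seed)
  nt <- length(series$times)
  acc <- array(NA_real_, dim = c(nt, nt, folds))
  lam <- matrix(NA_real_, nt, folds)
  for (f in seq_len(folds)) {
    tr <- fold != f
    for (i in seq_len(nt)) {
      Xi <- series$matrices[[i]]$X
      inner_seed <- (seed * 7919L + f * 1009L + i) %% 2147483647L
      sel <- select_lambda(Xi[tr, , drop = FALSE], y[tr], grid,
                           inner_folds, inner_seed)
      model <- fit_lasso_logistic(Xi[tr, , drop = FALSE], y[tr],
                                  grid[grid >= sel$lambda])
      lam[i, f] <- sel$lambda
      test_tps <- if (generalize) seq_len(nt) else i
      for (j in test_tps) {
        pr <- predict_classes(model, series$matrices[[j]]$X[!tr, ,
                                                            drop = FALSE])
        acc[i, j, f] <- mean(pr$class == y[!tr])
      }
    }
  }
  diag_acc <- vapply(seq_len(folds), function(f)
    acc[cbind(seq_len(nt), seq_len(nt), f)], numeric(nt))
  diag_acc <- matrix(diag_acc, nrow = nt)
  structure(list(accuracy = acc,
                 timecourse = rowMeans(diag_acc),
                 fold_timecourse = diag_acc,
                 times = series$times, fold = fold, lambda = lam,
                 band = series$band),
            class = "generalization_result")
}

#' Group-mean generalization matrix
#'
#' Fold-mean matrix per subject, then the unweighted mean over subjects.
#'
#' @param results list of `generalization_result`s (one per subject).
#' @return train x test matrix.
#' @export
group_generalization <- function(results) {
  mats <- lapply(results, function(r) rowMeans(r$accuracy, dims = 2L))
  Reduce(`+`, mats) / length(mats)
}

#' Subjects x time accuracy matrix
#'
#' @param results list of `generalization_result`s.
#' @return matrix, subjects x timepoints, of fold-mean diagonal accuracies.
#' @export
group_timecourse <- function(results) {
  do.call(rbind, lapply(results, function(r) r$timecourse))
}

#' Per-subject fold-mean generalization array
#'
#' @param results list of `generalization_result`s.
#' @return array subjects x train x test.
#' @export
subject_generalization <- function(results) {
  mats <- lapply(results, function(r) rowMeans(r$accuracy, dims = 2L))
  arr <- array(NA_real_, dim = c(length(mats), dim(mats[[1L]])))
  for (s in seq_along(mats)) arr[s, , ] <- mats[[s]]
  arr
}

#' Full-data coefficient models at every timepoint
#'
#' One classifier per timepoint trained on all stimuli (penalty selected by
#' inner CV on all stimuli). These models are never scored; they exist for
#' inspection of coefficients and code-direction analysis.
#'
#' @inheritParams outer_cv_decode
#' @return list of `classifier_model`s, one per timepoint, carrying the
#'   shared `feature_index` as an attribute.
#' @export
fit_full_models <- function(series, grid = lambda_grid(), inner_folds = 10,
                            seed = 1) {
  stopifnot(inherits(series, "feature_series"))
  models <- lapply(seq_along(series$times), function(i) {
    Xi <- series$matrices[[i]]$X
    inner_seed <- (seed * 104729L + i) %% 2147483647L
    sel <- select_lambda(Xi, series$y, grid, inner_folds, inner_seed)
    m <- fit_lasso_logistic(Xi, series$y, grid[grid >= sel$lambda])
    m$timepoint <- series$times[i]
    m
  })
  attr(models, "feature_index") <- series$feature_index
  attr(models, "times") <- series$times
  models
}
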