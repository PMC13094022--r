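#' Pairwise cosine distance between generalization-matrix rows
#'
#' `d(i, j) = 1 - (r_i . r_j) / (||r_i|| ||r_j||)`; symmetric with a zero
#' diagonal. Rows with zero norm are rejected.
#'
#' @param m numeric matrix (rows = training timepoints).
#' @return symmetric distance matrix.
#' @export
row_cosine_distance <- function(m) {
  m <- as.matrix(m)
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm == 0)) stop("cosine distance undefined for zero-norm rows")
  d <- 1 - (m %*% t(m)) / outer(nrm, nrm)
  d[d < 0] <- 0
  diag(d) <- 0
  d
}

#' Cluster training timepoints by generalization profile
#'
#' Agglomerative hierarchical clustering (complete linkage) on a precomputed
#' distance matrix, with the tree cut at `k` clusters. Cluster contiguity in
#' time is not assumed. When the accuracy matrix is supplied, per-cluster
#' mean test-time profiles are attached.
#'
#' @param dist square distance matrix (e.g. [row_cosine_distance()]).
#' @param k number of clusters; default 10.
#' @param profiles optional train x test accuracy matrix for cluster mean
#'   profiles.
#' @return An object of class `cluster_solution`: `assignment`, `k`, `tree`
#'   (the `hclust` object), and optionally `mean_profiles` (k x test).
#' @export
cluster_rows <- function(dist, k = 10, profiles = NULL) {
  dist <- as.matrix(dist)
  if (k > nrow(dist)) stop("k exceeds the number of rows")
  tree <- stats::hclust(stats::as.dist(dist), method = "complete")
  assignment <- stats::cutree(tree, k = k)
  mean_profiles <- NULL
  if (!is.null(profiles)) {
    profiles <- as.matrix(profiles)
    mean_profiles <- do.call(rbind, lapply(seq_len(k), function(cl)
      colMeans(profiles[assignment == cl, , drop = FALSE])))
  }
  structure(list(assignment = assignment, k = k, tree = tree,
                 mean_profiles = mean_profiles),
            class = "cluster_solution")
}

#' Signed area between an accuracy timecourse and chance
#'
#' Trapezoidal integral of `accuracy - chance` over the test-time range, in
#' accuracy x ms. Negative areas (below-chance stretches) are retained.
#'
#' @param acc accuracy per test time.
#' @param times uniform test-time grid, ms.
#' @param chance chance level.
#' @return signed area.
#' @export
auc_above_chance <- function(acc, times, chance = 0.5) {
  stopifnot(length(acc) == length(times))
  if (length(acc) < 2L) stop("need at least 2 points")
  dt <- diff(times)
  if (max(abs(dt - dt[1L])) > 1e-8) stop("time grid must be uniform")
  pracma::trapz(times, acc - chance)
}

piecewise_design <- function(x, breaks) {
  X <- cbind(1, x)
  for (b in breaks) X <- cbind(X, pmax(x - b, 0))
  X
}

piecewise_rss <- function(x, y, breaks) {
  fit <- stats::lm.fit(piecewise_design(x, breaks), y)
  sum(fit$residuals^2)
}

#' Continuous piecewise-linear fit with BIC breakpoint selection
#'
#' Fits continuous piecewise-linear least squares for 0 to `max_breaks`
#' breakpoints, with candidate breakpoints restricted to the interior of the
#' sampling grid. The search is exhaustive for up to two breakpoints and
#' greedy (best two-break solution extended by the best third) beyond.
#' Model choice uses `BIC = n * log(RSS / n) + p * log(n)` with
#' `p = 2 + 2 * breaks`; the minimum-BIC model wins (a tiny RSS floor keeps
#' exact fits comparable, so perfect fits prefer fewer breakpoints).
#'
#' @param x sampling grid (e.g. training times every 50 ms).
#' @param y values at `x` (e.g. generalization areas).
#' @param max_breaks maximum number of breakpoints.
#' @return An object of class `breakpoint_fit`: `breakpoints`, `n_breaks`,
#'   `coefficients`, `slopes` (per segment), `fitted`, `bic` (per candidate
#'   model), `rss`.
#' @export
fit_piecewise <- function(x, y, max_breaks = 3) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 2 * (max_breaks + 1))
    stop("need at least 2*(max_breaks+1) points")
  candidates <- x[-c(1L, n)]
  best_by_b <- vector("list", max_breaks + 1L)
  best_by_b[[1L]] <- list(breaks = numeric(0), rss = piecewise_rss(x, y,
                                                                   numeric(0)))
  if (max_breaks >= 1L) {
    rss1 <- vapply(candidates, function(b) piecewise_rss(x, y, b),
                   numeric(1))
    best_by_b[[2L]] <- list(breaks = candidates[which.min(rss1)],
                            rss = min(rss1))
  }
  if (max_breaks >= 2L && length(candidates) >= 2L) {
    combos <- utils::combn(candidates, 2L)
    rss2 <- apply(combos, 2L, function(b) piecewise_rss(x, y, b))
    best_by_b[[3L]] <- list(breaks = combos[, which.min(rss2)],
                            rss = min(rss2))
  }
  if (max_breaks >= 3L && length(candidates) >= 3L) {
    base <- best_by_b[[3L]]$breaks
    rest <- setdiff(candidates, base)
    rss3 <- vapply(rest, function(b)
      piecewise_rss(x, y, sort(c(base, b))), numeric(1))
    best_by_b[[4L]] <- list(breaks = sort(c(base, rest[which.min(rss3)])),
                            rss = min(rss3))
  }
  best_by_b <- Filter(Negate(is.null), best_by_b)
  bic <- vapply(best_by_b, function(bb) {
    p <- 2 + 2 * length(bb$breaks)
    n * log(max(bb$rss, 1e-12) / n) + p * log(n)
  }, numeric(1))
  sel <- best_by_b[[which.min(bic)]]
  fit <- stats::lm.fit(piecewise_design(x, sel$breaks), y)
  coefs <- fit$coefficients
  slopes <- cumsum(coefs[-1L])
  structure(list(breakpoints = sel$breaks, n_breaks = length(sel$breaks),
                 coefficients = coefs, slopes = unname(slopes),
                 fitted = fit$fitted.values, rss = sel$rss,
                 bic = stats::setNames(bic, vapply(best_by_b, function(bb)
                   as.character(length(bb$breaks)), character(1)))),
            class = "breakpoint_fit")
}

#' Code-direction map from full-data coefficient models
#'
#' Per subject, electrode and timepoint: the mean classifier coefficient
#' over the band's features at that electrode. At group level: the number of
#' subjects whose mean is nonzero and the proportion of those that are
#' negative (with class coding animate = 0 / inanimate = 1, a negative
#' coefficient means increased power or voltage signals the animate class).
#' The proportion is `NA` wherever no subject selected the electrode.
#'
#' @param models_by_subject list (subjects) of [fit_full_models()] results.
#' @param band band name or `"all"`; for power/phase features the band
#'   filters on the `frequency` column of the feature index, for voltage
#'   features all window offsets are used.
#' @param partition a [partition_bands()] result (needed for named bands on
#'   frequency features).
#' @return list with `subject_mean` (array subjects x electrodes x times),
#'   `map` (long data.frame: electrode, time, n_selected,
#'   proportion_negative), `electrodes`, `times`.
#' @export
code_direction <- function(models_by_subject, band = "all",
                           partition = NULL) {
  fi <- attr(models_by_subject[[1L]], "feature_index")
  times <- attr(models_by_subject[[1L]], "times")
  if (!is.null(fi$frequency) && !identical(band, "all")) {
    if (is.null(partition)) stop("a band partition is required")
    if (!band %in% names(partition$edges)) stop("unknown band: ", band)
    edge <- partition$edges[[band]]
    last <- band == names(partition$edges)[length(partition$edges)]
    keep <- fi$frequency >= edge[1] &
      (fi$frequency < edge[2] | (last & fi$frequency <= edge[2]))
  } else keep <- rep(TRUE, nrow(fi))
  if (!any(keep)) stop("band selects no features")
  electrodes <- unique(fi$electrode)
  ns <- length(models_by_subject); nt <- length(times)
  sm <- array(0, dim = c(ns, length(electrodes), nt),
              dimnames = list(NULL, electrodes, NULL))
  for (s in seq_len(ns)) {
    fis <- attr(models_by_subject[[s]], "feature_index")
    stopifnot(nrow(fis) == nrow(fi))
    for (ti in seq_len(nt)) {
      beta <- models_by_subject[[s]][[ti]]$coefficients
      agg <- tapply(beta[keep], fis$electrode[keep], mean)
      sm[s, names(agg), ti] <- agg
    }
  }
  n_sel <- apply(sm != 0, c(2L, 3L), sum)
  n_neg <- apply(sm < 0, c(2L, 3L), sum)
  prop_neg <- ifelse(n_sel > 0, n_neg / n_sel, NA_real_)
  map <- data.frame(
    electrode = rep(electrodes, times = nt),
    time = rep(times, each = length(electrodes)),
    band = band,
    n_selected = as.vector(n_sel),
    proportion_negative = as.vector(prop_neg))
  list(subject_mean = sm, map = map, electrodes = electrodes, times = times)
}
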