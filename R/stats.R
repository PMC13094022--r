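#' One-tailed one-sample t-tests of a group timecourse against chance
#'
#' Per timepoint, a one-sample t-test (alternative: greater than chance)
#' across subjects, df = n - 1, followed by Benjamini-Hochberg adjustment
#' across timepoints. Zero-variance timepoints are flagged degenerate and
#' get p = 0 when the mean exceeds chance, else p = 1.
#'
#' @param acc numeric matrix, subjects x timepoints.
#' @param chance chance level; default 0.5.
#' @param alpha FDR level for the significance flags.
#' @param times optional timepoint labels (ms).
#' @return data.frame with one row per timepoint: `time`, `mean`, `t`, `p`,
#'   `p_adj`, `significant`, `degenerate`.
#' @export
ttest_vs_chance <- function(acc, chance = 0.5, alpha = 0.05, times = NULL) {
  acc <- as.matrix(acc)
  n <- nrow(acc)
  if (n < 2L) stop("need at least 2 subjects")
  m <- colMeans(acc)
  s <- apply(acc, 2L, stats::sd)
  t_stat <- (m - chance) / (s / sqrt(n))
  p <- stats::pt(t_stat, df = n - 1L, lower.tail = FALSE)
  degenerate <- s == 0
  p[degenerate] <- ifelse(m[degenerate] > chance, 0, 1)
  t_stat[degenerate] <- NA_real_
  adj <- bh_fdr(p, alpha)
  data.frame(time = if (is.null(times)) seq_along(m) else times,
             mean = m, t = t_stat, p = p, p_adj = adj$p_adj,
             significant = adj$reject, degenerate = degenerate)
}

#' Classic paired t-test with degenerate-case guards
#'
#' Two-sided paired t-test on the differences. All-zero differences give
#' t = 0, p = 1 (flagged); nonzero constant differences have infinite t and
#' are reported as p = 0, also flagged.
#'
#' @param a,b equal-length numeric vectors (length >= 2), paired by subject.
#' @return list with `t`, `p`, `df`, `degenerate`.
#' @export
paired_ttest <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  d <- a - b
  n <- length(d)
  if (stats::sd(d) == 0) {
    if (all(d == 0)) return(list(t = 0, p = 1, df = n - 1L,
                                 degenerate = TRUE))
    return(list(t = sign(mean(d)) * Inf, p = 0, df = n - 1L,
                degenerate = TRUE))
  }
  t_stat <- mean(d) / (stats::sd(d) / sqrt(n))
  list(t = t_stat, p = 2 * stats::pt(abs(t_stat), df = n - 1L,
                                     lower.tail = FALSE),
       df = n - 1L, degenerate = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment (`adjusted p = min over j >= rank of m * p_(j) / j`,
#' capped at 1) with rejection flags at level `alpha`.
#'
#' @param p raw p-values in `[0, 1]`.
#' @param alpha FDR level.
#' @return list with `p_adj` and logical `reject`.
#' @export
bh_fdr <- function(p, alpha = 0.05) {
  if (length(p) == 0L) return(list(p_adj = numeric(0), reject = logical(0)))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(p, method = "BH")
  list(p_adj = adj, reject = !is.na(adj) & adj <= alpha)
}

#' Best-classifier equivalence map over a generalization matrix
#'
#' For each test timepoint, finds the training timepoint with the highest
#' group-mean accuracy, then asks — via paired t-tests across subjects,
#' BH-adjusted over all train x test cells — which other training timepoints
#' perform statistically indistinguishably from that best classifier.
#' Cells reliably worse than the best are classed above-chance when their
#' own one-tailed test against chance survives FDR, otherwise chance.
#'
#' @param gen array subjects x train x test of fold-mean accuracies (see
#'   [subject_generalization()]).
#' @param alpha FDR level.
#' @param chance chance accuracy.
#' @return list with `category` (train x test matrix coded 2 =
#'   best-equivalent, 1 = above-chance-but-worse, 0 = chance), `best_train`
#'   (index per test time), and the underlying adjusted p matrices.
#' @export
best_classifier_map <- function(gen, alpha = 0.05, chance = 0.5) {
  stopifnot(length(dim(gen)) == 3L)
  ns <- dim(gen)[1L]; nt <- dim(gen)[2L]
  if (ns < 2L) stop("need at least 2 subjects")
  gm <- apply(gen, c(2L, 3L), mean)
  best <- apply(gm, 2L, which.max)
  p_paired <- matrix(1, nt, nt)
  p_chance <- matrix(NA_real_, nt, nt)
  for (j in seq_len(nt)) {
    b <- best[j]
    for (i in seq_len(nt)) {
      if (i != b)
        p_paired[i, j] <- paired_ttest(gen[, b, j], gen[, i, j])$p
      x <- gen[, i, j]
      p_chance[i, j] <- if (stats::sd(x) == 0)
        ifelse(mean(x) > chance, 0, 1) else
          stats::pt((mean(x) - chance) / (stats::sd(x) / sqrt(ns)),
                    df = ns - 1L, lower.tail = FALSE)
    }
  }
  adj_paired <- matrix(bh_fdr(as.vector(p_paired), alpha)$p_adj, nt, nt)
  adj_chance <- matrix(bh_fdr(as.vector(p_chance), alpha)$p_adj, nt, nt)
  category <- matrix(0L, nt, nt)
  category[adj_chance <= alpha] <- 1L
  category[adj_paired > alpha] <- 2L
  for (j in seq_len(nt)) category[best[j], j] <- 2L
  list(category = category, best_train = best,
       p_paired_adj = adj_paired, p_chance_adj = adj_chance)
}
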