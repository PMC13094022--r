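#' Pipeline run configuration
#'
#' Bundles every stage parameter with explicit seeds so a run is fully
#' reproducible. The defaults describe a small synthetic cohort on a reduced
#' analysis grid; the full-study settings (60 frequencies, 10 ms steps,
#' 10 folds) are a matter of changing the arguments.
#'
#' @param n_subjects subjects to simulate.
#' @param synth a [synth_config()] (per-subject seeds are derived from it).
#' @param baseline_window,car,downsample,reject_sd preprocessing controls
#'   (ms pair, logical, logical, SD threshold or `NULL` to skip).
#' @param f_min,f_max,n_freqs,cycles time-frequency grid parameters.
#' @param times analysis time grid, ms.
#' @param db_baseline dB-normalization baseline window, ms.
#' @param bands character vector of decoders to run: band names, `"all"`,
#'   and/or `"voltage"`.
#' @param folds,inner_folds outer/inner CV folds.
#' @param lambda lambda search grid.
#' @param alpha FDR level.
#' @param k_clusters clusters for the generalization-profile analysis.
#' @param auc_step_ms spacing of training times entering the AUC/breakpoint
#'   analysis.
#' @param generalize compute full generalization matrices?
#' @param seed master seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(n_subjects = 4,
                       synth = synth_config(n_channels = 16,
                                            n_stimuli_per_class = 20,
                                            n_runs = 4),
                       baseline_window = c(-200, -1), car = TRUE,
                       downsample = FALSE, reject_sd = 10,
                       f_min = 4, f_max = 200, n_freqs = 12,
                       cycles = c(5, 15),
                       times = seq(0, 1600, by = 100),
                       db_baseline = c(-300, -100),
                       bands = c("all"), folds = 5, inner_folds = 5,
                       lambda = lambda_grid(), alpha = 0.05,
                       k_clusters = 4, auc_step_ms = 200,
                       generalize = TRUE, seed = 1) {
  known <- c(names(default_band_edges()), "all", "voltage")
  bad <- setdiff(bands, known)
  if (length(bad))
    stop("unknown band name in `bands`: ", paste(bad, collapse = ", "))
  cfg <- list(n_subjects = n_subjects, synth = synth,
              baseline_window = baseline_window, car = car,
              downsample = downsample, reject_sd = reject_sd,
              f_min = f_min, f_max = f_max, n_freqs = n_freqs,
              cycles = cycles, times = times, db_baseline = db_baseline,
              bands = bands, folds = folds, inner_folds = inner_folds,
              lambda = lambda, alpha = alpha, k_clusters = k_clusters,
              auc_step_ms = auc_step_ms, generalize = generalize,
              seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

config_to_list <- function(cfg) {
  x <- unclass(cfg)
  x$synth <- unclass(x$synth)
  x$synth$effects <- lapply(x$synth$effects, function(e) {
    e <- unclass(e)
    e$envelope <- unclass(e$envelope)
    if (!is.null(e$sign_schedule))
      e$sign_schedule <- as.list(as.data.frame(e$sign_schedule))
    e
  })
  x
}

list_to_config <- function(x) {
  eff <- lapply(x$synth$effects, function(e) {
    env <- do.call(
      switch(e$envelope$type,
             boxcar = envelope_boxcar, ramp = envelope_ramp,
             fig6 = envelope_fig6),
      e$envelope[setdiff(names(e$envelope), "type")])
    ss <- if (!is.null(e$sign_schedule))
      as.data.frame(lapply(e$sign_schedule, unlist)) else NULL
    effect_spec(unlist(e$electrodes), unlist(e$freq_band),
                unlist(e$amplitude_by_class), env, ss, e$phase)
  })
  sy <- x$synth
  synth <- synth_config(sy$n_channels, sy$n_stimuli_per_class, sy$n_runs,
                        sy$fs, unlist(sy$epoch_window), sy$noise_exponent,
                        sy$noise_scale, eff, sy$seed)
  args <- x[setdiff(names(x), "synth")]
  args <- lapply(args, function(v) if (is.list(v)) unlist(v) else v)
  do.call(run_config, c(list(synth = synth), args))
}

#' Write / read a run configuration as YAML
#'
#' The YAML round-trip is lossless: `read_run_config(write_run_config(cfg))`
#' reproduces `cfg`.
#'
#' @param cfg a [run_config()].
#' @param path YAML file path.
#' @return `path` invisibly (write) or a `run_config` (read).
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(config_to_list(cfg), path, precision = 15)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  list_to_config(yaml::read_yaml(path))
}

stage_files_md5 <- function(files) {
  sums <- tools::md5sum(files)
  data.frame(file = basename(files), md5 = unname(sums))
}

#' Run the full pipeline on a synthetic cohort
#'
#' Executes simulate -> preprocess -> time-frequency -> decode (per
#' requested feature set) -> group stats -> dynamics, writing TSV artifacts
#' plus a manifest of per-stage checksums and timings. Subjects are
#' processed independently and aggregated at the group level.
#'
#' @param cfg a [run_config()].
#' @param out_dir output directory.
#' @return the manifest data.frame, invisibly; also written to
#'   `manifest.tsv`.
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  clock <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    v <- force(expr)
    list(value = v, seconds = proc.time()[["elapsed"]] - t0)
  }
  cfg_path <- file.path(out_dir, "config.yaml")
  write_run_config(cfg, cfg_path)

  st <- clock({
    cohort <- simulate_cohort(cfg$synth, cfg$n_subjects)
    cohort
  })
  cohort <- st$value
  manifest$simulate <- data.frame(stage = "simulate", file = "config.yaml",
                                  md5 = unname(tools::md5sum(cfg_path)),
                                  seconds = st$seconds)

  grid <- build_grid(cfg$f_min, cfg$f_max, cfg$n_freqs, cfg$cycles)
  partition <- partition_bands(grid)

  st <- clock(lapply(cohort, function(subj) {
    rec <- subj$recording
    rec <- baseline_correct(rec, cfg$baseline_window)
    if (cfg$car) rec <- common_average_reference(rec)
    if (cfg$downsample) rec <- boxcar_downsample(rec)
    if (!is.null(cfg$reject_sd)) rec <- reject_extreme_trials(rec,
                                                              cfg$reject_sd)
    rec
  }))
  pre <- st$value
  manifest$preprocess <- data.frame(stage = "preprocess", file = NA,
                                    md5 = NA, seconds = st$seconds)

  st <- clock(lapply(pre, function(rec)
    extract_power(rec, grid, cfg$times, cfg$db_baseline)))
  tensors <- st$value
  manifest$tfr <- data.frame(stage = "tfr", file = NA, md5 = NA,
                             seconds = st$seconds)

  results <- list()
  for (band in cfg$bands) {
    st <- clock(lapply(seq_along(tensors), function(s) {
      series <- if (identical(band, "voltage"))
        build_feature_series(average_repetitions(pre[[s]]),
                             times = cfg$times) else
        build_feature_series(tensors[[s]], band = band,
                             partition = partition)
      outer_cv_decode(series, folds = cfg$folds,
                      seed = cfg$seed + s, generalize = cfg$generalize,
                      grid = cfg$lambda, inner_folds = cfg$inner_folds)
    }))
    results[[band]] <- st$value
    tc <- group_timecourse(st$value)
    stats_df <- ttest_vs_chance(tc, alpha = cfg$alpha, times = cfg$times)
    f_tc <- file.path(out_dir, sprintf("timecourse_%s.tsv", band))
    utils::write.table(stats_df, f_tc, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    files <- f_tc
    if (cfg$generalize) {
      gm <- group_generalization(st$value)
      f_gm <- file.path(out_dir, sprintf("generalization_%s.tsv", band))
      utils::write.table(as.data.frame(gm), f_gm, sep = "\t",
                         row.names = FALSE, quote = FALSE)
      files <- c(files, f_gm)
    }
    mf <- stage_files_md5(files)
    manifest[[paste0("decode_", band)]] <-
      data.frame(stage = paste0("decode_", band), file = mf$file,
                 md5 = mf$md5, seconds = st$seconds)
  }

  if (cfg$generalize && length(results)) {
    band1 <- names(results)[1L]
    st <- clock({
      gm <- group_generalization(results[[band1]])
      dist <- row_cosine_distance(gm - 0.5)
      cl <- cluster_rows(dist, k = min(cfg$k_clusters, nrow(gm)),
                         profiles = gm)
      keep <- which((cfg$times - cfg$times[1L]) %% cfg$auc_step_ms == 0)
      areas <- vapply(keep, function(i)
        auc_above_chance(gm[i, ], cfg$times), numeric(1))
      pw <- fit_piecewise(cfg$times[keep], areas,
                          max_breaks = min(3, floor(length(keep) / 2) - 1))
      list(clusters = cl, areas = areas, piecewise = pw, keep = keep)
    })
    dyn <- st$value
    f_cl <- file.path(out_dir, "clusters.tsv")
    utils::write.table(
      data.frame(train_time = cfg$times,
                 cluster = dyn$clusters$assignment),
      f_cl, sep = "\t", row.names = FALSE, quote = FALSE)
    f_auc <- file.path(out_dir, "auc.tsv")
    utils::write.table(
      data.frame(train_time = cfg$times[dyn$keep], area = dyn$areas),
      f_auc, sep = "\t", row.names = FALSE, quote = FALSE)
    mf <- stage_files_md5(c(f_cl, f_auc))
    manifest$dynamics <- data.frame(stage = "dynamics", file = mf$file,
                                    md5 = mf$md5, seconds = st$seconds)
  }

  manifest <- do.call(rbind, manifest)
  rownames(manifest) <- NULL
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
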