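#' Write an epoched recording to a plain-text container directory
#'
#' Layout: `voltage.tsv` (columns `channel`, `trial`, then one column per
#' sample), `times_ms.tsv`, `trials.tsv`, `channels.tsv` and `meta.yaml`
#' (`fs`, dimensions). Everything is diffable, language-portable text.
#'
#' @param rec an [epoched_recording()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_recording <- function(rec, dir) {
  stopifnot(inherits(rec, "epoched_recording"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(rec$voltage)
  flat <- do.call(rbind, lapply(seq_len(d[1L]), function(ch)
    t(matrix(rec$voltage[ch, , ], d[2L], d[3L]))))
  df <- cbind(data.frame(channel = rep(seq_len(d[1L]), each = d[3L]),
                         trial = rep(seq_len(d[3L]), d[1L])),
              as.data.frame(flat))
  utils::write.table(df, file.path(dir, "voltage.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(data.frame(time_ms = rec$times),
                     file.path(dir, "times_ms.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(rec$trials, file.path(dir, "trials.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(rec$channels, file.path(dir, "channels.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  yaml::write_yaml(list(fs = rec$fs, n_channels = d[1L],
                        n_samples = d[2L], n_trials = d[3L],
                        averaged = is_averaged(rec)),
                   file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' Read an epoched recording written by [write_recording()]
#'
#' @param dir container directory.
#' @return an [epoched_recording()].
#' @export
read_recording <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  df <- utils::read.table(file.path(dir, "voltage.tsv"), header = TRUE,
                          sep = "\t")
  times <- utils::read.table(file.path(dir, "times_ms.tsv"), header = TRUE,
                             sep = "\t")$time_ms
  trials <- utils::read.table(file.path(dir, "trials.tsv"), header = TRUE,
                              sep = "\t")
  channels <- utils::read.table(file.path(dir, "channels.tsv"),
                                header = TRUE, sep = "\t")
  df <- df[order(df$channel, df$trial), ]
  volt <- array(0, dim = c(meta$n_channels, meta$n_samples, meta$n_trials))
  vals <- as.matrix(df[, -(1:2)])
  for (r in seq_len(nrow(df)))
    volt[df$channel[r], , df$trial[r]] <- vals[r, ]
  rec <- epoched_recording(volt, times, meta$fs, trials, channels)
  if (isTRUE(meta$averaged)) attr(rec, "averaged") <- TRUE
  rec
}

#' Write / read planted ground truth as structured text
#'
#' Serializes the `ground_truth` record emitted by [generate_recording()] —
#' stimulus labels, effect electrodes, bands, amplitudes, envelope samples
#' and sign schedules — as YAML.
#'
#' @param truth a `ground_truth` object.
#' @param path YAML file path.
#' @return `path` invisibly (write); a `ground_truth` (read).
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  x <- unclass(truth)
  x$labels <- as.list(x$labels)
  x$effects <- lapply(x$effects, function(e) {
    if (!is.null(e$sign_schedule))
      e$sign_schedule <- as.list(as.data.frame(e$sign_schedule))
    e
  })
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- yaml::read_yaml(path)
  x$labels <- data.frame(stimulus_id = unlist(x$labels$stimulus_id),
                         class = unlist(x$labels$class))
  x$effects <- lapply(x$effects, function(e) {
    e$electrodes <- unlist(e$electrodes)
    e$freq_band <- unlist(e$freq_band)
    e$amplitude_by_class <- unlist(e$amplitude_by_class)
    e$envelope <- unlist(e$envelope)
    if (!is.null(e$sign_schedule))
      e$sign_schedule <- as.data.frame(lapply(e$sign_schedule, unlist))
    e
  })
  x$times <- unlist(x$times)
  structure(x, class = "ground_truth")
}

#' Export a feature matrix as TSV
#'
#' Rows are stimuli; the header encodes the feature index
#' (`electrode.frequency` or `electrode.offset`), compatible with a
#' deposited stimuli x features layout. A `class` column holds the labels.
#'
#' @param fm a [build_features()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  fi <- fm$feature_index
  tag <- if (!is.null(fi$frequency))
    sprintf("%s.f%.4g", fi$electrode, fi$frequency) else
      sprintf("%s.t%+g", fi$electrode, fi$offset_ms)
  df <- data.frame(class = fm$y, fm$X)
  names(df) <- c("class", tag)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Import a feature matrix written by [write_feature_matrix()]
#'
#' @param path TSV file with a `class` column and feature columns.
#' @param timepoint time label to attach, ms.
#' @return a `feature_matrix` (feature index reduced to column/electrode
#'   tags parsed from the header).
#' @export
read_feature_matrix <- function(path, timepoint = NA_real_) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  y <- df$class
  X <- as.matrix(df[, setdiff(names(df), "class"), drop = FALSE])
  tags <- colnames(X)
  electrode <- sub("\\.[ft][^.]*$", "", tags)
  structure(list(X = unname(X), y = as.integer(y),
                 feature_index = data.frame(column = seq_along(tags),
                                            electrode = electrode,
                                            tag = tags),
                 timepoint = timepoint, band = "imported"),
            class = "feature_matrix")
}
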