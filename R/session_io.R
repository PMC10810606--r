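## On-disk session layout (plain text, deterministic):
##   trials.csv    one row per trial, canonical column order
##   neurons.csv   per-neuron metadata
##   spikes.csv    long table (neuron_id, spike_time)
##   eye.csv       per-sample x, y, pupil (+ meta in session.yaml)
##   channels.csv  time x channels voltage matrix (+ meta in session.yaml)
##   session.yaml  config and stream metadata
## Numbers are written with %.17g so that save -> load round-trips doubles
## bit-exactly and re-saving an unchanged session is byte-identical.

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, character(1))
  out
}

fmt_col <- function(x) {
  if (is.numeric(x)) return(fmt_num(x))
  if (is.logical(x)) return(ifelse(is.na(x), "NA", ifelse(x, "TRUE", "FALSE")))
  ifelse(is.na(x), "NA", as.character(x))
}

write_exact_csv <- function(df, path) {
  cols <- lapply(df, fmt_col)
  lines <- c(paste(names(df), collapse = ","),
             if (nrow(df)) do.call(paste, c(cols, sep = ",")))
  writeLines(lines, path)
}

read_exact_csv <- function(path, col_classes) {
  read.csv(path, colClasses = col_classes, na.strings = "NA",
           stringsAsFactors = FALSE)
}

TRIAL_CLASSES <- c(trial_id = "integer", mouse = "character", task = "character",
                   figure_side = "character", background_orientation = "numeric",
                   stimulus_onset = "numeric", stimulus = "character",
                   response = "character", reaction_time = "numeric",
                   laser_onset = "numeric", is_correction = "logical",
                   excluded = "logical", exclusion_reason = "character")

#' Save a session bundle to a directory
#'
#' Writes the deterministic plain-text layout described in the package
#' vignette (`trials.csv`, `neurons.csv`, `spikes.csv`, optional `eye.csv`
#' and `channels.csv`, and `session.yaml`). Numeric fields are written at
#' full double precision, so saving and re-loading reproduces every field
#' bit-exactly and re-saving an unchanged session yields byte-identical
#' files.
#'
#' @param session an [fg_session()]; must pass [validate_session()].
#' @param path target directory (created if absent).
#' @param strict if `TRUE` (default), refuse to save a session with
#'   validation violations.
#' @return `path`, invisibly.
#' @export
save_session <- function(session, path, strict = TRUE) {
  if (strict) {
    rep <- validate_session(session)
    if (nrow(rep)) {
      stop("session fails validation (", nrow(rep), " violation(s)); ",
           "first: ", rep$message[1])
    }
  }
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  write_exact_csv(as.data.frame(session$trials), file.path(path, "trials.csv"))

  nmeta <- data.frame(
    neuron_id = vapply(session$neurons, `[[`, character(1), "neuron_id"),
    channel = vapply(session$neurons, function(n) as.integer(n$channel), integer(1)),
    estimated_depth = vapply(session$neurons, function(n) as.numeric(n$estimated_depth), numeric(1)),
    is_stable = vapply(session$neurons, function(n) isTRUE(n$is_stable), logical(1)),
    is_visual = vapply(session$neurons, function(n) {
      if (is.na(n$is_visual)) NA else isTRUE(n$is_visual)
    }, logical(1)),
    rf_class = vapply(session$neurons, `[[`, character(1), "rf_class"),
    stringsAsFactors = FALSE)
  write_exact_csv(nmeta, file.path(path, "neurons.csv"))
  spikes <- data.frame(
    neuron_id = rep(nmeta$neuron_id,
                    vapply(session$neurons, function(n) length(n$spike_times), integer(1))),
    spike_time = unlist(lapply(session$neurons, `[[`, "spike_times"), use.names = FALSE),
    stringsAsFactors = FALSE)
  if (!nrow(spikes)) spikes <- data.frame(neuron_id = character(), spike_time = numeric())
  write_exact_csv(spikes, file.path(path, "spikes.csv"))

  meta <- list(config = unclass(session$config))
  if (!is.null(session$eye)) {
    write_exact_csv(data.frame(x = session$eye$x, y = session$eye$y,
                               pupil = session$eye$pupil),
                    file.path(path, "eye.csv"))
    meta$eye <- list(sample_rate = session$eye$sample_rate, t0 = session$eye$t0)
  }
  if (!is.null(session$channels)) {
    m <- t(session$channels$samples)
    df <- as.data.frame(m)
    names(df) <- paste0("ch", seq_len(ncol(df)))
    write_exact_csv(df, file.path(path, "channels.csv"))
    meta$channels <- list(sample_rate = session$channels$sample_rate,
                          channel_spacing = session$channels$channel_spacing,
                          t0 = session$channels$t0)
  }
  yaml::write_yaml(meta, file.path(path, "session.yaml"),
                   precision = 17)
  invisible(path)
}

#' Load a session bundle from a directory
#'
#' Reads the layout written by [save_session()], reconstructs the bundle,
#' and attaches a validation report (attribute `"validation"`). Missing
#' mandatory files raise an error naming the file.
#'
#' @param path session directory.
#' @return an [fg_session()] with a `"validation"` attribute.
#' @export
load_session <- function(path) {
  for (f in c("trials.csv", "neurons.csv", "spikes.csv", "session.yaml")) {
    if (!file.exists(file.path(path, f))) {
      stop("session at '", path, "' is missing mandatory file: ", f)
    }
  }
  trials <- as_trial_table(read_exact_csv(file.path(path, "trials.csv"),
                                          TRIAL_CLASSES))
  meta <- yaml::read_yaml(file.path(path, "session.yaml"))
  cfg <- do.call(analysis_config, meta$config)
  nmeta <- read_exact_csv(file.path(path, "neurons.csv"),
                          c(neuron_id = "character", channel = "integer",
                            estimated_depth = "numeric", is_stable = "logical",
                            is_visual = "logical", rf_class = "character"))
  spikes <- read_exact_csv(file.path(path, "spikes.csv"),
                           c(neuron_id = "character", spike_time = "numeric"))
  neurons <- lapply(seq_len(nrow(nmeta)), function(i) {
    neuron_recording(nmeta$neuron_id[i],
                     spikes$spike_time[spikes$neuron_id == nmeta$neuron_id[i]],
                     channel = nmeta$channel[i],
                     estimated_depth = nmeta$estimated_depth[i],
                     is_stable = nmeta$is_stable[i],
                     is_visual = nmeta$is_visual[i],
                     rf_class = nmeta$rf_class[i])
  })
  eye <- NULL
  if (file.exists(file.path(path, "eye.csv"))) {
    e <- read_exact_csv(file.path(path, "eye.csv"),
                        c(x = "numeric", y = "numeric", pupil = "numeric"))
    eye <- eye_trace(e$x, e$y, e$pupil, sample_rate = meta$eye$sample_rate,
                     t0 = meta$eye$t0)
  }
  channels <- NULL
  if (file.exists(file.path(path, "channels.csv"))) {
    m <- as.matrix(read.csv(file.path(path, "channels.csv"),
                            colClasses = "numeric"))
    dimnames(m) <- NULL
    channels <- channel_data(t(m), sample_rate = meta$channels$sample_rate,
                             channel_spacing = meta$channels$channel_spacing,
                             t0 = meta$channels$t0)
  }
  ses <- fg_session(trials, neurons, eye, channels, cfg)
  attr(ses, "validation") <- validate_session(ses)
  ses
}
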