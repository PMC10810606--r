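## Shared data model: trial tables, neuron recordings, eye traces,
## multichannel voltage, and the session bundle that joins them.

TRIAL_COLUMNS <- c("trial_id", "mouse", "task", "figure_side",
                   "background_orientation", "stimulus_onset", "stimulus",
                   "response", "reaction_time", "laser_onset", "is_correction",
                   "excluded", "exclusion_reason")

TASKS <- c("contrast", "orientation", "phase")
RESPONSES <- c("hit", "error", "miss")
EXCLUSION_REASONS <- c("none", "eye_movement", "emua_artifact", "other")
RF_CLASSES <- c("inside", "edge", "outside", "unreliable")

#' Construct a trial table
#'
#' A trial table is a `data.frame` (class `trial_table`) with one row per
#' trial and the canonical columns: `trial_id`, `mouse`, `task`
#' (contrast/orientation/phase), `figure_side` (left/right),
#' `background_orientation` (0 or 90 degrees), `stimulus_onset` (seconds on
#' the session clock), `stimulus` ("figure" when the figure covers the
#' recorded receptive field, "ground" when it is placed in the opposite
#' hemifield, `NA` for purely behavioral sessions), `response`
#' (hit/error/miss), `reaction_time` (seconds from stimulus onset; `NA` on
#' misses), `laser_onset` (seconds from stimulus onset; `NA` on no-laser
#' trials), `is_correction`, `excluded`, and `exclusion_reason`.
#'
#' @param df a data.frame carrying at least `trial_id`, `task`,
#'   `figure_side`, `stimulus_onset`, and `response`; missing optional
#'   columns are filled with defaults.
#' @return the completed `trial_table`.
#' @export
as_trial_table <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("trial_id", "task", "figure_side", "stimulus_onset", "response")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("trial table lacks column(s): ", paste(miss, collapse = ", "))
  if (is.null(df[["mouse"]])) df$mouse <- "m1"
  if (is.null(df[["background_orientation"]])) df$background_orientation <- 0
  if (is.null(df[["stimulus"]])) df[["stimulus"]] <- NA_character_
  if (is.null(df[["reaction_time"]])) df$reaction_time <- NA_real_
  if (is.null(df[["laser_onset"]])) df$laser_onset <- NA_real_
  if (is.null(df[["is_correction"]])) df$is_correction <- FALSE
  if (is.null(df[["excluded"]])) df$excluded <- FALSE
  if (is.null(df[["exclusion_reason"]])) df$exclusion_reason <- "none"
  df <- df[, TRIAL_COLUMNS]
  df$trial_id <- as.integer(df$trial_id)
  df$stimulus_onset <- as.numeric(df$stimulus_onset)
  df$reaction_time <- as.numeric(df$reaction_time)
  df$laser_onset <- as.numeric(df$laser_onset)
  class(df) <- c("trial_table", "data.frame")
  df
}

#' Construct a neuron recording
#'
#' @param neuron_id character id.
#' @param spike_times numeric vector of spike times (seconds, session clock),
#'   sorted ascending.
#' @param channel recording channel index (integer) or `NA`.
#' @param estimated_depth micrometers from the collicular surface, or `NA`.
#' @param is_stable logical; stable across the session.
#' @param is_visual logical or `NA`; passes the visual-responsiveness
#'   criterion.
#' @param rf_class one of `"inside"`, `"edge"`, `"outside"`, `"unreliable"`.
#' @return an object of class `neuron_recording`.
#' @export
neuron_recording <- function(neuron_id, spike_times, channel = NA_integer_,
                             estimated_depth = NA_real_, is_stable = TRUE,
                             is_visual = NA, rf_class = "unreliable") {
  stopifnot(is.character(neuron_id), length(neuron_id) == 1L)
  rf_class <- match.arg(rf_class, RF_CLASSES)
  structure(list(neuron_id = neuron_id,
                 spike_times = as.numeric(spike_times),
                 channel = as.integer(channel),
                 estimated_depth = as.numeric(estimated_depth),
                 is_stable = isTRUE(is_stable),
                 is_visual = is_visual,
                 rf_class = rf_class),
            class = "neuron_recording")
}

#' Construct an eye trace
#'
#' @param x,y gaze position in degrees azimuth/elevation, one value per
#'   sample.
#' @param pupil pupil size (arbitrary units), one value per sample.
#' @param sample_rate samples per second.
#' @param t0 session-clock time of the first sample (seconds).
#' @return an object of class `eye_trace`.
#' @export
eye_trace <- function(x, y, pupil = rep(NA_real_, length(x)),
                      sample_rate, t0 = 0) {
  if (length(x) != length(y) || length(x) != length(pupil)) {
    stop("x, y and pupil must have equal lengths")
  }
  if (sample_rate <= 0) stop("sample_rate must be positive")
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 pupil = as.numeric(pupil),
                 sample_rate = as.numeric(sample_rate),
                 t0 = as.numeric(t0)),
            class = "eye_trace")
}

#' Construct a multichannel voltage segment
#'
#' @param samples numeric matrix, channels x time, microvolts. Channel index
#'   increases with depth along the probe.
#' @param sample_rate samples per second.
#' @param channel_spacing inter-channel spacing in micrometers (default 25).
#' @param t0 session-clock time of the first sample (seconds).
#' @return an object of class `channel_data`.
#' @export
channel_data <- function(samples, sample_rate, channel_spacing = 25, t0 = 0) {
  stopifnot(is.matrix(samples))
  structure(list(samples = samples, sample_rate = as.numeric(sample_rate),
                 channel_spacing = as.numeric(channel_spacing),
                 t0 = as.numeric(t0)),
            class = "channel_data")
}

#' Bundle session components
#'
#' @param trials a [as_trial_table()] trial table.
#' @param neurons list of [neuron_recording()] objects (may be empty).
#' @param eye optional [eye_trace()].
#' @param channels optional [channel_data()] (raw voltage).
#' @param config an [analysis_config()].
#' @return an object of class `fg_session`.
#' @export
fg_session <- function(trials, neurons = list(), eye = NULL, channels = NULL,
                       config = analysis_config()) {
  structure(list(trials = trials, neurons = neurons, eye = eye,
                 channels = channels, config = config),
            class = "fg_session")
}

#' Validate a session bundle
#'
#' Checks every data-model invariant and reports violations; content problems
#' are reported, never raised. Checks include: reaction time present iff the
#' response is not a miss and within the 0.2--2 s response window; laser
#' onsets non-negative; exclusion reason consistent with the excluded flag;
#' spike times sorted; visual neurons have an RF inside or on the edge of the
#' figure; eye-trace array lengths equal; voltage sampling fast enough for
#' the 500--5000 Hz eMUA band; and all stimulus onsets within the recording
#' span of any attached continuous data.
#'
#' @param session an [fg_session()].
#' @return a `data.frame` with columns `component`, `id`, `rule`, `message`;
#'   zero rows iff all invariants hold.
#' @export
validate_session <- function(session) {
  out <- list()
  add <- function(component, id, rule, message) {
    out[[length(out) + 1L]] <<- data.frame(component = component, id = as.character(id),
                                           rule = rule, message = message,
                                           stringsAsFactors = FALSE)
  }
  tr <- session$trials
  if (!is.null(tr)) {
    has_rt <- !is.na(tr$reaction_time)
    bad <- which(has_rt & tr$response == "miss")
    for (i in bad) add("trials", tr$trial_id[i], "rt_on_miss",
                       "reaction_time present on a miss trial")
    bad <- which(!has_rt & tr$response != "miss")
    for (i in bad) add("trials", tr$trial_id[i], "rt_missing",
                       "reaction_time absent on a non-miss trial")
    bad <- which(has_rt & (tr$reaction_time < 0.2 | tr$reaction_time > 2.0))
    for (i in bad) add("trials", tr$trial_id[i], "rt_range",
                       "reaction_time outside the 0.2-2 s response window")
    bad <- which(!is.na(tr$laser_onset) & tr$laser_onset < 0)
    for (i in bad) add("trials", tr$trial_id[i], "laser_onset_negative",
                       "laser_onset must be >= 0")
    bad <- which(xor(tr$excluded, tr$exclusion_reason != "none"))
    for (i in bad) add("trials", tr$trial_id[i], "exclusion_consistency",
                       "exclusion_reason must be 'none' iff excluded is FALSE")
    bad <- which(!tr$response %in% RESPONSES)
    for (i in bad) add("trials", tr$trial_id[i], "response_enum",
                       "response must be hit/error/miss")
    bad <- which(!tr$task %in% TASKS)
    for (i in bad) add("trials", tr$trial_id[i], "task_enum",
                       "task must be contrast/orientation/phase")
  }
  for (nr in session$neurons) {
    if (is.unsorted(nr$spike_times)) {
      add("neurons", nr$neuron_id, "spikes_sorted",
          "spike_times must be non-decreasing")
    }
    if (isTRUE(nr$is_visual) && !nr$rf_class %in% c("inside", "edge")) {
      add("neurons", nr$neuron_id, "visual_rf_class",
          "is_visual implies rf_class inside or edge")
    }
  }
  eye <- session$eye
  if (!is.null(eye)) {
    if (eye$sample_rate <= 0) add("eye", "eye", "sample_rate", "sample_rate must be > 0")
    if (length(eye$x) != length(eye$y) || length(eye$x) != length(eye$pupil)) {
      add("eye", "eye", "lengths", "x, y, pupil lengths differ")
    }
    if (!is.null(tr) && length(eye$x)) {
      span <- eye$t0 + c(0, length(eye$x) / eye$sample_rate)
      bad <- which(tr$stimulus_onset < span[1] | tr$stimulus_onset > span[2])
      for (i in bad) add("eye", tr$trial_id[i], "onset_in_span",
                         "stimulus_onset outside the eye-trace span")
    }
  }
  ch <- session$channels
  if (!is.null(ch)) {
    if (ch$sample_rate < 10000) {
      add("channels", "channels", "sample_rate_emua",
          "sample_rate must be >= 10 kHz for the 500-5000 Hz eMUA band")
    }
    if (!is.null(tr) && ncol(ch$samples)) {
      span <- ch$t0 + c(0, ncol(ch$samples) / ch$sample_rate)
      bad <- which(tr$stimulus_onset < span[1] | tr$stimulus_onset > span[2])
      for (i in bad) add("channels", tr$trial_id[i], "onset_in_span",
                         "stimulus_onset outside the voltage-recording span")
    }
  }
  if (!length(out)) {
    return(data.frame(component = character(), id = character(),
                      rule = character(), message = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
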