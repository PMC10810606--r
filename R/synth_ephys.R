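## Synthetic electrophysiology: trial tables for recorded sessions, spike
## trains with figure-ground rate modulation, multichannel envelope signals
## with injected artifacts, eye traces with labeled saccades, and sparse-noise
## receptive-field maps from a known 2D Gaussian.

#' Specification for a synthetic ephys session
#'
#' Spikes are drawn from an inhomogeneous Poisson process with rate
#' `baseline + visual_gain * v(t) + fgm_amplitude * m(t) * 1{figure}`, where
#' `v(t)` is a stereotyped visual-response kernel (difference of
#' exponentials peaking near 55 ms) and `m(t)` a ramp starting at
#' `fgm_onset`. Per-trial multiplicative gamma gain noise with coefficient of
#' variation `rate_noise_cv` produces the over-dispersion typical of
#' collicular spike counts.
#'
#' @param n_neurons number of neurons.
#' @param baseline_rate spontaneous rate, spikes/s.
#' @param visual_gain peak visual-response amplitude, spikes/s.
#' @param fgm_amplitude figure-minus-ground modulation amplitude, spikes/s.
#' @param fgm_onset modulation onset, seconds after stimulus onset.
#' @param fgm_duration duration of the modulation plateau, seconds.
#' @param fgm_amplitude_error optional modulation amplitude used on error
#'   trials (default `NULL`: same as `fgm_amplitude`); lets outcome-dependent
#'   discriminability be generated with known ground truth.
#' @param n_figure,n_ground trials per stimulus class (per task).
#' @param tasks character vector of task labels to generate.
#' @param hit_rate per-trial probability that the response is a hit.
#' @param miss_rate per-trial probability of a miss.
#' @param rate_noise_cv coefficient of variation of the per-trial gain.
#' @param rf_center,rf_sd receptive-field center/SD in degrees (carried as
#'   ground truth for placement code).
#' @param artifact_rate per-trial probability of an injected eMUA trial
#'   artifact (used by [gen_emua_channels()]).
#' @param saccade_rate per-trial probability of a labeled saccade (used by
#'   [gen_eye()]).
#' @param seed integer seed.
#' @return a list of class `ephys_gen_spec`.
#' @export
ephys_gen_spec <- function(n_neurons = 20L, baseline_rate = 5,
                           visual_gain = 15, fgm_amplitude = 5,
                           fgm_onset = 0.075, fgm_duration = 0.10,
                           fgm_amplitude_error = NULL,
                           n_figure = 30L, n_ground = 30L,
                           tasks = "orientation", hit_rate = 0.8,
                           miss_rate = 0, rate_noise_cv = 0.3,
                           rf_center = c(30, 15), rf_sd = c(8, 8),
                           artifact_rate = 0, saccade_rate = 0, seed = 1L) {
  stopifnot(baseline_rate >= 0, visual_gain >= 0, fgm_onset >= 0,
            n_figure >= 1L, n_ground >= 1L)
  structure(list(n_neurons = as.integer(n_neurons),
                 baseline_rate = baseline_rate, visual_gain = visual_gain,
                 fgm_amplitude = fgm_amplitude, fgm_onset = fgm_onset,
                 fgm_duration = fgm_duration,
                 fgm_amplitude_error = fgm_amplitude_error,
                 n_figure = as.integer(n_figure), n_ground = as.integer(n_ground),
                 tasks = tasks, hit_rate = hit_rate, miss_rate = miss_rate,
                 rate_noise_cv = rate_noise_cv, rf_center = rf_center,
                 rf_sd = rf_sd, artifact_rate = artifact_rate,
                 saccade_rate = saccade_rate, seed = as.integer(seed)),
            class = "ephys_gen_spec")
}

#' Generate the trial table of a synthetic recorded session
#'
#' @param spec an [ephys_gen_spec()].
#' @param spacing seconds between consecutive stimulus onsets.
#' @param mouse mouse id.
#' @return a trial table with the `stimulus` column filled
#'   (figure/ground relative to the recorded receptive field).
#' @export
gen_ephys_trials <- function(spec, spacing = 2, mouse = "m1") {
  stopifnot(inherits(spec, "ephys_gen_spec"))
  with_seed_if(spec$seed, {
    rows <- do.call(rbind, lapply(spec$tasks, function(task) {
      data.frame(task = task,
                 stimulus = rep(c("figure", "ground"),
                                c(spec$n_figure, spec$n_ground)),
                 stringsAsFactors = FALSE)
    }))
    n <- nrow(rows)
    rows <- rows[sample.int(n), , drop = FALSE]
    miss <- runif(n) < spec$miss_rate
    hit <- runif(n) < spec$hit_rate
    response <- ifelse(miss, "miss", ifelse(hit, "hit", "error"))
    # lick spout reaches the mouse 0.5 s after stimulus onset
    rt <- ifelse(miss, NA_real_, pmin(0.55 + rgamma(n, shape = 3, scale = 0.15), 1.99))
    # the figure is over the RF on "figure" trials: with the RF in the left
    # hemifield the figure side equals the stimulus class deterministically
    df <- data.frame(trial_id = seq_len(n), mouse = mouse, task = rows$task,
                     figure_side = ifelse(rows$stimulus == "figure", "left", "right"),
                     background_orientation = sample(c(0, 90), n, replace = TRUE),
                     stimulus_onset = 1 + (seq_len(n) - 1L) * spacing,
                     stimulus = rows$stimulus, response = response,
                     reaction_time = rt, stringsAsFactors = FALSE)
    as_trial_table(df)
  })
}

# visual-response kernel: difference of exponentials, unit peak near 55 ms
visual_kernel <- function(t, tau_rise = 0.030, tau_decay = 0.120) {
  v <- ifelse(t > 0, exp(-t / tau_decay) - exp(-t / tau_rise), 0)
  tpk <- log(tau_decay / tau_rise) * tau_rise * tau_decay / (tau_decay - tau_rise)
  v / (exp(-tpk / tau_decay) - exp(-tpk / tau_rise))
}

# modulation time course: ramp up over 30 ms from `onset`, plateau for
# `duration`, ramp down over 50 ms
fgm_kernel <- function(t, onset, duration, rise = 0.030, fall = 0.050) {
  up <- pmin(pmax((t - onset) / rise, 0), 1)
  down <- pmin(pmax(1 - (t - onset - rise - duration) / fall, 0), 1)
  up * down
}

#' Generate synthetic spike trains
#'
#' Inhomogeneous Poisson spikes per neuron and trial; figure trials carry an
#' additional modulation `fgm_amplitude * m(t)` (and error trials
#' `fgm_amplitude_error * m(t)` when that field is set). Ground-truth rate
#' functions are attached as attribute `"truth"`.
#'
#' @param spec an [ephys_gen_spec()].
#' @param trials trial table from [gen_ephys_trials()].
#' @param window per-trial simulation window, seconds relative to onset.
#' @param dt rate-grid resolution, seconds.
#' @return a list of [neuron_recording()] objects with attribute `"truth"`
#'   (time grid, `v`, `m`, per-class rate functions, spec).
#' @export
gen_spikes <- function(spec, trials, window = c(-0.3, 0.6), dt = 0.001) {
  stopifnot(inherits(spec, "ephys_gen_spec"))
  tg <- seq(window[1] + dt / 2, window[2] - dt / 2, by = dt)
  v <- visual_kernel(tg)
  m <- fgm_kernel(tg, spec$fgm_onset, spec$fgm_duration)
  amp_err <- spec$fgm_amplitude_error %||% spec$fgm_amplitude
  rate_of <- function(is_figure, amp) {
    spec$baseline_rate + spec$visual_gain * v + if (is_figure) amp * m else 0
  }
  groups <- list(
    fig_hit = list(sel = trials$stimulus == "figure" & trials$response != "error",
                   rate = rate_of(TRUE, spec$fgm_amplitude)),
    fig_err = list(sel = trials$stimulus == "figure" & trials$response == "error",
                   rate = rate_of(TRUE, amp_err)),
    gnd = list(sel = trials$stimulus == "ground", rate = rate_of(FALSE, 0)))
  cv <- spec$rate_noise_cv
  with_seed_if(spec$seed + 1L, {
    neurons <- lapply(seq_len(spec$n_neurons), function(i) {
      st <- numeric(0)
      for (g in groups) {
        idx <- which(g$sel)
        if (!length(idx)) next
        lam <- g$rate
        big_lam <- sum(lam) * dt
        gain <- if (cv > 0) rgamma(length(idx), shape = 1 / cv^2, scale = cv^2) else rep(1, length(idx))
        counts <- rpois(length(idx), big_lam * gain)
        tot <- sum(counts)
        if (tot) {
          gi <- sample.int(length(tg), tot, replace = TRUE, prob = lam)
          times <- tg[gi] + runif(tot, -dt / 2, dt / 2) +
            rep(trials$stimulus_onset[idx], counts)
          st <- c(st, times)
        }
      }
      neuron_recording(sprintf("n%03d", i), sort(st), channel = i)
    })
    attr(neurons, "truth") <- list(time = tg, v = v, m = m,
                                   rate_figure = rate_of(TRUE, spec$fgm_amplitude),
                                   rate_figure_error = rate_of(TRUE, amp_err),
                                   rate_ground = rate_of(FALSE, 0),
                                   spec = spec)
    neurons
  })
}

#' Ground-truth modulation crossing time
#'
#' The time at which the noiseless figure-minus-ground rate difference of a
#' generated population -- smoothed with the same Gaussian kernel the
#' analysis applies to spike trains -- first reaches `criterion` of its
#' maximum. This is the value the modulation-latency estimator targets by
#' construction.
#'
#' @param truth the `"truth"` attribute of [gen_spikes()] output.
#' @param smooth_sd analysis smoothing SD, seconds (default 0.010).
#' @param criterion fraction of the maximum (default 0.33).
#' @return crossing time in seconds.
#' @export
truth_fgm_crossing <- function(truth, smooth_sd = 0.010, criterion = 0.33) {
  d <- truth$rate_figure - truth$rate_ground
  dt <- diff(truth$time[1:2])
  k <- gauss_kernel(smooth_sd, dt)
  pad <- (length(k) - 1L) %/% 2L
  sm <- convolve(d, rev(k), type = "open")[(pad + 1L):(pad + length(d))] * dt
  truth$time[min(which(sm >= criterion * max(sm)))]
}

#' Generate multichannel voltage with injected artifacts
#'
#' Per-channel Gaussian broadband noise; injected artifacts are either brief
#' large simultaneous excursions across a configurable majority of channels
#' (sample artifacts) or a sustained amplitude increase across a whole trial
#' (trial artifacts, emulating muscle noise). Truth labels identify both.
#'
#' @param n_channels number of channels (probe order, 25 um spacing).
#' @param trials trial table giving stimulus onsets.
#' @param sample_rate sampling rate, Hz (>= 10 kHz so the 500--5000 Hz band
#'   is defined).
#' @param trial_window per-trial analysis window, seconds relative to onset.
#' @param sample_artifact_rate per-trial probability of one injected sample
#'   artifact.
#' @param trial_artifact_rate per-trial probability of a sustained trial
#'   artifact.
#' @param sample_amp amplitude of sample artifacts, in noise SDs.
#' @param trial_gain noise-amplitude multiplier on artifact trials.
#' @param artifact_channels number of channels carrying each sample artifact
#'   (default all).
#' @param seed integer seed.
#' @return list with `channels` (a [channel_data()]), `truth`
#'   (`sample_artifacts`: data.frame trial/sample-in-window;
#'   `trial_artifacts`: trial ids), and `trial_window`.
#' @export
gen_emua_channels <- function(n_channels = 8L, trials,
                              sample_rate = 12000,
                              trial_window = c(0, 0.25),
                              sample_artifact_rate = 0,
                              trial_artifact_rate = 0,
                              sample_amp = 10, trial_gain = 3,
                              artifact_channels = n_channels,
                              seed = 1L) {
  stopifnot(sample_rate >= 10000)
  n_tr <- nrow(trials)
  onsets <- trials$stimulus_onset
  dur <- max(onsets) + trial_window[2] + 0.05
  ns <- ceiling(dur * sample_rate)
  wlen <- round(diff(trial_window) * sample_rate)
  with_seed_if(seed, {
    x <- matrix(rnorm(n_channels * ns), n_channels, ns)
    trial_art <- which(runif(n_tr) < trial_artifact_rate)
    samp_art_tr <- which(runif(n_tr) < sample_artifact_rate)
    start_idx <- round((onsets + trial_window[1]) * sample_rate) + 1L
    for (j in trial_art) {
      cols <- start_idx[j]:(start_idx[j] + wlen - 1L)
      x[, cols] <- x[, cols] * trial_gain
    }
    samp_art <- data.frame(trial = integer(0), sample = integer(0))
    for (j in samp_art_tr) {
      s <- sample.int(wlen - 10L, 1L) + 5L
      cols <- start_idx[j] + s - 1L + (0:2)
      ch <- sample.int(n_channels, min(artifact_channels, n_channels))
      x[ch, cols] <- x[ch, cols] + sample_amp * sample(c(-1, 1), 1L)
      samp_art <- rbind(samp_art, data.frame(trial = trials$trial_id[j], sample = s))
    }
    list(channels = channel_data(x, sample_rate = sample_rate, t0 = 0),
         truth = list(sample_artifacts = samp_art,
                      trial_artifacts = trials$trial_id[trial_art]),
         trial_window = trial_window)
  })
}

#' Generate an eye trace with labeled saccade trials
#'
#' Slow drift plus, on labeled trials, a step-like saccade of
#' `amplitude_deg` within 0--450 ms after stimulus onset.
#'
#' @param trials trial table.
#' @param saccade_rate per-trial probability of a saccade.
#' @param amplitude_deg saccade amplitude in degrees.
#' @param sample_rate eye-tracker sampling rate, Hz.
#' @param drift_sd SD of the per-sample drift increment, degrees.
#' @param seed integer seed.
#' @return list with `eye` (an [eye_trace()]) and `truth` (saccade trial
#'   ids).
#' @export
gen_eye <- function(trials, saccade_rate = 0.1, amplitude_deg = 10,
                    sample_rate = 500, drift_sd = 0.01, seed = 1L) {
  onsets <- trials$stimulus_onset
  dur <- max(onsets) + 1
  ns <- ceiling(dur * sample_rate)
  tt <- (seq_len(ns) - 1) / sample_rate
  with_seed_if(seed, {
    x <- moving_average(cumsum(rnorm(ns, 0, drift_sd)), round(0.05 * sample_rate))
    y <- moving_average(cumsum(rnorm(ns, 0, drift_sd)), round(0.05 * sample_rate))
    sacc <- which(runif(nrow(trials)) < saccade_rate)
    for (j in sacc) {
      t_s <- onsets[j] + runif(1, 0.05, 0.40)
      dir <- runif(1, 0, 2 * pi)
      step <- amplitude_deg * plogis((tt - t_s) / 0.004)
      x <- x + cos(dir) * step
      y <- y + sin(dir) * step
    }
    pupil <- 1 + 0.05 * sin(2 * pi * 0.1 * tt) + rnorm(ns, 0, 0.01)
    list(eye = eye_trace(x, y, pupil, sample_rate = sample_rate, t0 = 0),
         truth = list(saccade_trials = trials$trial_id[sacc]))
  })
}

#' Generate a sparse-noise receptive-field mapping log
#'
#' Checkers of `checker_deg` degrees appear at random grid positions; the
#' evoked response per presentation is drawn around a 2D Gaussian tuning
#' surface with known center and width. With `noise_sd = 0` the per-event
#' responses equal the Gaussian surface exactly.
#'
#' @param true_center c(azimuth, elevation), degrees.
#' @param true_sd c(sd_x, sd_y), degrees.
#' @param n_reps presentations per grid position and polarity.
#' @param noise_sd SD of additive Gaussian response noise (spikes per
#'   event).
#' @param grid_x,grid_y checker-center grids, degrees.
#' @param peak_resp peak evoked response above baseline, spikes per event.
#' @param base_resp baseline response, spikes per event.
#' @param polarity `"ON"`, `"OFF"`, or `"both"`: which polarity drives the
#'   neuron.
#' @param window response window relative to checker onset, seconds.
#' @param checker_deg checker size in degrees (metadata only).
#' @param seed integer seed.
#' @return list with `events` (data.frame onset/x/y/polarity/count/
#'   baseline_count), `window`, `baseline_window`, and `truth`.
#' @export
gen_rf_map <- function(true_center = c(30, 15), true_sd = c(8, 8),
                       n_reps = 10L, noise_sd = 0,
                       grid_x = seq(0, 60, by = 5), grid_y = seq(-10, 40, by = 5),
                       peak_resp = 10, base_resp = 1, polarity = "ON",
                       window = c(0.04, 0.30), checker_deg = 5, seed = 1L) {
  stopifnot(true_center[1] >= min(grid_x), true_center[1] <= max(grid_x),
            true_center[2] >= min(grid_y), true_center[2] <= max(grid_y))
  grid <- expand.grid(x = grid_x, y = grid_y)
  pols <- c("ON", "OFF")
  with_seed_if(seed, {
    ev <- do.call(rbind, lapply(pols, function(p) {
      g <- grid[rep(seq_len(nrow(grid)), n_reps), ]
      g$polarity <- p
      g
    }))
    ev <- ev[sample.int(nrow(ev)), ]
    ev$onset <- seq_len(nrow(ev)) * 1.0
    surface <- peak_resp * exp(-((ev$x - true_center[1])^2 / (2 * true_sd[1]^2) +
                                   (ev$y - true_center[2])^2 / (2 * true_sd[2]^2)))
    drives <- if (polarity == "both") c("ON", "OFF") else polarity
    mu <- base_resp + ifelse(ev$polarity %in% drives, surface, 0)
    ev$count <- mu + if (noise_sd > 0) rnorm(nrow(ev), 0, noise_sd) else 0
    ev$baseline_count <- base_resp * (0.05 / diff(window)) *
      (1 + if (noise_sd > 0) rnorm(nrow(ev), 0, noise_sd / base_resp / 4) else 0)
    rownames(ev) <- NULL
    list(events = ev[, c("onset", "x", "y", "polarity", "count", "baseline_count")],
         window = window, baseline_window = c(-0.05, 0),
         truth = list(center = true_center, sd = true_sd,
                      peak_resp = peak_resp, base_resp = base_resp,
                      polarity = polarity))
  })
}
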