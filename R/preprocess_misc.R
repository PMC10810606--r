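## Spike-rate estimation, eye-movement trial exclusion, common-average
## referencing, and CSD-referenced depth assignment.

gauss_kernel <- function(sd, dt, half_width = 5) {
  pad <- ceiling(half_width * sd / dt)
  k <- dnorm(seq(-pad, pad) * dt, 0, sd)
  k / (sum(k) * dt)   # unit integral so smoothing conserves spike count
}

#' Smooth spike trains into continuous rate estimates
#'
#' Convolves each trial's spike train with a Gaussian kernel (SD
#' `sd`, default 10 ms) on a `dt` grid. The kernel is normalised to unit
#' integral, so the integral of the rate trace over a trial equals the spike
#' count in that trial (for spikes away from the window edges).
#'
#' @param recording a [neuron_recording()].
#' @param trials trial table (stimulus onsets on the session clock).
#' @param sd kernel SD, seconds.
#' @param window per-trial window, seconds relative to stimulus onset.
#' @param dt grid resolution, seconds.
#' @return list with `time` (bin centers, seconds relative to onset) and
#'   `rates` (`[trials, time]`, spikes/s).
#' @export
smooth_spikes <- function(recording, trials, sd = 0.010,
                          window = c(-0.3, 0.6), dt = 0.001) {
  st <- recording$spike_times
  onsets <- trials$stimulus_onset
  k <- gauss_kernel(sd, dt)
  pad <- (length(k) - 1L) %/% 2L
  nb <- round(diff(window) / dt)
  nbp <- nb + 2L * pad
  lo <- window[1] - pad * dt
  rates <- matrix(0, length(onsets), nb)
  for (j in seq_along(onsets)) {
    rel <- st[st >= onsets[j] + lo & st < onsets[j] + lo + nbp * dt] - onsets[j]
    if (!length(rel)) next
    counts <- tabulate(floor((rel - lo) / dt) + 1L, nbins = nbp)
    sm <- convolve(counts, rev(k), type = "open")
    rates[j, ] <- sm[(2L * pad + 1L):(2L * pad + nb)]
  }
  list(time = window[1] + (seq_len(nb) - 0.5) * dt, rates = rates)
}

#' Trial-averaged smoothed rate (PSTH) for a subset of trials
#'
#' Pools the binned spike counts of the selected trials before a single
#' kernel convolution, which by linearity equals the mean of the per-trial
#' [smooth_spikes()] traces.
#'
#' @param recording a [neuron_recording()].
#' @param trials trial table.
#' @param sel logical selector over trials (default all).
#' @param sd,window,dt as in [smooth_spikes()].
#' @return list with `time` and `rate` (spikes/s).
#' @export
condition_psth <- function(recording, trials, sel = rep(TRUE, nrow(trials)),
                           sd = 0.010, window = c(-0.3, 0.6), dt = 0.001) {
  onsets <- trials$stimulus_onset[sel]
  k <- gauss_kernel(sd, dt)
  pad <- (length(k) - 1L) %/% 2L
  nb <- round(diff(window) / dt)
  nbp <- nb + 2L * pad
  lo <- window[1] - pad * dt
  counts <- numeric(nbp)
  st <- recording$spike_times
  for (on in onsets) {
    rel <- st[st >= on + lo & st < on + lo + nbp * dt] - on
    if (length(rel)) counts <- counts + tabulate(floor((rel - lo) / dt) + 1L, nbins = nbp)
  }
  sm <- convolve(counts / max(length(onsets), 1L), rev(k), type = "open")
  list(time = window[1] + (seq_len(nb) - 0.5) * dt,
       rate = sm[(2L * pad + 1L):(2L * pad + nb)])
}

#' Per-trial spike rates in a fixed window
#'
#' Spike counts per trial in `[window[1], window[2])` relative to stimulus
#' onset, expressed as rates in spikes/s.
#'
#' @param neurons list of [neuron_recording()].
#' @param trials trial table.
#' @param window window in seconds relative to stimulus onset.
#' @return numeric matrix, neurons x trials.
#' @export
window_rates <- function(neurons, trials, window) {
  onsets <- trials$stimulus_onset
  w <- diff(window)
  out <- matrix(0, length(neurons), nrow(trials))
  for (i in seq_along(neurons)) {
    st <- neurons[[i]]$spike_times
    lo <- findInterval(onsets + window[1] - 1e-12, st)
    hi <- findInterval(onsets + window[2] - 1e-12, st)
    out[i, ] <- (hi - lo) / w
  }
  rownames(out) <- vapply(neurons, `[[`, character(1), "neuron_id")
  out
}

#' Exclude trials with eye movements
#'
#' Per trial, the eye speed is the mean (or max) instantaneous speed in the
#' window 0--450 ms after stimulus onset, computed by finite differences
#' after a 20 ms moving-average denoising. Trials whose speed exceeds the
#' across-trial mean + `nsd` SD are flagged `eye_movement`; trials whose
#' window is not covered by the trace are flagged `other`.
#'
#' @param eye an [eye_trace()].
#' @param trials trial table.
#' @param window window relative to stimulus onset, seconds.
#' @param nsd threshold in across-trial SDs (default 2.5).
#' @param stat `"mean"` (default) or `"max"` speed within the window.
#' @param smooth_s moving-average length for denoising, seconds.
#' @return list with `kept`, `excluded` (trial ids), per-trial `speeds`
#'   (deg/s), `threshold`, and the updated `trials` table.
#' @export
exclude_eye_trials <- function(eye, trials, window = c(0, 0.450), nsd = 2.5,
                               stat = c("mean", "max"), smooth_s = 0.020) {
  stat <- match.arg(stat)
  fs <- eye$sample_rate
  k <- max(1L, round(smooth_s * fs))
  xs <- moving_average(eye$x, k)
  ys <- moving_average(eye$y, k)
  n <- length(xs)
  speeds <- rep(NA_real_, nrow(trials))
  gap <- logical(nrow(trials))
  for (j in seq_len(nrow(trials))) {
    i0 <- floor((trials$stimulus_onset[j] + window[1] - eye$t0) * fs) + 1L
    i1 <- ceiling((trials$stimulus_onset[j] + window[2] - eye$t0) * fs)
    if (i0 < 1L || i1 > n || i1 - i0 < 2L) { gap[j] <- TRUE; next }
    sp <- sqrt(diff(xs[i0:i1])^2 + diff(ys[i0:i1])^2) * fs
    speeds[j] <- if (stat == "mean") mean(sp) else max(sp)
  }
  mu <- mean(speeds, na.rm = TRUE)
  sdv <- stats::sd(speeds, na.rm = TRUE)
  thr <- mu + nsd * sdv
  out <- !gap & !is.na(speeds) & speeds > thr
  trials$excluded[out] <- TRUE
  trials$exclusion_reason[out] <- "eye_movement"
  trials$excluded[gap] <- TRUE
  trials$exclusion_reason[gap] <- "other"
  list(kept = trials$trial_id[!out & !gap],
       excluded = trials$trial_id[out],
       gap = trials$trial_id[gap],
       speeds = speeds, threshold = thr, trials = trials)
}

#' Subtract the common average across channels
#'
#' @param raw a [channel_data()] with at least 2 channels.
#' @return a [channel_data()] whose per-sample mean across channels is 0.
#' @export
common_average_reference <- function(raw) {
  if (nrow(raw$samples) < 2L) stop("need at least 2 channels")
  ref <- colMeans(raw$samples)
  channel_data(sweep(raw$samples, 2, ref), sample_rate = raw$sample_rate,
               channel_spacing = raw$channel_spacing, t0 = raw$t0)
}

#' Assign recording depths from the current-source-density sink
#'
#' Low-pass filters the voltage to the LFP band, removes 50 Hz line noise
#' with a band-stop filter, averages the stimulus-locked LFP over trials,
#' and computes the CSD as the (negated curvature) second spatial difference
#' across channels. The channel with the lowest CSD value in the
#' visual-response window is the reference sink, placed `surface_offset`
#' micrometers below the collicular surface; other channels follow at the
#' probe spacing.
#'
#' @param lfp a [channel_data()] (raw or already low-passed voltage).
#' @param trials trial table.
#' @param surface_offset depth of the sink channel, micrometers (default
#'   119).
#' @param response_window window for the sink search, seconds relative to
#'   stimulus onset.
#' @param lp_cutoff LFP low-pass cutoff, Hz.
#' @param notch logical; apply the 50 Hz band-stop filter.
#' @return a `depth_map`: list with `csd` (`[channels, samples]`, interior
#'   channels only padded with `NA` at the probe edges), `sink_channel`,
#'   `depth_per_channel` (micrometers from the surface), and `flagged`
#'   (`TRUE` when the sink is unreliable: on the probe edge or no sink).
#' @export
assign_depths <- function(lfp, trials, surface_offset = 119,
                          response_window = c(0.02, 0.15),
                          lp_cutoff = 100, notch = TRUE) {
  nch <- nrow(lfp$samples)
  if (nch < 5L) stop("need at least 5 channels for a CSD")
  fs <- lfp$sample_rate
  x <- lfp$samples
  if (lp_cutoff < fs / 2) {
    lp <- signal::butter(4, lp_cutoff / (fs / 2), type = "low")
    x <- t(apply(x, 1, function(ch) signal::filtfilt(lp, ch)))
  }
  if (notch && fs / 2 > 51) {
    bs <- signal::butter(2, c(49, 51) / (fs / 2), type = "stop")
    x <- t(apply(x, 1, function(ch) signal::filtfilt(bs, ch)))
  }
  ep <- epoch_channels(channel_data(x, fs, lfp$channel_spacing, lfp$t0),
                       trials, response_window)
  avg <- rowMeans(ep, dims = 2)               # channels x samples
  h <- lfp$channel_spacing
  csd <- matrix(NA_real_, nch, ncol(avg))
  for (c in 2:(nch - 1L)) {
    csd[c, ] <- (2 * avg[c, ] - avg[c - 1L, ] - avg[c + 1L, ]) / h^2
  }
  interior <- csd[2:(nch - 1L), , drop = FALSE]
  flagged <- FALSE
  if (diff(range(interior)) < 1e-9) {
    flagged <- TRUE
    sink <- NA_integer_
    depths <- rep(NA_real_, nch)
  } else {
    idx <- which(interior == min(interior), arr.ind = TRUE)[1, ]
    sink <- as.integer(idx[1]) + 1L
    if (sink == 2L || sink == nch - 1L) flagged <- TRUE
    depths <- surface_offset + (seq_len(nch) - sink) * h
  }
  structure(list(csd = csd, sink_channel = sink,
                 depth_per_channel = depths, flagged = flagged),
            class = "depth_map")
}
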