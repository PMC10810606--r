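## Envelope multi-unit activity (eMUA) artifact rejection.
##
## The raw voltage is band-pass filtered 500-5000 Hz, half-wave rectified and
## low-pass filtered at 200 Hz to produce a per-channel envelope. Each
## channel's envelope is z-scored over all trials and time points and the
## absolute value taken (zmua); the geometric mean across channels gives the
## consensus statistic Z, which only reaches extreme values when a majority
## of channels excurse together. Samples with Z > 3 are removed from all
## channels with +/-3 samples of padding, Z is recomputed, the per-trial
## statistic chi = (mean_i Z_ij)^2 is fitted with a Gaussian by nonlinear
## least squares, and trials beyond 3 sigma are removed.

#' Compute the envelope multi-unit activity (eMUA)
#'
#' Band-pass filters each channel between `band` Hz (zero-phase 4th-order
#' Butterworth), half-wave rectifies (negative parts set to zero), and
#' low-pass filters at `lowpass` Hz.
#'
#' @param raw a [channel_data()] with `sample_rate >= 10000`.
#' @param band band-pass edges, Hz.
#' @param lowpass envelope low-pass cutoff, Hz.
#' @return a [channel_data()] holding the per-channel envelope.
#' @export
compute_emua <- function(raw, band = c(500, 5000), lowpass = 200) {
  fs <- raw$sample_rate
  if (fs < 2 * band[2]) {
    stop("sample_rate ", fs, " too low: band-pass upper edge ", band[2],
         " Hz must be below Nyquist")
  }
  bp <- signal::butter(2, band / (fs / 2), type = "pass")
  lp <- signal::butter(4, lowpass / (fs / 2), type = "low")
  env <- t(apply(raw$samples, 1, function(ch) {
    e <- pmax(signal::filtfilt(bp, ch), 0)
    signal::filtfilt(lp, e)
  }))
  channel_data(env, sample_rate = fs, channel_spacing = raw$channel_spacing,
               t0 = raw$t0)
}

#' Epoch continuous channel data into per-trial segments
#'
#' @param x a [channel_data()].
#' @param trials trial table (stimulus onsets on the session clock).
#' @param window window in seconds relative to stimulus onset.
#' @return numeric array `[channels, samples, trials]`.
#' @export
epoch_channels <- function(x, trials, window) {
  fs <- x$sample_rate
  wlen <- round(diff(window) * fs)
  start <- round((trials$stimulus_onset + window[1] - x$t0) * fs) + 1L
  if (any(start < 1L) || any(start + wlen - 1L > ncol(x$samples))) {
    stop("trial window extends beyond the recorded span")
  }
  nch <- nrow(x$samples)
  out <- array(0, c(nch, wlen, nrow(trials)))
  for (j in seq_len(nrow(trials))) {
    out[, , j] <- x$samples[, start[j]:(start[j] + wlen - 1L)]
  }
  out
}

# |z| per channel over all trials and time points; optional logical mask of
# already-removed samples (same dim as [samples, trials]) excluded from the
# mean/SD and set to NA in the output
zmua_stats <- function(epochs, mask = NULL) {
  nch <- dim(epochs)[1]
  z <- epochs
  for (c in seq_len(nch)) {
    v <- epochs[c, , ]
    if (!is.null(mask)) v[mask] <- NA
    s <- stats::sd(v, na.rm = TRUE)
    if (!is.finite(s) || s == 0) {
      stop("channel ", c, " has zero variance; cannot z-score")
    }
    z[c, , ] <- abs((epochs[c, , ] - mean(v, na.rm = TRUE)) / s)
    if (!is.null(mask)) z[c, , ][mask] <- NA
  }
  z
}

# geometric mean across channels (dimension 1) with epsilon guard
geomean_channels <- function(zmua, eps = 1e-12) {
  lg <- log(zmua + eps)
  exp(colMeans(lg, dims = 1))
}

#' Identify and mask artifact samples from the eMUA consensus statistic
#'
#' Computes `zmua` (per-channel |z| over all trials and time points), the
#' geometric mean `Z` across channels, masks samples with `Z > threshold`
#' together with `pad` preceding and following samples on all channels, and
#' recomputes `Z` on the masked data.
#'
#' @param epochs envelope epochs `[channels, samples, trials]` from
#'   [epoch_channels()] applied to [compute_emua()] output.
#' @param threshold consensus threshold on `Z` (default 3).
#' @param pad samples of padding on each side of a flagged sample.
#' @return list with `mask` (`[samples, trials]` logical), `Z` (recomputed,
#'   `NA` at masked samples), `Z_pre` (before masking), and `n_removed`.
#' @export
reject_artifact_samples <- function(epochs, threshold = 3, pad = 3L) {
  if (dim(epochs)[1] < 2L) stop("need at least 2 channels")
  z0 <- zmua_stats(epochs)
  Z0 <- geomean_channels(z0)
  mask <- Z0 > threshold
  if (any(mask) && pad > 0L) {
    ns <- nrow(mask)
    for (j in seq_len(ncol(mask))) {
      idx <- which(mask[, j])
      if (length(idx)) {
        ext <- unique(pmin(pmax(rep(idx, each = 2L * pad + 1L) +
                                  (-pad):pad, 1L), ns))
        mask[ext, j] <- TRUE
      }
    }
  }
  z1 <- if (any(mask)) zmua_stats(epochs, mask) else z0
  Z1 <- geomean_channels(z1)
  if (any(mask)) Z1[mask] <- NA
  list(mask = mask, Z = Z1, Z_pre = Z0, n_removed = sum(mask))
}

#' Identify and remove artifact trials from the per-trial chi statistic
#'
#' `chi_j = (mean_i Z_ij)^2` per trial; the chi distribution is fitted with
#' a Gaussian by nonlinear least squares on a Freedman-Diaconis histogram,
#' and trials with `|chi - mu| > nsigma * sigma` are removed.
#'
#' @param Z recomputed consensus statistic `[samples, trials]` (from
#'   [reject_artifact_samples()]); `NA` entries are ignored.
#' @param trials trial table aligned with the columns of `Z`.
#' @param nsigma removal threshold in fitted SDs (default 3).
#' @param min_trials minimum number of trials for a stable fit.
#' @return list with `kept` and `removed` (trial ids), `chi`, `mu`, `sigma`,
#'   and the updated `trials` table with `excluded`/`exclusion_reason` set.
#' @export
reject_artifact_trials <- function(Z, trials, nsigma = 3, min_trials = 20L) {
  if (ncol(Z) != nrow(trials)) stop("Z columns must align with trials")
  if (nrow(trials) < min_trials) {
    stop("need at least ", min_trials, " trials to fit the chi distribution")
  }
  chi <- suppressWarnings(colMeans(Z, na.rm = TRUE)^2)
  # a trial whose samples were all masked is artifactual by construction
  all_masked <- !is.finite(chi)
  if (stats::sd(chi[!all_masked]) < 1e-10) {
    stop("degenerate chi distribution (sd ~ 0); cannot fit a Gaussian")
  }
  h <- graphics::hist(chi[!all_masked], breaks = "FD", plot = FALSE)
  fit <- tryCatch(
    minpack.lm::nlsLM(counts ~ a * exp(-(mids - mu)^2 / (2 * s^2)),
                      data = data.frame(mids = h$mids, counts = h$counts),
                      start = list(a = max(h$counts), mu = stats::median(chi[!all_masked]),
                                   s = max(stats::mad(chi[!all_masked]),
                                           diff(h$mids[1:2]))),
                      lower = c(a = 0, mu = -Inf, s = 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) stop("Gaussian fit to the chi distribution failed")
  p <- coef(fit)
  if (p["s"] <= 0) stop("degenerate Gaussian fit (sigma <= 0)")
  out <- all_masked | abs(chi - p["mu"]) > nsigma * p["s"]
  trials$excluded[out] <- TRUE
  trials$exclusion_reason[out] <- "emua_artifact"
  list(kept = trials$trial_id[!out], removed = trials$trial_id[out],
       chi = chi, mu = unname(p["mu"]), sigma = unname(p["s"]),
       trials = trials)
}
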