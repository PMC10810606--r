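#' Analysis configuration
#'
#' Bundles every threshold and analysis window used by the pipeline, with
#' defaults matching the experimental conventions of the figure-detection
#' study design: a 150 ms pre-stimulus baseline, a 50--200 ms peak/visual
#' window with a 3 spikes/s evoked-rate inclusion criterion, a 0--450 ms eye
#' window with a 2.5 SD speed threshold, 10 ms spike smoothing, and the
#' bootstrap/permutation counts of the statistical procedures. All randomised
#' operations draw their seed from here (or from an explicit `seed` argument);
#' there is no implicit global randomness.
#'
#' @param baseline_window baseline window in seconds relative to stimulus
#'   onset, default `c(-0.15, 0)`.
#' @param peak_window window used for the normalisation maximum, seconds,
#'   default `c(0.05, 0.20)`.
#' @param visual_window window for the visual-responsiveness criterion,
#'   seconds, default `c(0.05, 0.20)`.
#' @param visual_threshold minimum baseline-subtracted evoked rate (spikes/s)
#'   for a neuron to count as visual, default 3.
#' @param eye_window window for eye-speed trial exclusion, seconds, default
#'   `c(0, 0.450)`.
#' @param eye_nsd eye-speed threshold in across-trial SDs above the mean,
#'   default 2.5.
#' @param smooth_sd SD of the Gaussian spike-smoothing kernel, seconds,
#'   default 0.010.
#' @param cluster_alpha per-bin alpha for cluster formation, default 0.05.
#' @param n_perm permutations for the cluster test, default 1000.
#' @param n_boot_decode decoder bootstrap repetitions, default 2000.
#' @param n_shuffle_dprime trial-identity shuffles for the d-prime null,
#'   default 1000.
#' @param emua_threshold sample-artifact threshold on the geometric-mean
#'   statistic, default 3.
#' @param emua_pad samples of padding removed around each artifact sample,
#'   default 3.
#' @param decode_window_width,decode_window_step sliding decoding window
#'   width and step, seconds, defaults 0.050 and 0.010.
#' @param seed integer seed used by randomised operations when no explicit
#'   seed is passed.
#' @return an object of class `fg_config` (a named list).
#' @export
analysis_config <- function(baseline_window = c(-0.15, 0),
                            peak_window = c(0.05, 0.20),
                            visual_window = c(0.05, 0.20),
                            visual_threshold = 3,
                            eye_window = c(0, 0.450),
                            eye_nsd = 2.5,
                            smooth_sd = 0.010,
                            cluster_alpha = 0.05,
                            n_perm = 1000L,
                            n_boot_decode = 2000L,
                            n_shuffle_dprime = 1000L,
                            emua_threshold = 3,
                            emua_pad = 3L,
                            decode_window_width = 0.050,
                            decode_window_step = 0.010,
                            seed = 1L) {
  cfg <- list(baseline_window = as.numeric(baseline_window),
              peak_window = as.numeric(peak_window),
              visual_window = as.numeric(visual_window),
              visual_threshold = as.numeric(visual_threshold),
              eye_window = as.numeric(eye_window),
              eye_nsd = as.numeric(eye_nsd),
              smooth_sd = as.numeric(smooth_sd),
              cluster_alpha = as.numeric(cluster_alpha),
              n_perm = as.integer(n_perm),
              n_boot_decode = as.integer(n_boot_decode),
              n_shuffle_dprime = as.integer(n_shuffle_dprime),
              emua_threshold = as.numeric(emua_threshold),
              emua_pad = as.integer(emua_pad),
              decode_window_width = as.numeric(decode_window_width),
              decode_window_step = as.numeric(decode_window_step),
              seed = as.integer(seed))
  for (w in c("baseline_window", "peak_window", "visual_window", "eye_window")) {
    if (length(cfg[[w]]) != 2L || cfg[[w]][1] >= cfg[[w]][2]) {
      stop("config window '", w, "' must satisfy start < end")
    }
  }
  if (cfg$cluster_alpha <= 0 || cfg$cluster_alpha >= 1) {
    stop("cluster_alpha must lie in (0, 1)")
  }
  if (is.na(cfg$seed)) stop("seed must be an explicit integer")
  structure(cfg, class = "fg_config")
}

#' @export
print.fg_config <- function(x, ...) {
  cat("<fg_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-20s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}
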