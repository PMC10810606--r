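## Receptive-field estimation from sparse-noise responses: evoked-response
## maps, 2D Gaussian fits, the bootstrapped variability index (BVI), and
## classification of the RF relative to the task figure.

#' Evoked-response map from a sparse-noise event log
#'
#' Averages the evoked response per checker position (ON and OFF
#' separately): the mean rate in the response window minus the pre-event
#' baseline rate. Event logs may carry pre-computed window counts (columns
#' `count`/`baseline_count`, as written by [gen_rf_map()]); otherwise a
#' spike-time recording is counted in a per-neuron window. The window is
#' constrained to 40--300 ms after checker onset; when `window` is `NULL`
#' and spikes are supplied, the contiguous 100 ms sub-window (stepped by
#' 20 ms) maximising the absolute evoked response is chosen automatically.
#'
#' @param rf_map an RF mapping log: list with `events` (data.frame
#'   onset/x/y/polarity and optionally count/baseline_count), `window`,
#'   `baseline_window` -- or a bare events data.frame.
#' @param recording optional [neuron_recording()] used when the log has no
#'   counts.
#' @param window response window override, seconds in `[0.04, 0.30]`.
#' @return object of class `rf_map`: data.frame `grid` with `x`, `y`,
#'   `on`, `off` (evoked rates; `NA` where a position was never shown),
#'   `n_on`, `n_off`, plus the `window` used.
#' @export
rf_response_map <- function(rf_map, recording = NULL, window = NULL) {
  if (is.data.frame(rf_map)) rf_map <- list(events = rf_map)
  ev <- rf_map$events
  baseline_window <- rf_map$baseline_window %||% c(-0.05, 0)
  if (!is.null(ev$count)) {
    win <- window %||% rf_map$window %||% c(0.04, 0.30)
    resp <- ev$count / diff(win)
    base <- ev$baseline_count / abs(diff(baseline_window))
  } else {
    if (is.null(recording)) stop("event log has no counts; supply a recording")
    win <- window %||% pick_rf_window(recording, ev)
    st <- recording$spike_times
    lo <- findInterval(ev$onset + win[1] - 1e-12, st)
    hi <- findInterval(ev$onset + win[2] - 1e-12, st)
    resp <- (hi - lo) / diff(win)
    lo <- findInterval(ev$onset + baseline_window[1] - 1e-12, st)
    hi <- findInterval(ev$onset + baseline_window[2] - 1e-12, st)
    base <- (hi - lo) / diff(baseline_window)
  }
  evoked <- resp - base
  grid <- expand.grid(x = sort(unique(ev$x)), y = sort(unique(ev$y)))
  per_pos <- function(pol) {
    sel <- ev$polarity == pol
    key <- paste(ev$x, ev$y)
    means <- tapply(evoked[sel], key[sel], mean)
    counts <- tapply(evoked[sel], key[sel], length)
    gkey <- paste(grid$x, grid$y)
    list(mean = as.numeric(means[gkey]),
         n = as.integer(ifelse(is.na(counts[gkey]), 0L, counts[gkey])))
  }
  on <- per_pos("ON"); off <- per_pos("OFF")
  grid$on <- on$mean; grid$off <- off$mean
  grid$n_on <- on$n; grid$n_off <- off$n
  structure(list(grid = grid, window = win,
                 baseline_window = baseline_window),
            class = "rf_map")
}

# deterministic per-neuron response window: the 100 ms sub-window of
# [40, 300] ms (stepped by 20 ms) with the largest |evoked - baseline| rate
pick_rf_window <- function(recording, events, width = 0.100, step = 0.020,
                           bounds = c(0.04, 0.30)) {
  st <- recording$spike_times
  starts <- seq(bounds[1], bounds[2] - width, by = step)
  base_lo <- findInterval(events$onset - 0.05 - 1e-12, st)
  base_hi <- findInterval(events$onset - 1e-12, st)
  base <- mean(base_hi - base_lo) / 0.05
  scores <- vapply(starts, function(s) {
    lo <- findInterval(events$onset + s - 1e-12, st)
    hi <- findInterval(events$onset + s + width - 1e-12, st)
    abs(mean(hi - lo) / width - base)
  }, numeric(1))
  s <- starts[which.max(scores)]
  c(s, s + width)
}

gauss2d <- function(x, y, base, amp, cx, cy, sx, sy) {
  base + amp * exp(-((x - cx)^2 / (2 * sx^2) + (y - cy)^2 / (2 * sy^2)))
}

fit_gauss2d_one <- function(x, y, z) {
  ok <- is.finite(z)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  if (length(z) < 9L) return(NULL)
  i_pk <- which.max(abs(z - stats::median(z)))
  amp0 <- z[i_pk] - stats::median(z)
  dx <- min(diff(sort(unique(x)))); dy <- min(diff(sort(unique(y))))
  fit <- tryCatch(
    minpack.lm::nlsLM(z ~ gauss2d(x, y, base, amp, cx, cy, sx, sy),
                      data = data.frame(x = x, y = y, z = z),
                      start = list(base = stats::median(z), amp = amp0,
                                   cx = x[i_pk], cy = y[i_pk],
                                   sx = 2 * dx, sy = 2 * dy),
                      lower = c(base = -Inf, amp = -Inf, cx = min(x),
                                cy = min(y), sx = dx / 4, sy = dy / 4),
                      upper = c(base = Inf, amp = Inf, cx = max(x),
                                cy = max(y), sx = diff(range(x)),
                                sy = diff(range(y))),
                      control = minpack.lm::nls.lm.control(maxiter = 400)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  p <- coef(fit)
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((z - mean(z))^2)
  list(params = p, r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_)
}

#' Fit a 2D Gaussian receptive field
#'
#' Bounded nonlinear least squares of a 2D Gaussian to the evoked-response
#' map; ON and OFF maps are fitted separately and the more reliable fit
#' (higher r-squared) is retained as the RF estimate.
#'
#' @param map an `rf_map` from [rf_response_map()].
#' @param polarity force `"ON"` or `"OFF"` (default: pick the better fit).
#' @param min_r2 r-squared below which the fit is marked unreliable.
#' @return object of class `rf_fit`: list with `center` (azimuth,
#'   elevation), `sd` (sx, sy), `amplitude`, `baseline`, `polarity`, `r2`,
#'   `bvi` (`NA` until [bootstrap_bvi()]), `window`, `reliable`,
#'   `converged`.
#' @export
fit_rf_gaussian <- function(map, polarity = NULL, min_r2 = 0.25) {
  stopifnot(inherits(map, "rf_map"))
  g <- map$grid
  cands <- list()
  for (pol in (if (is.null(polarity)) c("ON", "OFF") else polarity)) {
    z <- if (pol == "ON") g$on else g$off
    f <- fit_gauss2d_one(g$x, g$y, z)
    if (!is.null(f)) cands[[pol]] <- f
  }
  if (!length(cands)) {
    return(structure(list(center = c(NA_real_, NA_real_), sd = c(NA_real_, NA_real_),
                          amplitude = NA_real_, baseline = NA_real_,
                          polarity = NA_character_, r2 = NA_real_,
                          bvi = NA_real_, window = map$window,
                          reliable = FALSE, converged = FALSE),
                     class = "rf_fit"))
  }
  r2s <- vapply(cands, `[[`, numeric(1), "r2")
  pol <- names(cands)[which.max(r2s)]
  p <- cands[[pol]]$params
  structure(list(center = unname(c(p["cx"], p["cy"])),
                 sd = unname(c(p["sx"], p["sy"])),
                 amplitude = unname(p["amp"]), baseline = unname(p["base"]),
                 polarity = pol, r2 = cands[[pol]]$r2, bvi = NA_real_,
                 window = map$window,
                 reliable = cands[[pol]]$r2 >= min_r2, converged = TRUE),
            class = "rf_fit")
}

#' Bootstrapped variability index (BVI) of an RF fit
#'
#' Resamples the mapping events with replacement (same number as
#' recorded), refits the Gaussian each time, and returns the ratio of the
#' bootstrap SD of the fitted center to the SD (width) of the fitted
#' Gaussian: `BVI = SD(centers) / SD(Gaussian)`, with the center SD taken
#' as the rms of the per-axis SDs and the Gaussian SD as the geometric
#' mean of `sx` and `sy`. Small values indicate a reliable center
#' estimate.
#'
#' @param rf_map the mapping log (see [rf_response_map()]).
#' @param fit the point [fit_rf_gaussian()] on the original data.
#' @param recording optional spike-time recording (for logs without
#'   counts).
#' @param B bootstrap repetitions (default 200).
#' @param seed integer seed.
#' @param max_fail_frac BVI is undefined when more than this fraction of
#'   refits fail.
#' @param bvi_threshold reliability threshold on the BVI.
#' @return the `rf_fit` with `bvi` filled in and `reliable` updated
#'   (`reliable` requires both `bvi < bvi_threshold` and the r-squared
#'   criterion of the point fit).
#' @export
bootstrap_bvi <- function(rf_map, fit, recording = NULL, B = 200L, seed = 1L,
                          max_fail_frac = 0.2, bvi_threshold = 0.5) {
  stopifnot(inherits(fit, "rf_fit"))
  if (!fit$converged) stop("point fit did not converge; BVI undefined")
  if (is.data.frame(rf_map)) rf_map <- list(events = rf_map)
  ev <- rf_map$events
  centers <- with_seed_if(seed, {
    t(vapply(seq_len(B), function(b) {
      boot <- rf_map
      boot$events <- ev[sample.int(nrow(ev), nrow(ev), replace = TRUE), ,
                        drop = FALSE]
      m <- tryCatch(rf_response_map(boot, recording, window = fit$window),
                    error = function(e) NULL)
      if (is.null(m)) return(c(NA_real_, NA_real_))
      f <- fit_rf_gaussian(m, polarity = fit$polarity)
      if (f$converged) f$center else c(NA_real_, NA_real_)
    }, numeric(2)))
  })
  fails <- sum(!is.finite(centers[, 1]))
  if (fails > max_fail_frac * B) {
    fit$bvi <- NA_real_
    fit$reliable <- FALSE
    return(fit)
  }
  sd_center <- sqrt((var(centers[, 1], na.rm = TRUE) +
                       var(centers[, 2], na.rm = TRUE)) / 2)
  sd_gauss <- sqrt(prod(fit$sd))
  fit$bvi <- sd_center / sd_gauss
  fit$reliable <- fit$reliable && fit$bvi < bvi_threshold
  fit
}

#' Classify an RF relative to the task figure
#'
#' The RF disk is the `k` sigma contour around the fitted center (sigma =
#' geometric mean of the axis SDs). The RF is `inside` iff the disk lies
#' entirely within the figure circle, `edge` iff it intersects the figure
#' boundary, `outside` otherwise; an unreliable fit yields `unreliable`.
#'
#' @param fit an `rf_fit`.
#' @param figure_center c(azimuth, elevation) of the figure, degrees.
#' @param figure_diameter figure diameter, degrees (default 40).
#' @param k contour radius in Gaussian SDs (default 1).
#' @return one of `"inside"`, `"edge"`, `"outside"`, `"unreliable"`.
#' @export
classify_rf <- function(fit, figure_center, figure_diameter = 40, k = 1) {
  if (!isTRUE(fit$reliable)) return("unreliable")
  r_rf <- k * sqrt(prod(fit$sd))
  R <- figure_diameter / 2
  dist <- sqrt(sum((fit$center - figure_center)^2))
  if (dist + r_rf <= R) "inside"
  else if (dist - r_rf > R) "outside"
  else "edge"
}

#' Place the figure and ground stimuli for a recorded RF
#'
#' The figure is centered on the RF; the ground stimulus places the figure
#' `displacement` degrees lateral of the RF into the opposite hemifield
#' (azimuth sign flip). If the default displacement does not reach the
#' opposite hemifield it is stretched up to `max_displacement`; failing
#' that, the placement is clipped just across the vertical meridian with a
#' warning.
#'
#' @param fit a reliable `rf_fit`.
#' @param displacement lateral displacement, degrees (default 55, the
#'   midpoint of the 50--60 degree convention).
#' @param max_displacement upper bound of the displacement range.
#' @return list with `figure_position`, `ground_position` (azimuth,
#'   elevation), `displacement`, `clipped`.
#' @export
place_stimuli <- function(fit, displacement = 55, max_displacement = 60) {
  if (!isTRUE(fit$reliable)) stop("RF fit is not reliable; cannot place stimuli")
  az <- fit$center[1]; el <- fit$center[2]
  s <- if (az >= 0) 1 else -1
  gaz <- az - s * displacement
  d <- displacement
  clipped <- FALSE
  if (sign(gaz) == s) {            # did not cross the meridian: stretch
    d <- max_displacement
    gaz <- az - s * d
    if (sign(gaz) == s) {
      warning("RF too lateral to place the ground stimulus 50-60 degrees ",
              "into the opposite hemifield; clipping across the meridian")
      gaz <- -s * 2
      clipped <- TRUE
    }
  }
  list(figure_position = c(az, el), ground_position = c(gaz, el),
       displacement = d, clipped = clipped)
}
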