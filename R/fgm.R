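## Figure-ground modulation: visual-responsiveness inclusion, response
## normalisation, the cluster-based permutation test with mixed-model
## statistics, the modulation-latency fit, and optogenetic suppression.

# trials whose stimulus drives the RF with a grating: figure trials always;
# ground trials too in the orientation/phase tasks (the background grating
# covers the RF), but not in the contrast task (gray background)
in_rf_grating <- function(trials) {
  trials$stimulus == "figure" |
    (trials$task %in% c("orientation", "phase") & trials$stimulus == "ground")
}

#' Visual-responsiveness inclusion criterion
#'
#' A neuron is visual iff its baseline-subtracted evoked rate -- mean rate
#' in the 50--200 ms window minus mean rate in the 150 ms pre-stimulus
#' baseline, averaged over all grating-in-RF trials -- is at least
#' `threshold` spikes/s.
#'
#' @param recording a [neuron_recording()].
#' @param trials trial table (with `stimulus` labels).
#' @param config an [analysis_config()].
#' @param baseline_subtract subtract the baseline rate (default `TRUE`).
#' @return list with `included`, `evoked`, `response`, `baseline`.
#' @export
visual_inclusion <- function(recording, trials, config = analysis_config(),
                             baseline_subtract = TRUE) {
  sel <- in_rf_grating(trials) & !trials$excluded
  if (!any(sel)) return(list(included = FALSE, evoked = NA_real_,
                             response = NA_real_, baseline = NA_real_))
  sub <- trials[sel, , drop = FALSE]
  resp <- mean(window_rates(list(recording), sub, config$visual_window))
  base <- mean(window_rates(list(recording), sub, config$baseline_window))
  evoked <- if (baseline_subtract) resp - base else resp
  list(included = evoked >= config$visual_threshold, evoked = evoked,
       response = resp, baseline = base)
}

#' Per-neuron normalisation constants
#'
#' From each neuron's trial-averaged smoothed rate over all grating-in-RF
#' trials: the baseline is the mean rate in the 0.15 s before stimulus
#' onset, the maximum the peak of the average rate 0.05--0.20 s after
#' onset. Responses are normalised as
#' `(R - R_baseline) / (R_max - R_baseline)`.
#'
#' @param neurons list of [neuron_recording()].
#' @param trials trial table.
#' @param config an [analysis_config()].
#' @param window,dt smoothing window and resolution passed to the rate
#'   estimator.
#' @return data.frame per neuron: `baseline`, `rmax`, `degenerate`.
#' @export
normalization_constants <- function(neurons, trials, config = analysis_config(),
                                    window = c(-0.3, 0.6), dt = 0.001) {
  sel <- in_rf_grating(trials) & !trials$excluded
  if (!any(sel)) stop("no grating-in-RF trials to normalise against")
  out <- do.call(rbind, lapply(neurons, function(nr) {
    ps <- condition_psth(nr, trials, sel, sd = config$smooth_sd,
                         window = window, dt = dt)
    base <- mean(ps$rate[ps$time >= config$baseline_window[1] &
                           ps$time < config$baseline_window[2]])
    rmax <- max(ps$rate[ps$time >= config$peak_window[1] &
                          ps$time < config$peak_window[2]])
    data.frame(neuron_id = nr$neuron_id, baseline = base, rmax = rmax,
               degenerate = (rmax - base) < 1e-9, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Normalise response traces with per-neuron constants
#'
#' Applies the affine map `(R - baseline) / (rmax - baseline)` of
#' [normalization_constants()] to every trial of each neuron (figure and
#' ground alike). Degenerate neurons (`rmax == baseline`) are flagged and
#' excluded from population traces.
#'
#' @param rates list per neuron of `[trials, time]` rate matrices (or a
#'   single matrix for one neuron).
#' @param constants data.frame from [normalization_constants()] (rows
#'   aligned with `rates`).
#' @return list with `traces` (same shape, normalised; `NULL` for
#'   degenerate neurons) and `degenerate` (logical per neuron).
#' @export
normalize_responses <- function(rates, constants) {
  if (is.matrix(rates)) rates <- list(rates)
  stopifnot(length(rates) == nrow(constants))
  traces <- lapply(seq_along(rates), function(i) {
    if (constants$degenerate[i]) return(NULL)
    (rates[[i]] - constants$baseline[i]) /
      (constants$rmax[i] - constants$baseline[i])
  })
  list(traces = traces, degenerate = constants$degenerate)
}

#' Population figure/ground traces on a common time base
#'
#' Per neuron: trial-averaged smoothed rates for figure and ground trials,
#' normalised with that neuron's constants, then binned to `bin` s bins --
#' the input expected by [cluster_permutation_test()].
#'
#' @param neurons list of [neuron_recording()].
#' @param trials trial table (only non-excluded trials are used).
#' @param config an [analysis_config()].
#' @param window analysis window, seconds relative to stimulus onset.
#' @param bin time-bin width for the permutation test, seconds.
#' @param dt smoothing grid, seconds.
#' @return list with `time` (bin centers), `figure` and `ground`
#'   (`[neurons, bins]` matrices), and `constants`.
#' @export
population_traces <- function(neurons, trials, config = analysis_config(),
                              window = c(-0.1, 0.4), bin = 0.010, dt = 0.001) {
  keep <- !trials$excluded
  tr <- trials[keep, , drop = FALSE]
  consts <- normalization_constants(neurons, tr, config,
                                    window = c(window[1] - 0.2, window[2] + 0.1),
                                    dt = dt)
  nb <- round(diff(window) / bin)
  per_bin <- round(bin / dt)
  bin_means <- function(x) colMeans(matrix(x, per_bin, nb))
  fig <- gnd <- matrix(NA_real_, length(neurons), nb)
  for (i in seq_along(neurons)) {
    if (consts$degenerate[i]) next
    scale <- consts$rmax[i] - consts$baseline[i]
    f <- condition_psth(neurons[[i]], tr, tr$stimulus == "figure",
                        sd = config$smooth_sd, window = window, dt = dt)
    g <- condition_psth(neurons[[i]], tr, tr$stimulus == "ground",
                        sd = config$smooth_sd, window = window, dt = dt)
    fig[i, ] <- bin_means((f$rate - consts$baseline[i]) / scale)
    gnd[i, ] <- bin_means((g$rate - consts$baseline[i]) / scale)
  }
  ok <- !consts$degenerate
  list(time = window[1] + (seq_len(nb) - 0.5) * bin,
       figure = fig[ok, , drop = FALSE], ground = gnd[ok, , drop = FALSE],
       constants = consts)
}

# Closed-form per-bin F statistic for the balanced two-condition
# random-intercept model on per-neuron condition means. With one figure and
# one ground observation per neuron the REML mixed-model F for the
# condition effect equals the paired t-squared, F = n * mean(d)^2 / var(d),
# whenever the between-neuron variance estimate is interior
# (var(pair means) >= var(d) / 4). On the boundary (estimate truncated at
# zero) the model collapses to iid errors and
# F = n * mean(d)^2 / (2 * var(a) + var(d) / 2), where a are the pair
# means. `a_var` can be supplied because pair means are invariant under
# within-pair label swaps. Returns list(F, p) with df (1, n - 1).
paired_F <- function(d, a_var = NULL) {
  n <- nrow(d)
  m <- colMeans(d)
  v <- (colSums(d^2) - n * m^2) / (n - 1)
  if (is.null(a_var)) stop("a_var (variance of pair means per bin) required")
  boundary <- a_var < v / 4
  denom <- ifelse(boundary, 2 * a_var + v / 2, v)
  F <- n * m^2 / pmax(denom, 1e-300)
  list(F = F, p = pf(F, 1, n - 1, lower.tail = FALSE))
}

# per-bin F via lme4: response ~ condition + (1 | neuron); used as the
# slower reference engine
lmer_F <- function(fig, gnd) {
  n <- nrow(fig)
  Fv <- numeric(ncol(fig))
  for (b in seq_len(ncol(fig))) {
    df <- data.frame(y = c(fig[, b], gnd[, b]),
                     cond = rep(c("figure", "ground"), each = n),
                     id = factor(rep(seq_len(n), 2)))
    fit <- suppressMessages(lme4::lmer(y ~ cond + (1 | id), data = df,
                                       REML = TRUE))
    Fv[b] <- anova(fit)[1, "F value"]
  }
  list(F = Fv, p = pf(Fv, 1, n - 1, lower.tail = FALSE))
}

# maximal runs of TRUE; returns data.frame(start, end) of indices
find_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Cluster-based permutation test for figure versus ground
#'
#' Per time bin, a mixed model of the normalised response on stimulus
#' condition with a random intercept per neuron yields an F statistic;
#' contiguous bins with p < `alpha` form clusters scored by their summed F.
#' Permutations swap the figure/ground labels within neuron (whole-condition
#' swaps, preserving the within-neuron pairing), and each observed cluster
#' is compared against the permutation null of maximum cluster scores with
#' +1 smoothing. For this balanced design the mixed-model F has the exact
#' closed form of the paired t-squared, which the default engine uses; the
#' `"lmer"` engine fits lme4 per bin and gives identical statistics.
#'
#' @param figure,ground `[neurons, bins]` matrices of per-neuron mean
#'   normalised responses (e.g. from [population_traces()]).
#' @param time bin centers, seconds.
#' @param n_perm number of permutations.
#' @param alpha per-bin cluster-forming alpha.
#' @param seed integer seed.
#' @param engine `"exact"` (closed form, default) or `"lmer"`.
#' @return object of class `cluster_test_result`: list with `clusters`
#'   (data.frame t_start/t_end/summed_F/p_perm), `per_bin_F`, `per_bin_p`,
#'   `alpha`, `n_perm`, `time`, `null_max`.
#' @export
cluster_permutation_test <- function(figure, ground, time, n_perm = 1000L,
                                     alpha = 0.05, seed = 1L,
                                     engine = c("exact", "lmer")) {
  engine <- match.arg(engine)
  stopifnot(ncol(figure) == ncol(ground), nrow(figure) == nrow(ground),
            ncol(figure) == length(time))
  n <- nrow(figure)
  if (n < 2L) stop("need at least 2 neurons")
  d <- figure - ground
  a <- (figure + ground) / 2
  a_var <- apply(a, 2, var)
  obs <- if (engine == "exact") paired_F(d, a_var) else lmer_F(figure, ground)
  runs <- find_runs(obs$p < alpha)
  clusters <- if (nrow(runs)) {
    data.frame(t_start = time[runs$start], t_end = time[runs$end],
               bin_start = runs$start, bin_end = runs$end,
               summed_F = vapply(seq_len(nrow(runs)), function(k) {
                 sum(obs$F[runs$start[k]:runs$end[k]])
               }, numeric(1)))
  } else {
    data.frame(t_start = numeric(0), t_end = numeric(0),
               bin_start = integer(0), bin_end = integer(0),
               summed_F = numeric(0))
  }
  null_max <- with_seed_if(seed, {
    S <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    if (engine == "exact") {
      ss <- colSums(d^2)
      M <- (S %*% d) / n
      V <- sweep(-n * M^2, 2, ss, `+`) / (n - 1)
      # pair means are invariant under within-pair swaps, so a_var is fixed
      AV <- matrix(a_var, n_perm, length(a_var), byrow = TRUE)
      boundary <- AV < V / 4
      denom <- ifelse(boundary, 2 * AV + V / 2, V)
      Fp <- n * M^2 / pmax(denom, 1e-300)
      Pp <- pf(Fp, 1, n - 1, lower.tail = FALSE)
      vapply(seq_len(n_perm), function(r) {
        rr <- find_runs(Pp[r, ] < alpha)
        if (!nrow(rr)) return(0)
        max(vapply(seq_len(nrow(rr)), function(k) {
          sum(Fp[r, rr$start[k]:rr$end[k]])
        }, numeric(1)))
      }, numeric(1))
    } else {
      vapply(seq_len(n_perm), function(r) {
        s <- S[r, ]
        fig_p <- figure; gnd_p <- ground
        swap <- s < 0
        fig_p[swap, ] <- ground[swap, ]
        gnd_p[swap, ] <- figure[swap, ]
        st <- lmer_F(fig_p, gnd_p)
        rr <- find_runs(st$p < alpha)
        if (!nrow(rr)) return(0)
        max(vapply(seq_len(nrow(rr)), function(k) {
          sum(st$F[rr$start[k]:rr$end[k]])
        }, numeric(1)))
      }, numeric(1))
    }
  })
  clusters$p_perm <- vapply(clusters$summed_F, function(sF) {
    (1 + sum(null_max >= sF)) / (n_perm + 1)
  }, numeric(1))
  structure(list(clusters = clusters, per_bin_F = obs$F, per_bin_p = obs$p,
                 alpha = alpha, n_perm = n_perm, time = time,
                 null_max = null_max, engine = engine),
            class = "cluster_test_result")
}

#' Significant clusters of a cluster test
#'
#' @param result a `cluster_test_result`.
#' @param alpha cluster-level significance threshold.
#' @return the rows of `result$clusters` with `p_perm < alpha`.
#' @export
significant_clusters <- function(result, alpha = 0.05) {
  result$clusters[result$clusters$p_perm < alpha, , drop = FALSE]
}

# exponentially modified Gaussian density (mean mu, SD sigma of the
# Gaussian stage, exponential time constant tau)
exgauss_density <- function(t, mu, sigma, tau) {
  z <- (t - mu) / sigma - sigma / tau
  (1 / tau) * exp((mu - t) / tau + sigma^2 / (2 * tau^2)) * pnorm(z)
}

fgm_latency_fun <- function(t, A, B, mu, sigma, tau) {
  A * exgauss_density(t, mu, sigma, tau) + B * pnorm((t - mu) / sigma)
}

#' Fit the figure-ground modulation latency
#'
#' Fits the sum of an exponentially modified Gaussian and a cumulative
#' Gaussian (shared mu and sigma) to the figure-minus-ground population
#' trace in a 0--300 ms window by bounded nonlinear least squares; the
#' latency is the time on the rising flank at which the fitted curve
#' reaches `criterion` (default 33%) of its maximum.
#'
#' @param diff_trace figure-minus-ground population trace.
#' @param time time base of `diff_trace`, seconds.
#' @param fit_window fitting window, seconds (default `c(0, 0.3)`).
#' @param criterion fraction of the fitted maximum (default 0.33).
#' @return object of class `latency_fit`: list with `params`, `latency`
#'   (seconds; `NA` when not converged), `converged`, `fitted`, `time`.
#' @export
fit_fgm_latency <- function(diff_trace, time, fit_window = c(0, 0.300),
                            criterion = 0.33) {
  sel <- time >= fit_window[1] & time <= fit_window[2]
  tt <- time[sel]; yy <- diff_trace[sel]
  bad <- function(reason) structure(list(params = NULL, latency = NA_real_,
                                         converged = FALSE, reason = reason,
                                         fitted = NULL, time = tt),
                                    class = "latency_fit")
  if (length(tt) < 8L) return(bad("trace must cover the fit window"))
  if (max(yy) <= 0 || stats::sd(yy) < 1e-12) return(bad("no positive modulation"))
  t_half <- tt[which(yy >= 0.5 * max(yy))[1]]
  starts <- list(
    list(A = max(yy) * 0.05, B = max(0, mean(yy[tt > max(tt) - 0.05])),
         mu = t_half, sigma = 0.02, tau = 0.05),
    list(A = max(yy) * 0.1, B = max(yy) * 0.2, mu = 0.1, sigma = 0.03, tau = 0.1))
  fit <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ fgm_latency_fun(t, A, B, mu, sigma, tau),
                        data = data.frame(t = tt, y = yy), start = st,
                        lower = c(A = 0, B = 0, mu = fit_window[1],
                                  sigma = 2e-3, tau = 5e-3),
                        upper = c(A = Inf, B = Inf, mu = fit_window[2],
                                  sigma = 0.15, tau = 0.5),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) return(bad("nonlinear least squares did not converge"))
  p <- as.list(coef(fit))
  grid <- seq(fit_window[1], fit_window[2], length.out = 3001L)
  yhat <- fgm_latency_fun(grid, p$A, p$B, p$mu, p$sigma, p$tau)
  if (max(yhat) <= 0) return(bad("fitted maximum not positive"))
  target <- criterion * max(yhat)
  i_max <- which.max(yhat)
  below <- which(yhat[seq_len(i_max)] < target)
  latency <- if (!length(below)) {
    grid[1]
  } else {
    i0 <- max(below)
    uniroot(function(t) fgm_latency_fun(t, p$A, p$B, p$mu, p$sigma, p$tau) - target,
            lower = grid[i0], upper = grid[min(i0 + 1L, i_max)])$root
  }
  structure(list(params = unlist(p), latency = latency, converged = TRUE,
                 reason = "ok", fitted = yhat, time = grid,
                 criterion = criterion),
            class = "latency_fit")
}

#' Optogenetic suppression of visual responses
#'
#' Per unit, the visual response is the mean rate 0--0.2 s after stimulus
#' onset; units enter iff their baseline-subtracted evoked rate without the
#' laser is at least `min_evoked` spikes/s and their laser-off rate is
#' positive. The per-unit reduction is `100 * (1 - on / off)`.
#'
#' @param rates_on,rates_off per-unit visual-response rates with laser on /
#'   off (spikes/s).
#' @param evoked_off per-unit baseline-subtracted evoked rates without the
#'   laser; defaults to `rates_off` (no baseline available).
#' @param min_evoked inclusion threshold, spikes/s (default 2).
#' @return list with `percent_reduction` (per included unit),
#'   `mean_reduction`, `included` (logical per unit).
#' @export
opto_suppression <- function(rates_on, rates_off, evoked_off = rates_off,
                             min_evoked = 2) {
  stopifnot(length(rates_on) == length(rates_off))
  inc <- evoked_off >= min_evoked & rates_off > 0
  red <- 100 * (1 - rates_on[inc] / rates_off[inc])
  list(percent_reduction = red,
       mean_reduction = if (any(inc)) mean(red) else NA_real_,
       included = inc)
}
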