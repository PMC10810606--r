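## Behavioral analysis: accuracy, session inclusion, psychometric fitting
## with bootstrapped inflection points, and the repeated-measures ANOVA on
## the laser-onset effect.

# label laser-onset conditions, mapping NA to "no_laser"
onset_condition <- function(laser_onset) {
  ifelse(is.na(laser_onset), "no_laser", sprintf("%.4f", laser_onset))
}

# analysis trials: non-correction, non-excluded
usable_trials <- function(trials, drop_corrections = TRUE) {
  keep <- !trials$excluded
  if (drop_corrections) keep <- keep & !trials$is_correction
  trials[keep, , drop = FALSE]
}

#' Compute task accuracy per condition
#'
#' Accuracy is hits/(hits + errors); with `include_misses = TRUE` it is
#' hits/(hits + errors + misses). Correction trials are removed when
#' `drop_corrections` is set, as are excluded trials. A zero denominator
#' yields `NA` accuracy with `undefined = TRUE`, never 0.
#'
#' @param trials a trial table.
#' @param include_misses count misses in the denominator.
#' @param drop_corrections drop correction trials (default `TRUE`).
#' @param by grouping columns; `"condition"` refers to the laser-onset
#'   condition (with `"no_laser"` for laser-off trials).
#' @return data.frame with counts, `accuracy`, and `undefined` per group.
#' @export
compute_accuracy <- function(trials, include_misses = FALSE,
                             drop_corrections = TRUE,
                             by = c("mouse", "condition")) {
  tr <- usable_trials(trials, drop_corrections)
  if (!nrow(tr)) stop("no usable trials after filtering")
  tr$condition <- onset_condition(tr$laser_onset)
  tr$laser <- ifelse(is.na(tr$laser_onset), NA_real_, tr$laser_onset)
  key <- interaction(tr[, by, drop = FALSE], drop = TRUE, sep = "\r")
  agg <- lapply(split(tr, key), function(g) {
    hits <- sum(g$response == "hit")
    errors <- sum(g$response == "error")
    misses <- sum(g$response == "miss")
    denom <- hits + errors + if (include_misses) misses else 0L
    row <- g[1, by, drop = FALSE]
    row$laser_onset <- g$laser[1]
    row$hits <- hits; row$errors <- errors; row$misses <- misses
    row$n <- denom
    row$accuracy <- if (denom > 0) hits / denom else NA_real_
    row$undefined <- denom == 0
    row
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out[order(out[[by[1]]], out$laser_onset, na.last = FALSE), , drop = FALSE]
}

#' Session inclusion by performance
#'
#' For sessions of at least `n_threshold` scored trials, the session (per
#' task) is included iff the accuracy is significantly above chance by a
#' one-sided exact binomial test (p < alpha vs 0.5). Shorter sessions are
#' included iff accuracy is at least 65% and per-side accuracy at least
#' 50%.
#'
#' @param trials trial table (a single task's trials).
#' @param n_threshold session length at which the binomial rule applies
#'   (default 40).
#' @param alpha significance level for the binomial test.
#' @param min_accuracy,min_side_accuracy short-session thresholds.
#' @return list with `included`, `p` (binomial p, `NA` under the short
#'   rule), `n`, `accuracy`, `rule`, and `reason`.
#' @export
session_inclusion <- function(trials, n_threshold = 40L, alpha = 0.05,
                              min_accuracy = 0.65, min_side_accuracy = 0.50) {
  tr <- usable_trials(trials)
  tr <- tr[tr$response != "miss", , drop = FALSE]
  n <- nrow(tr)
  if (n == 0L) {
    return(list(included = FALSE, p = NA_real_, n = 0L, accuracy = NA_real_,
                rule = "empty", reason = "no scored trials"))
  }
  hits <- sum(tr$response == "hit")
  acc <- hits / n
  if (n >= n_threshold) {
    p <- binom.test(hits, n, 0.5, alternative = "greater")$p.value
    return(list(included = p < alpha, p = p, n = n, accuracy = acc,
                rule = "binomial",
                reason = if (p < alpha) "above chance" else "not above chance"))
  }
  side_ok <- all(vapply(split(tr, tr$figure_side), function(g) {
    mean(g$response == "hit") >= min_side_accuracy
  }, logical(1)))
  inc <- acc >= min_accuracy && side_ok
  list(included = inc, p = NA_real_, n = n, accuracy = acc, rule = "short",
       reason = if (inc) "short-session rule met" else "short-session rule failed")
}

#' Fit a logistic psychometric function
#'
#' Bounded least squares of [logistic_accuracy()] to mean accuracy versus
#' laser-onset latency; the floor is bounded below at chance (0.5) and the
#' ceiling above at 1. The inflection point is the logistic location
#' parameter -- the latency of the curve's midpoint between floor and
#' ceiling.
#'
#' @param latencies laser-onset latencies, seconds.
#' @param accuracies mean accuracy at each latency.
#' @return object of class `psychometric_fit`: list with `params`
#'   (floor/ceiling/inflection/slope), `converged`, `reason`, `latencies`,
#'   `accuracies`, and `fitted`.
#' @export
fit_psychometric <- function(latencies, accuracies) {
  stopifnot(length(latencies) == length(accuracies))
  ok <- is.finite(latencies) & is.finite(accuracies)
  latencies <- latencies[ok]; accuracies <- accuracies[ok]
  if (length(latencies) < 4L) {
    return(structure(list(params = NULL, converged = FALSE,
                          reason = "need at least 4 latencies",
                          latencies = latencies, accuracies = accuracies,
                          fitted = NULL), class = "psychometric_fit"))
  }
  if (diff(range(accuracies)) < 1e-3) {
    return(structure(list(params = NULL, converged = FALSE,
                          reason = "flat accuracies: slope unidentifiable",
                          latencies = latencies, accuracies = accuracies,
                          fitted = NULL), class = "psychometric_fit"))
  }
  rng <- range(latencies)
  span <- diff(rng)
  start <- list(fl = max(0.5, min(accuracies)),
                ce = min(1, max(accuracies)),
                ip = latencies[which.min(abs(accuracies -
                                               (min(accuracies) + max(accuracies)) / 2))],
                sl = 10 / span)
  fit <- tryCatch(
    minpack.lm::nlsLM(acc ~ logistic_accuracy(lat, fl, ce, ip, sl),
                      data = data.frame(lat = latencies, acc = accuracies),
                      start = start,
                      lower = c(fl = 0.5, ce = 0.5, ip = rng[1], sl = 1e-3),
                      upper = c(fl = 1, ce = 1, ip = rng[2], sl = 2000 / span),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(params = NULL, converged = FALSE,
                          reason = "nonlinear least squares did not converge",
                          latencies = latencies, accuracies = accuracies,
                          fitted = NULL), class = "psychometric_fit"))
  }
  p <- coef(fit)
  params <- c(floor = unname(p["fl"]), ceiling = unname(p["ce"]),
              inflection = unname(p["ip"]), slope = unname(p["sl"]))
  structure(list(params = params, converged = TRUE, reason = "ok",
                 latencies = latencies, accuracies = accuracies,
                 fitted = logistic_accuracy(latencies, p["fl"], p["ce"],
                                            p["ip"], p["sl"])),
            class = "psychometric_fit")
}

# mean accuracy across mice at each laser latency (laser trials only)
mean_accuracy_by_latency <- function(trials, include_misses = FALSE) {
  acc <- compute_accuracy(trials, include_misses = include_misses,
                          by = c("mouse", "condition"))
  acc <- acc[!is.na(acc$laser_onset) & !acc$undefined, , drop = FALSE]
  agg <- aggregate(accuracy ~ laser_onset, data = acc, FUN = mean)
  agg[order(agg$laser_onset), ]
}

#' Bootstrap the psychometric inflection point
#'
#' Resamples trials with replacement within each mouse (stratified by
#' laser-onset condition so every latency stays represented), averages
#' accuracies across mice, refits the logistic, and reports the mean and SD
#' of the `B` bootstrapped inflection points.
#'
#' @param trials trial table with `mouse` and `laser_onset` columns.
#' @param B bootstrap repetitions (default 1000).
#' @param seed integer seed.
#' @param max_fail_frac flag the result if more than this fraction of
#'   refits fail (default 0.2).
#' @return object of class `psychometric_result`: the point fit plus
#'   `inflection_boot`, `inflection_mean`, `inflection_sd`, `n_failed`, and
#'   `flagged`.
#' @export
bootstrap_inflection <- function(trials, B = 1000L, seed = 1L,
                                 max_fail_frac = 0.2) {
  tr <- usable_trials(trials)
  tr <- tr[!is.na(tr$laser_onset) & tr$response != "miss", , drop = FALSE]
  point <- {
    m <- mean_accuracy_by_latency(trials)
    fit_psychometric(m$laser_onset, m$accuracy)
  }
  if (!point$converged) {
    stop("point fit failed (", point$reason, "); cannot bootstrap")
  }
  cells <- split(seq_len(nrow(tr)),
                 list(tr$mouse, onset_condition(tr$laser_onset)), drop = TRUE)
  lat_levels <- sort(unique(tr$laser_onset))
  boots <- with_seed_if(seed, {
    vapply(seq_len(B), function(b) {
      idx <- unlist(lapply(cells, function(ix) ix[sample.int(length(ix),
                                                             length(ix),
                                                             replace = TRUE)]),
                    use.names = FALSE)
      g <- tr[idx, , drop = FALSE]
      per_mouse <- aggregate(hit ~ mouse + laser_onset,
                             data = data.frame(mouse = g$mouse,
                                               laser_onset = g$laser_onset,
                                               hit = g$response == "hit"),
                             FUN = mean)
      m <- aggregate(hit ~ laser_onset, data = per_mouse, FUN = mean)
      f <- fit_psychometric(m$laser_onset, m$hit)
      if (f$converged) unname(f$params["inflection"]) else NA_real_
    }, numeric(1))
  })
  n_failed <- sum(is.na(boots))
  structure(list(latencies = lat_levels,
                 mean_accuracy = mean_accuracy_by_latency(trials)$accuracy,
                 fitted_params = point$params,
                 inflection_boot = boots,
                 inflection_mean = mean(boots, na.rm = TRUE),
                 inflection_sd = stats::sd(boots, na.rm = TRUE),
                 n_failed = n_failed, B = B,
                 flagged = n_failed > max_fail_frac * B),
            class = "psychometric_result")
}

#' Repeated-measures ANOVA on the laser-onset effect
#'
#' One-way repeated-measures ANOVA of per-mouse accuracy on laser-onset
#' condition, with Bonferroni-adjusted paired comparisons of each onset
#' against the no-laser condition.
#'
#' @param acc_matrix numeric matrix, mice x onsets, with onset condition
#'   names as column names (one of them `"no_laser"` for the pairwise
#'   table, if present).
#' @return list with `F`, `df`, `p`, and `pairwise` (onset, t, p_raw,
#'   p_bonferroni vs the reference column).
#' @export
onset_effect_anova <- function(acc_matrix) {
  if (anyNA(acc_matrix)) {
    bad <- which(is.na(acc_matrix), arr.ind = TRUE)[1, ]
    stop("missing accuracy for mouse ", rownames(acc_matrix)[bad[1]] %||% bad[1],
         " at onset ", colnames(acc_matrix)[bad[2]] %||% bad[2])
  }
  long <- data.frame(
    accuracy = as.vector(acc_matrix),
    mouse = factor(rep(rownames(acc_matrix) %||% seq_len(nrow(acc_matrix)),
                       ncol(acc_matrix))),
    onset = factor(rep(colnames(acc_matrix) %||% seq_len(ncol(acc_matrix)),
                       each = nrow(acc_matrix))))
  fit <- aov(accuracy ~ onset + Error(mouse), data = long)
  tab <- summary(fit)[["Error: Within"]][[1]]
  Fv <- tab["onset", "F value"]
  pv <- tab["onset", "Pr(>F)"]
  dfs <- c(tab["onset", "Df"], tab["Residuals", "Df"])
  ref <- if ("no_laser" %in% colnames(acc_matrix)) "no_laser" else
    colnames(acc_matrix)[ncol(acc_matrix)]
  others <- setdiff(colnames(acc_matrix), ref)
  pw <- do.call(rbind, lapply(others, function(on) {
    tt <- t.test(acc_matrix[, on], acc_matrix[, ref], paired = TRUE)
    data.frame(onset = on, reference = ref, t = unname(tt$statistic),
               p_raw = tt$p.value, stringsAsFactors = FALSE)
  }))
  pw$p_bonferroni <- pmin(pw$p_raw * length(others), 1)
  list(F = Fv, df = dfs, p = pv, pairwise = pw)
}

#' Reaction-time and responsiveness summaries per condition
#'
#' Aggregates within mouse first (the mouse is the statistical unit), then
#' across mice: mean reaction time on non-miss trials and the response rate
#' (fraction of trials with any lick) per laser-onset condition.
#'
#' @param trials trial table.
#' @param drop_corrections drop correction trials.
#' @return data.frame per condition: `mean_reaction_time`,
#'   `response_rate`, `n_mice`.
#' @export
response_summaries <- function(trials, drop_corrections = TRUE) {
  tr <- usable_trials(trials, drop_corrections)
  tr$condition <- onset_condition(tr$laser_onset)
  per_mouse <- lapply(split(tr, list(tr$mouse, tr$condition), drop = TRUE),
                      function(g) {
    data.frame(mouse = g$mouse[1], condition = g$condition[1],
               rt = mean(g$reaction_time[g$response != "miss"]),
               response_rate = mean(g$response != "miss"),
               stringsAsFactors = FALSE)
  })
  pm <- do.call(rbind, per_mouse)
  out <- do.call(rbind, lapply(split(pm, pm$condition), function(g) {
    data.frame(condition = g$condition[1],
               mean_reaction_time = mean(g$rt, na.rm = TRUE),
               response_rate = mean(g$response_rate),
               n_mice = nrow(g), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
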