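## d-prime discriminability between figure and ground responses, its
## trial-shuffle null, and the hit/error comparison with mixed-model
## selection by AIC.

#' d-prime between two response distributions
#'
#' `d' = (mean_F - mean_G) / sqrt((var_F + var_G) / 2)`: the standardised
#' mean difference quantifying single-trial discriminability.
#'
#' @param figure,ground per-trial responses for the two stimulus classes
#'   (at least 2 trials each).
#' @return the d-prime; `NA` (with a warning) when both variances are zero.
#' @export
dprime <- function(figure, ground) {
  if (length(figure) < 2L || length(ground) < 2L) {
    stop("need at least 2 trials per class")
  }
  pooled <- (var(figure) + var(ground)) / 2
  if (pooled == 0) {
    warning("both classes have zero variance; d-prime undefined")
    return(NA_real_)
  }
  (mean(figure) - mean(ground)) / sqrt(pooled)
}

#' Trial-shuffle null distribution of the population d-prime
#'
#' Recomputes each neuron's d-prime after shuffling its trial identities
#' (class labels), `n_shuffle` times; reports the null distribution of the
#' population mean d-prime, its 95% confidence interval, and where the
#' observed mean falls.
#'
#' @param features list per neuron of `list(figure=, ground=)` response
#'   vectors.
#' @param n_shuffle shuffles (default 1000).
#' @param seed integer seed.
#' @return list with `observed` (per-neuron d-primes), `observed_mean`,
#'   `null_mean` (per shuffle), `ci` (2.5/97.5% of the null), and
#'   `above_null` (observed mean exceeds the upper CI bound).
#' @export
dprime_shuffle_null <- function(features, n_shuffle = 1000L, seed = 1L) {
  obs <- vapply(features, function(f) dprime(f$figure, f$ground), numeric(1))
  nf <- vapply(features, function(f) length(f$figure), integer(1))
  null_mean <- with_seed_if(seed, {
    vapply(seq_len(n_shuffle), function(s) {
      mean(vapply(seq_along(features), function(i) {
        pool <- c(features[[i]]$figure, features[[i]]$ground)
        pool <- pool[sample.int(length(pool))]
        dprime(pool[seq_len(nf[i])], pool[-seq_len(nf[i])])
      }, numeric(1)), na.rm = TRUE)
    }, numeric(1))
  })
  ci <- unname(quantile(null_mean, c(0.025, 0.975)))
  list(observed = obs, observed_mean = mean(obs, na.rm = TRUE),
       null_mean = null_mean, ci = ci,
       above_null = mean(obs, na.rm = TRUE) > ci[2])
}

#' Per-neuron hit/error d-primes over the onset-to-lick window
#'
#' For each neuron, per-trial responses are mean rates between stimulus
#' onset and the first lick; d-primes between figure and ground are
#' computed separately on hit and on error trials (tasks pooled). Neurons
#' with fewer than `min_trials` trials in any stimulus-by-outcome cell are
#' omitted from the corresponding outcome.
#'
#' @param neurons list of [neuron_recording()].
#' @param trials trial table with `response` (hit/error) and
#'   `reaction_time`; misses are excluded (no outcome label).
#' @param min_trials minimum trials per cell (default 2).
#' @return data.frame with `neuron_id`, `outcome`, `dprime`, `n_figure`,
#'   `n_ground`.
#' @export
outcome_dprimes <- function(neurons, trials, min_trials = 2L) {
  tr <- trials[!trials$excluded & trials$response %in% c("hit", "error") &
                 !is.na(trials$reaction_time), , drop = FALSE]
  rows <- list()
  for (i in seq_along(neurons)) {
    st <- neurons[[i]]$spike_times
    lo <- findInterval(tr$stimulus_onset - 1e-12, st)
    hi <- findInterval(tr$stimulus_onset + tr$reaction_time - 1e-12, st)
    resp <- (hi - lo) / tr$reaction_time
    for (oc in c("hit", "error")) {
      f <- resp[tr$response == oc & tr$stimulus == "figure"]
      g <- resp[tr$response == oc & tr$stimulus == "ground"]
      if (length(f) >= min_trials && length(g) >= min_trials) {
        dp <- suppressWarnings(dprime(f, g))
        rows[[length(rows) + 1L]] <-
          data.frame(neuron_id = neurons[[i]]$neuron_id, outcome = oc,
                     dprime = dp, n_figure = length(f), n_ground = length(g),
                     stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no neuron has enough hit and error trials")
  out
}

#' Pool outcome d-primes across recording sessions
#'
#' Neurons recorded in different sessions share their session's trials, so
#' their hit/error d-primes carry a common session-level component (the
#' same reaction-time windows enter every neuron's responses). Pooling
#' sessions with explicit session labels lets [hit_error_dprime()] absorb
#' that component in a session-by-outcome random term.
#'
#' @param sessions list of `list(neurons =, trials =)` pairs, one per
#'   session.
#' @param min_trials minimum trials per stimulus-by-outcome cell.
#' @return the [outcome_dprimes()] table with session-qualified neuron ids
#'   and a `session` column.
#' @export
pooled_outcome_dprimes <- function(sessions, min_trials = 2L) {
  nm <- names(sessions) %||% sprintf("s%02d", seq_along(sessions))
  out <- do.call(rbind, lapply(seq_along(sessions), function(s) {
    dp <- outcome_dprimes(sessions[[s]]$neurons, sessions[[s]]$trials,
                          min_trials)
    dp$session <- nm[s]
    dp$neuron_id <- paste(nm[s], dp$neuron_id, sep = "/")
    dp
  }))
  out
}

#' Hit versus error discriminability with mixed-model selection
#'
#' Computes the per-neuron outcome-split d-primes and compares mixed models
#' of increasing complexity -- intercept-only versus an outcome fixed
#' effect, both with a random intercept per neuron (plus a
#' session-by-outcome random intercept when the table spans several
#' sessions) -- by AIC on maximum-likelihood fits. The outcome effect is
#' reported with a Satterthwaite-approximation p-value from the REML fit.
#'
#' @param neurons list of [neuron_recording()], or a pre-computed d-prime
#'   table from [outcome_dprimes()] / [pooled_outcome_dprimes()] (then
#'   `trials` is ignored).
#' @param trials trial table (single-session interface).
#' @param min_trials minimum trials per stimulus-by-outcome cell.
#' @return object of class `dprime_result`: list with `dprimes` (the
#'   per-neuron table), `mean_hit`, `mean_error`, `aic` (per model),
#'   `best_model`, `effect` (hit-minus-error estimate), `p`
#'   (Satterthwaite).
#' @export
hit_error_dprime <- function(neurons, trials = NULL, min_trials = 2L) {
  dp <- if (is.data.frame(neurons)) neurons else
    outcome_dprimes(neurons, trials, min_trials)
  dp <- dp[is.finite(dp$dprime), , drop = FALSE]
  both <- intersect(dp$neuron_id[dp$outcome == "hit"],
                    dp$neuron_id[dp$outcome == "error"])
  dp <- dp[dp$neuron_id %in% both, , drop = FALSE]
  if (length(both) < 3L) stop("need at least 3 neurons with both outcomes")
  dp$outcome <- factor(dp$outcome, levels = c("error", "hit"))
  multi <- !is.null(dp$session) && length(unique(dp$session)) > 1L
  f1 <- if (multi) {
    dprime ~ outcome + (1 | neuron_id) + (1 | session:outcome)
  } else {
    dprime ~ outcome + (1 | neuron_id)
  }
  f0 <- if (multi) {
    dprime ~ 1 + (1 | neuron_id) + (1 | session:outcome)
  } else {
    dprime ~ 1 + (1 | neuron_id)
  }
  quiet <- function(expr) suppressWarnings(suppressMessages(expr))
  m0 <- quiet(lme4::lmer(f0, data = dp, REML = FALSE))
  m1 <- quiet(lme4::lmer(f1, data = dp, REML = FALSE))
  aics <- c(intercept_only = AIC(m0), outcome = AIC(m1))
  mt <- quiet(lmerTest::lmer(f1, data = dp, REML = TRUE))
  ct <- stats::coef(summary(mt))
  structure(list(dprimes = dp,
                 mean_hit = mean(dp$dprime[dp$outcome == "hit"]),
                 mean_error = mean(dp$dprime[dp$outcome == "error"]),
                 aic = aics,
                 best_model = names(aics)[which.min(aics)],
                 effect = unname(ct["outcomehit", "Estimate"]),
                 p = unname(ct["outcomehit", "Pr(>|t|)"])),
            class = "dprime_result")
}
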