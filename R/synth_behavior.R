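## Synthetic behavioral sessions: accuracy follows a logistic function of the
## laser-onset latency, emulating optogenetic silencing of the superior
## colliculus at graded delays after stimulus onset.

#' Specification for a synthetic behavioral session
#'
#' Defaults describe a task in which accuracy recovers from near-chance at
#' the earliest silencing onset to the no-laser ceiling, with the logistic
#' midpoint at 99 ms -- the regime the behavioral analyses are designed for.
#'
#' @param p_floor accuracy at the earliest laser onset (>= 0.5).
#' @param p_ceiling no-laser accuracy (>= `p_floor`, <= 1).
#' @param inflection logistic midpoint, seconds of laser-onset latency.
#' @param slope logistic slope, 1/seconds.
#' @param latencies laser-onset latencies sampled in the session (seconds).
#' @param trials_per_latency trials recorded at each latency (per mouse).
#' @param n_no_laser number of no-laser trials.
#' @param miss_rate per-trial probability of a miss (no lick).
#' @param seed integer seed.
#' @return a list of class `behavior_gen_spec`.
#' @export
behavior_gen_spec <- function(p_floor = 0.55, p_ceiling = 0.85,
                              inflection = 0.099, slope = 50,
                              latencies = seq(0, 0.2, by = 0.025),
                              trials_per_latency = 40L, n_no_laser = 40L,
                              miss_rate = 0.05, seed = 1L) {
  if (!(p_floor >= 0.5 && p_floor <= p_ceiling && p_ceiling <= 1)) {
    stop("need 0.5 <= p_floor <= p_ceiling <= 1")
  }
  if (inflection < min(latencies) || inflection > max(latencies)) {
    stop("inflection must lie within the latency range")
  }
  structure(list(p_floor = p_floor, p_ceiling = p_ceiling,
                 inflection = inflection, slope = slope,
                 latencies = as.numeric(latencies),
                 trials_per_latency = as.integer(trials_per_latency),
                 n_no_laser = as.integer(n_no_laser),
                 miss_rate = miss_rate, seed = as.integer(seed)),
            class = "behavior_gen_spec")
}

#' Logistic accuracy curve used by the behavior generator and fitter
#'
#' `p(t) = floor + (ceiling - floor) / (1 + exp(-slope * (t - inflection)))`.
#'
#' @param t laser-onset latency, seconds.
#' @param floor,ceiling,inflection,slope curve parameters.
#' @return accuracy at `t`.
#' @export
logistic_accuracy <- function(t, floor, ceiling, inflection, slope) {
  floor + (ceiling - floor) / (1 + exp(-slope * (t - inflection)))
}

#' Generate a synthetic behavioral trial table
#'
#' Hit probability at each laser-onset latency follows the logistic of the
#' spec; misses are drawn independently at `miss_rate`; no-laser trials are
#' drawn at `p_ceiling`. A pure function of spec + seed.
#'
#' @param spec a [behavior_gen_spec()].
#' @param mouse mouse id for the `mouse` column.
#' @param task task label (contrast/orientation/phase).
#' @return a [as_trial_table()] trial table with a `"truth"` attribute
#'   holding the generating parameters.
#' @export
gen_behavior <- function(spec, mouse = "m1", task = "contrast") {
  stopifnot(inherits(spec, "behavior_gen_spec"))
  with_seed_if(spec$seed, {
    lat <- c(rep(spec$latencies, each = spec$trials_per_latency),
             rep(NA_real_, spec$n_no_laser))
    n <- length(lat)
    p_hit <- ifelse(is.na(lat), spec$p_ceiling,
                    logistic_accuracy(lat, spec$p_floor, spec$p_ceiling,
                                      spec$inflection, spec$slope))
    miss <- runif(n) < spec$miss_rate
    hit <- runif(n) < p_hit
    response <- ifelse(miss, "miss", ifelse(hit, "hit", "error"))
    rt <- ifelse(miss, NA_real_, pmin(0.2 + rgamma(n, shape = 4, scale = 0.12), 1.99))
    df <- data.frame(trial_id = seq_len(n), mouse = mouse, task = task,
                     figure_side = sample(c("left", "right"), n, replace = TRUE),
                     background_orientation = sample(c(0, 90), n, replace = TRUE),
                     stimulus_onset = seq_len(n) * 10,
                     response = response, reaction_time = rt, laser_onset = lat,
                     stringsAsFactors = FALSE)
    out <- as_trial_table(df)
    attr(out, "truth") <- list(p_hit = p_hit, spec = spec)
    out
  })
}
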