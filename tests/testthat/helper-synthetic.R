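# Shared fixture builders: everything is generated in code at test time.

# minimal hand-built trial table
make_trials <- function(n = 10L, response = rep("hit", n), task = "orientation",
                        stimulus = rep(c("figure", "ground"), length.out = n),
                        onset_spacing = 2, mouse = "m1",
                        reaction_time = ifelse(response == "miss", NA_real_, 0.6),
                        laser_onset = NA_real_) {
  as_trial_table(data.frame(
    trial_id = seq_len(n), mouse = mouse, task = task,
    figure_side = ifelse(stimulus == "figure", "left", "right"),
    stimulus_onset = 1 + (seq_len(n) - 1L) * onset_spacing,
    stimulus = stimulus, response = response,
    reaction_time = reaction_time, laser_onset = laser_onset,
    stringsAsFactors = FALSE))
}

# regular (deterministic) spike train at `rate` sp/s across each trial's
# [win[1], win[2]) plus `extra_rate` sp/s confined to `extra_win`
make_regular_neuron <- function(trials, rate, extra_rate = 0,
                                extra_win = c(0.05, 0.20), win = c(-0.3, 0.6),
                                id = "n001") {
  st <- unlist(lapply(trials$stimulus_onset, function(on) {
    base <- if (rate > 0) on + seq(win[1], win[2] - 1e-9, by = 1 / rate) else numeric(0)
    ext <- if (extra_rate > 0) {
      on + seq(extra_win[1], extra_win[2] - 1e-9, by = 1 / (extra_rate / 1))
    } else numeric(0)
    c(base, ext)
  }))
  neuron_recording(id, sort(st))
}

# multi-mouse behavioral session at the study's scale
make_behavior_cohort <- function(n_mice = 8L, trials_per_latency = 40L,
                                 inflection = 0.099, seed = 100L) {
  tabs <- lapply(seq_len(n_mice), function(m) {
    gen_behavior(behavior_gen_spec(trials_per_latency = trials_per_latency,
                                   inflection = inflection, seed = seed + m),
                 mouse = sprintf("m%d", m))
  })
  out <- do.call(rbind, tabs)
  out$trial_id <- seq_len(nrow(out))
  as_trial_table(out)
}

# small ephys session: trials + spikes (+ constants) in one call
make_ephys <- function(..., spacing = 2) {
  spec <- ephys_gen_spec(...)
  trials <- gen_ephys_trials(spec, spacing = spacing)
  neurons <- gen_spikes(spec, trials)
  list(spec = spec, trials = trials, neurons = neurons)
}
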