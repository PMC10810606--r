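test_that("visual inclusion transitions at 3 spikes/s evoked", {
  tr <- make_trials(10L, stimulus = rep("figure", 10L))
  # deterministic trains: baseline 5 sp/s everywhere plus T extra spikes in
  # the 50-200 ms visual window spread over the 10 trials, so the evoked
  # rate is exactly T / (10 * 0.15) sp/s
  with_extras <- function(T) {
    st <- make_regular_neuron(tr, rate = 5)$spike_times
    extra <- tr$stimulus_onset[seq_len(T)] + 0.12
    neuron_recording("nx", sort(c(st, extra)))
  }
  evoked <- vapply(0:8, function(T) visual_inclusion(with_extras(T), tr)$evoked,
                   numeric(1))
  expect_equal(evoked, (0:8) / 1.5, tolerance = 1e-9)
  inc <- vapply(0:8, function(T) visual_inclusion(with_extras(T), tr)$included,
                logical(1))
  # threshold 3 sp/s crossed between T = 4 (2.67) and T = 5 (3.33)
  expect_identical(inc, (0:8) / 1.5 >= 3)
})

test_that("normalisation maps baseline to 0 and peak to 1, and is idempotent", {
  e <- make_ephys(n_neurons = 3L, n_figure = 20L, n_ground = 20L,
                  visual_gain = 15, seed = 71L)
  cst <- normalization_constants(e$neurons, e$trials)
  expect_false(any(cst$degenerate))
  pt <- population_traces(e$neurons, e$trials, window = c(-0.15, 0.3))
  base_bins <- pt$time < 0
  peak_bins <- pt$time >= 0.05 & pt$time < 0.20
  # in-RF mean trace (orientation task: all trials) hits 0 at baseline, 1 at peak
  avg <- (colMeans(pt$figure) + colMeans(pt$ground)) / 2
  expect_lt(abs(mean(avg[base_bins])), 0.05)
  expect_gt(max(avg[peak_bins]), 0.8)
  # affine map on a known matrix
  m <- matrix(c(2, 2, 12, 2), 1, 4)
  out <- normalize_responses(m, data.frame(neuron_id = "a", baseline = 2,
                                           rmax = 12, degenerate = FALSE))
  expect_equal(out$traces[[1]], matrix(c(0, 0, 1, 0), 1, 4))
  # degenerate neuron flagged
  outd <- normalize_responses(m, data.frame(neuron_id = "a", baseline = 2,
                                            rmax = 2, degenerate = TRUE))
  expect_null(outd$traces[[1]])
  # constants do not depend on trial order
  shuf <- e$trials[sample.int(nrow(e$trials)), ]
  cst2 <- normalization_constants(e$neurons, shuf)
  expect_equal(cst$baseline, cst2$baseline, tolerance = 1e-12)
  expect_equal(cst$rmax, cst2$rmax, tolerance = 1e-12)
})

test_that("exact closed-form per-bin F equals the per-bin mixed model", {
  for (s in c(77L, 78L)) {
    e <- make_ephys(n_neurons = 8L, n_figure = 10L, n_ground = 10L, seed = s)
    pt <- population_traces(e$neurons, e$trials, window = c(0, 0.2))
    exact <- cluster_permutation_test(pt$figure, pt$ground, pt$time,
                                      n_perm = 10L, seed = 1L, engine = "exact")
    ref <- cluster_permutation_test(pt$figure, pt$ground, pt$time,
                                    n_perm = 10L, seed = 1L, engine = "lmer")
    expect_equal(exact$per_bin_F, ref$per_bin_F, tolerance = 1e-5)
  }
})

test_that("cluster test finds injected modulation and nothing in null data", {
  e <- make_ephys(n_neurons = 20L, n_figure = 30L, n_ground = 30L,
                  fgm_amplitude = 10, fgm_onset = 0.075, seed = 81L)
  pt <- population_traces(e$neurons, e$trials)
  ct <- cluster_permutation_test(pt$figure, pt$ground, pt$time,
                                 n_perm = 500L, seed = 2L)
  sig <- significant_clusters(ct)
  expect_gt(nrow(sig), 0L)
  # a significant cluster overlaps the generated modulation window
  expect_true(any(sig$t_start < 0.175 & sig$t_end > 0.085))
  expect_true(all(ct$clusters$p_perm >= 1 / (ct$n_perm + 1)))
  # identical figure and ground -> no clusters at all
  ct0 <- cluster_permutation_test(pt$figure, pt$figure, pt$time,
                                  n_perm = 100L, seed = 3L)
  expect_equal(nrow(ct0$clusters), 0L)
})

test_that("modulation latency is scale-invariant and recovered on a known ramp", {
  # constructed trace whose 33% crossing is known by construction
  tt <- seq(0.005, 0.295, by = 0.01)
  ramp <- pmin(pmax((tt - 0.055) / 0.036, 0), 1) * exp(-pmax(tt - 0.15, 0) / 0.1)
  # the rising flank is linear, so the crossing is analytic
  truth <- 0.055 + 0.33 * max(ramp) * 0.036
  expect_equal(truth, 0.067, tolerance = 2e-3)
  fit <- fit_fgm_latency(ramp, tt)
  expect_true(fit$converged)
  expect_lt(abs(fit$latency - truth), 0.005)
  # scaling the trace leaves the fractional criterion unchanged
  fit10 <- fit_fgm_latency(10 * ramp, tt)
  expect_equal(fit10$latency, fit$latency, tolerance = 1e-3)
  # degenerate traces are flagged, not fitted
  expect_false(fit_fgm_latency(rep(0, length(tt)), tt)$converged)
  expect_false(fit_fgm_latency(-ramp, tt)$converged)
})

test_that("opto suppression recovers the generated rate reduction", {
  expect_equal(opto_suppression(5, 5)$mean_reduction, 0)
  expect_equal(opto_suppression(0, 5)$mean_reduction, 100)
  # 76% scaling with Poisson sampling noise
  withr::with_seed(91L, {
    off <- rpois(200, 400) / 20          # evoked rates ~ 20 sp/s
    on <- rpois(200, 400 * 0.24) / 20
  })
  res <- opto_suppression(on, off)
  expect_equal(res$mean_reduction, 76, tolerance = 1.5)
  # sub-threshold units are excluded
  res2 <- opto_suppression(c(1, 10), c(1.5, 20), evoked_off = c(1.5, 19))
  expect_identical(res2$included, c(FALSE, TRUE))
})
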