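test_that("emua envelope passes its band and rejects out-of-band power", {
  fs <- 20000
  tt <- seq(0, 1, by = 1 / fs)[-1]
  in_band <- sin(2 * pi * 2000 * tt)
  out_band <- sin(2 * pi * 50 * tt)
  raw <- channel_data(rbind(in_band, out_band), sample_rate = fs)
  env <- compute_emua(raw)
  mid <- 5000:15000
  expect_gt(mean(env$samples[1, mid]), 0.2)
  expect_lt(mean(abs(env$samples[2, mid])), 0.02)
  # all-zero input -> all-zero envelope
  z <- compute_emua(channel_data(matrix(0, 2, 4000), sample_rate = fs))
  expect_true(all(z$samples == 0))
  # injected broadband burst -> envelope peak at the burst
  x <- matrix(rnorm(2 * fs, 0, 0.1), 2)
  x[, 10000:10010] <- x[, 10000:10010] + 8
  envb <- compute_emua(channel_data(x, sample_rate = fs))
  expect_true(all(abs(apply(envb$samples[, mid], 1, which.max) + min(mid) - 1 -
                        10005) < 200))
  expect_error(compute_emua(channel_data(matrix(0, 2, 100), sample_rate = 9000)),
               "Nyquist")
})

test_that("consensus statistic equals the brute-force geometric mean", {
  # 8 channels x 100 samples x 5 trials of standard noise
  withr::with_seed(21L, ep <- array(rnorm(8 * 100 * 5), c(8, 100, 5)))
  res <- reject_artifact_samples(ep, threshold = Inf)
  # independent oracle: z-score each channel by hand, product^(1/n)
  for (tr in c(1L, 4L)) {
    for (s in c(3L, 50L, 97L)) {
      z <- vapply(1:8, function(c) {
        v <- ep[c, , ]
        abs((ep[c, s, tr] - mean(v)) / sd(v))
      }, numeric(1))
      expect_equal(res$Z[s, tr], prod(z + 1e-12)^(1 / 8), tolerance = 1e-12)
    }
  }
})

test_that("majority-channel excursions are masked with padding, single-channel ones are not", {
  withr::with_seed(22L, ep <- array(rnorm(8 * 100 * 4), c(8, 100, 4)))
  ep[, 40, 2] <- ep[, 40, 2] + 20          # all channels excursion
  res <- reject_artifact_samples(ep)
  expect_true(all(res$mask[37:43, 2]))     # +/-3 samples of padding
  expect_false(any(res$mask[, c(1, 3, 4)]))
  expect_true(all(is.na(res$Z[37:43, 2])))

  withr::with_seed(23L, ep1 <- array(rnorm(8 * 100 * 4), c(8, 100, 4)))
  ep1[1, 40, 2] <- ep1[1, 40, 2] + 50      # one channel only
  res1 <- reject_artifact_samples(ep1)
  expect_false(res1$mask[40, 2])

  # monotonicity: injecting one more artifact can only grow the mask
  ep2 <- ep
  ep2[, 70, 3] <- ep2[, 70, 3] + 20
  res2 <- reject_artifact_samples(ep2)
  expect_true(all(which(res$mask) %in% which(res2$mask)))

  # no excursion above threshold -> empty mask, Z returned unchanged
  withr::with_seed(24L, ep3 <- array(rnorm(4 * 50 * 30), c(4, 50, 30)))
  res3 <- reject_artifact_samples(ep3)
  expect_equal(res3$n_removed, 0L)
  expect_equal(res3$Z, res3$Z_pre)
  expect_error(reject_artifact_samples(array(1, c(4, 50, 30))), "zero variance")
})

test_that("chi rule removes injected artifact trials, spares clean ones", {
  tr <- gen_ephys_trials(ephys_gen_spec(n_figure = 50L, n_ground = 50L,
                                        seed = 31L), spacing = 0.3)
  g <- gen_emua_channels(8L, tr, trial_artifact_rate = 0.05, seed = 32L)
  env <- compute_emua(g$channels)
  ep <- epoch_channels(env, tr, g$trial_window)
  ras <- reject_artifact_samples(ep)
  rat <- reject_artifact_trials(ras$Z, tr)
  injected <- g$truth$trial_artifacts
  expect_gte(sum(injected %in% rat$removed) / length(injected), 0.9)
  clean <- setdiff(tr$trial_id, injected)
  expect_lte(sum(rat$removed %in% clean) / length(clean), 0.02)
  expect_true(all(rat$trials$exclusion_reason[rat$trials$trial_id %in%
                                                rat$removed] == "emua_artifact"))
  # homogeneous noise: expected removals are the 3-sigma Gaussian tail
  g0 <- gen_emua_channels(8L, tr, seed = 33L)
  ep0 <- epoch_channels(compute_emua(g0$channels), tr, g0$trial_window)
  r0 <- reject_artifact_trials(reject_artifact_samples(ep0)$Z, tr)
  expect_lte(length(r0$removed) / nrow(tr), 0.05)
  # identical trials -> degenerate
  Zsame <- matrix(1, 100, 30)
  expect_error(reject_artifact_trials(Zsame, tr[1:30, ]), "degenerate")
})

test_that("eye-speed exclusion finds exactly the extreme trials", {
  tr <- gen_ephys_trials(ephys_gen_spec(n_figure = 25L, n_ground = 25L,
                                        seed = 41L))
  # constant-position eye: zero speeds, nothing excluded
  ns <- ceiling((max(tr$stimulus_onset) + 1) * 500)
  still <- eye_trace(rep(3, ns), rep(-1, ns), rep(1, ns), sample_rate = 500)
  ex0 <- exclude_eye_trials(still, tr)
  expect_length(ex0$excluded, 0L)
  expect_true(all(ex0$speeds == 0, na.rm = TRUE))

  # labeled large saccades are all excluded
  g <- gen_eye(tr, saccade_rate = 0.1, amplitude_deg = 15, seed = 42L)
  ex <- exclude_eye_trials(g$eye, tr)
  expect_setequal(ex$excluded, g$truth$saccade_trials)

  # exactly one extreme trial among many
  g1 <- gen_eye(tr, saccade_rate = 0, seed = 43L)
  x <- g1$eye$x
  i0 <- round((tr$stimulus_onset[7] + 0.2) * 500)
  x[i0:length(x)] <- x[i0:length(x)] + 20
  ex1 <- exclude_eye_trials(eye_trace(x, g1$eye$y, g1$eye$pupil, 500), tr)
  expect_identical(ex1$excluded, tr$trial_id[7])

  # trace gap -> flagged "other"
  short <- eye_trace(rep(0, 1000), rep(0, 1000), rep(1, 1000), sample_rate = 500)
  exg <- exclude_eye_trials(short, tr)
  expect_true(all(exg$trials$exclusion_reason[exg$trials$trial_id %in% exg$gap]
                  == "other"))
  expect_gt(length(exg$gap), 0L)
})

test_that("spike smoothing conserves counts and matches known rates", {
  tr <- make_trials(1L)
  nr <- neuron_recording("n1", tr$stimulus_onset + 0.1)
  sm <- smooth_spikes(nr, tr, sd = 0.010, window = c(-0.3, 0.6))
  expect_equal(sum(sm$rates) * 0.001, 1, tolerance = 1e-6)
  expect_lt(abs(sm$time[which.max(sm$rates[1, ])] - 0.1), 2e-3)
  # empty train -> zero trace
  sm0 <- smooth_spikes(neuron_recording("n0", numeric(0)), tr)
  expect_true(all(sm0$rates == 0))
  # homogeneous Poisson at 10 sp/s -> mean trace near 10
  tr2 <- make_trials(100L)
  withr::with_seed(51L, {
    st <- sort(unlist(lapply(tr2$stimulus_onset, function(on) {
      on - 0.5 + runif(rpois(1, 15), 0, 1.5)
    })))
  })
  smp <- smooth_spikes(neuron_recording("np", st), tr2)
  expect_equal(mean(smp$rates), 10, tolerance = 0.5)
  # multi-spike count conservation
  tr1 <- make_trials(1L)
  nr2 <- neuron_recording("n2", tr1$stimulus_onset + c(-0.1, 0.05, 0.2, 0.21))
  sm2 <- smooth_spikes(nr2, tr1, window = c(-0.3, 0.6))
  expect_equal(sum(sm2$rates) * 0.001, 4, tolerance = 1e-6)
  # pooled condition PSTH equals the mean of per-trial traces (linearity)
  ps <- condition_psth(neuron_recording("np", st), tr2)
  expect_equal(ps$rate, colMeans(smp$rates), tolerance = 1e-10)
})

test_that("common average referencing zeroes the across-channel mean", {
  withr::with_seed(61L, x <- matrix(rnorm(6 * 500), 6, 500))
  car <- common_average_reference(channel_data(x, 20000))
  expect_lt(max(abs(colMeans(car$samples))), 1e-12)
  # identical channels -> all zero
  same <- channel_data(matrix(rep(sin(1:300), each = 4), 4, 300), 20000)
  expect_true(all(abs(common_average_reference(same)$samples) < 1e-12))
  # common offsets are invisible
  shifted <- channel_data(sweep(x, 2, rnorm(500), `+`), 20000)
  expect_equal(common_average_reference(shifted)$samples, car$samples,
               tolerance = 1e-10)
})

test_that("depth assignment finds the CSD sink and spaces depths by the probe", {
  fs <- 1000
  nt <- 6000
  tt <- (0:(nt - 1)) / fs
  trd <- make_trials(4L, onset_spacing = 1)
  # dipole: negative LFP deflection sharpest at channel 12
  prof <- -exp(-((1:32) - 12)^2 / 4)
  resp <- vapply(tt, function(t) {
    s <- (t - floor(t)) # within-second phase; onsets at integer+0 s
    exp(-(s - 0.06)^2 / 0.002)
  }, numeric(1))
  lfp <- channel_data(outer(prof, resp) + matrix(rnorm(32 * nt, 0, 1e-5), 32),
                      sample_rate = fs)
  dm <- assign_depths(lfp, trd, lp_cutoff = 200)
  expect_identical(dm$sink_channel, 12L)
  expect_false(dm$flagged)
  expect_equal(dm$depth_per_channel[12], 119)
  expect_equal(unique(diff(dm$depth_per_channel)), 25)
  # flat LFP -> flagged, no sink
  flat <- channel_data(matrix(0, 32, nt), sample_rate = fs)
  dmf <- assign_depths(flat, trd, notch = FALSE)
  expect_true(dmf$flagged)
  expect_true(is.na(dmf$sink_channel))
})
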