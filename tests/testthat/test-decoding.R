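test_that("decoding inclusion requires five trials of each stimulus class", {
  t5 <- make_trials(10L, stimulus = rep(c("figure", "ground"), each = 5))
  t54 <- make_trials(9L, stimulus = rep(c("figure", "ground"), c(5, 4)))
  ids <- select_decoding_neurons(list(a = t5, b = t54))
  expect_identical(ids, "a")
  # exclusions count against the requirement
  t5x <- t5; t5x$excluded[1] <- TRUE; t5x$exclusion_reason[1] <- "other"
  expect_length(select_decoding_neurons(list(a = t5x)), 0L)
  # synthetic population with known counts
  e <- make_ephys(n_neurons = 3L, n_figure = 5L, n_ground = 5L, seed = 1L)
  ids2 <- select_decoding_neurons(rep(list(e$trials), 3L),
                                  neuron_ids = c("n001", "n002", "n003"))
  expect_identical(ids2, c("n001", "n002", "n003"))
})

test_that("sliding windows cover a 0-250 ms epoch in exactly 21 steps", {
  w <- decoding_windows(c(0, 0.25))
  expect_identical(nrow(w), 21L)
  expect_equal(w$start, seq(0, 0.20, by = 0.01))
  expect_equal(w$end - w$start, rep(0.05, 21))
  expect_error(decoding_windows(c(0, 0.03)), "shorter")
})

test_that("d-prime matches its closed form and is antisymmetric", {
  expect_equal(dprime(c(0, 2), c(-1, 1)), 1 / sqrt(2))
  f <- c(1.2, 0.8, 1.0, 1.1); g <- c(0.1, -0.1, 0.2, 0)
  expect_equal(dprime(f, g),
               (mean(f) - mean(g)) / sqrt((var(f) + var(g)) / 2))
  expect_equal(dprime(f, g), -dprime(g, f))
  expect_equal(dprime(f, f), 0)
  expect_warning(dp <- dprime(c(1, 1), c(0, 0)), "zero variance")
  expect_true(is.na(dp))
  # Monte Carlo agreement with the analytic value at unit separation
  withr::with_seed(11L, {
    mc <- dprime(rnorm(1e4, 1, 1), rnorm(1e4, 0, 1))
  })
  expect_lt(abs(mc - 1), 3 * sqrt(3 / 1e4))
  expect_error(dprime(1, c(1, 2)), "2 trials")
})

test_that("Holm adjustment matches an independent step-down reference", {
  holm_ref <- function(p) {
    n <- length(p)
    o <- order(p)
    adj <- pmin(cummax((n - seq_len(n) + 1) * p[o]), 1)
    out <- numeric(n); out[o] <- adj
    out
  }
  withr::with_seed(12L, {
    for (k in c(3L, 21L, 50L)) {
      p <- runif(k)^2
      res <- list(n_correct = NA, n_boot = NA)
      expect_equal(p.adjust(p, "holm"), holm_ref(p), tolerance = 1e-15)
    }
  })
  # through the decoding interface: performance 0.5 -> adjusted p = 1
  res <- list(n_correct = c(250L, 320L), n_boot = 500L)
  p <- decode_significance(res)
  expect_equal(p[1], 1)
  expect_true(all(p >= vapply(res$n_correct, function(k) {
    binom.test(k, 500L, 0.5)$p.value
  }, numeric(1))))
})

test_that("bootstrap decoder is exact on separable and on constant features", {
  # perfectly separable features: every bootstrap must classify correctly
  sep <- replicate(3, list(figure = c(0.9, 1.0, 1.1, 1.05, 0.95, 1.0),
                           ground = c(-1.1, -1.0, -0.9, -0.95, -1.05, -1.0)),
                   simplify = FALSE)
  res <- decode_bootstrap(sep, n_boot = 60L, seed = 2L)
  expect_equal(res$performance, 1)
  # completely uninformative (identical constant) features: the decoder
  # degenerates to a constant prediction, and the alternating balanced test
  # schedule pins the expected performance at exactly 1/2
  flat <- replicate(3, list(figure = rep(1, 6), ground = rep(1, 6)),
                    simplify = FALSE)
  resf <- decode_bootstrap(flat, n_boot = 60L, seed = 3L)
  expect_equal(resf$performance, 0.5)
  # duplicating every neuron leaves performance at ceiling unchanged
  res2 <- decode_bootstrap(c(sep, sep), n_boot = 60L, seed = 4L)
  expect_equal(res2$performance, 1)
  # determinism
  expect_identical(decode_bootstrap(sep, n_boot = 30L, seed = 5L)$performance,
                   decode_bootstrap(sep, n_boot = 30L, seed = 5L)$performance)
})

test_that("decoder weights carry the sign and scale of neuronal selectivity", {
  withr::with_seed(21L, {
    pos <- list(figure = rnorm(12, 1, 0.3), ground = rnorm(12, -1, 0.3))
    neg <- list(figure = rnorm(12, -1, 0.3), ground = rnorm(12, 1, 0.3))
    null <- list(figure = rnorm(12, 0, 0.3), ground = rnorm(12, 0, 0.3))
  })
  res <- decode_bootstrap(list(pos, neg, null), n_boot = 100L, seed = 6L)
  w <- colMeans(res$weights)
  expect_gt(w[1], 0)
  expect_lt(w[2], 0)
  expect_gt(abs(w[1]), abs(w[3]))
  rel <- extract_weights(res$weights)
  expect_equal(sum(abs(rel$relative_weight)), 1)
  # a single dominant neuron takes nearly all relative weight
  dom <- decode_bootstrap(list(pos, null, null), n_boot = 100L, seed = 7L)
  reld <- extract_weights(dom$weights)
  expect_gt(abs(reld$relative_weight[1]), 0.6)
  # weights follow a permutation of the neurons
  resp <- decode_bootstrap(list(null, neg, pos), n_boot = 100L, seed = 6L)
  wp <- colMeans(resp$weights)
  expect_gt(wp[3], 0)
  expect_lt(wp[2], 0)
})

test_that("shuffle null brackets chance and detects a real separation", {
  withr::with_seed(31L, {
    eff <- replicate(10, list(figure = rnorm(15, 1.2, 1),
                              ground = rnorm(15, 0, 1)), simplify = FALSE)
  })
  withr::with_seed(32L, {
    none <- replicate(10, list(figure = rnorm(15, 0, 1),
                               ground = rnorm(15, 0, 1)), simplify = FALSE)
  })
  sn_eff <- dprime_shuffle_null(eff, n_shuffle = 300L, seed = 8L)
  expect_true(sn_eff$above_null)
  expect_lt(abs(mean(sn_eff$null_mean)), 0.1)   # null centered on zero
  sn_none <- dprime_shuffle_null(none, n_shuffle = 300L, seed = 9L)
  expect_false(sn_none$above_null)
  expect_true(sn_none$observed_mean >= sn_none$ci[1] - 0.2)
})

test_that("outcome-split d-primes detect outcome-dependent modulation", {
  e <- make_ephys(n_neurons = 15L, n_figure = 50L, n_ground = 50L,
                  fgm_amplitude = 12, fgm_amplitude_error = 0,
                  hit_rate = 0.65, rate_noise_cv = 0.2, seed = 41L)
  res <- hit_error_dprime(e$neurons, e$trials)
  expect_gt(res$mean_hit, res$mean_error)
  expect_identical(res$best_model, "outcome")
  expect_lt(res$p, 0.05)
  # misses never enter (no outcome label)
  trm <- e$trials; trm$response[1] <- "miss"; trm$reaction_time[1] <- NA
  dp <- outcome_dprimes(e$neurons[1:3], trm)
  expect_true(all(dp$outcome %in% c("hit", "error")))
})
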