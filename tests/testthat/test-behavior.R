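test_that("accuracy follows hits/(hits+errors), with and without misses", {
  tr <- make_trials(50L, response = c(rep("hit", 26), rep("error", 14),
                                      rep("miss", 10)))
  acc <- compute_accuracy(tr, by = "condition")
  expect_equal(acc$accuracy, 26 / 40)
  acc_m <- compute_accuracy(tr, include_misses = TRUE, by = "condition")
  expect_equal(acc_m$accuracy, 26 / 50)

  # correction trials are dropped
  tr$is_correction[1:26] <- TRUE
  expect_equal(compute_accuracy(tr, by = "condition")$accuracy, 0 / 14)
  # zero denominator: undefined, not zero
  tr2 <- make_trials(3L, response = rep("miss", 3))
  acc2 <- compute_accuracy(tr2, by = "condition")
  expect_true(acc2$undefined)
  expect_true(is.na(acc2$accuracy))
  # invariance to trial order
  tr3 <- make_trials(40L, response = sample(c(rep("hit", 26), rep("error", 14))))
  expect_equal(compute_accuracy(tr3, by = "condition")$accuracy, 0.65)
})

test_that("session inclusion agrees with the exact binomial tail for n <= 200", {
  # independent oracle: one-sided tail by direct summation
  tail_p <- function(k, n) sum(choose(n, k:n) * 0.5^n)
  for (n in c(20L, 40L, 41L, 60L, 100L, 200L)) {
    hits <- ceiling(0.65 * n)
    tr <- make_trials(n, response = c(rep("hit", hits), rep("error", n - hits)))
    res <- session_inclusion(tr)
    if (n >= 40L) {
      expect_equal(res$p, tail_p(hits, n), tolerance = 1e-12)
      expect_identical(res$included, res$p < 0.05)
      expect_identical(res$rule, "binomial")
    } else {
      expect_identical(res$rule, "short")
    }
  }
  # n = 40, 26 hits: p ~ 0.0403 -> included
  tr <- make_trials(40L, response = c(rep("hit", 26), rep("error", 14)))
  res <- session_inclusion(tr)
  expect_equal(res$p, 0.0403, tolerance = 2e-3)
  expect_true(res$included)
  # n = 20, 13 hits (65%): binomial p ~ 0.1316 so the short rule applies;
  # both sides at 50%+ and accuracy 65% -> included
  tr20 <- make_trials(20L, response = c(rep("hit", 7), rep("error", 3),
                                        rep("hit", 6), rep("error", 4)),
                      stimulus = rep(c("figure", "ground"), each = 10))
  expect_equal(tail_p(13, 20), 0.1316, tolerance = 1e-3)
  res20 <- session_inclusion(tr20)
  expect_identical(res20$rule, "short")
  expect_true(res20$included)
  # n = 30, 20 hits but left-side accuracy 0.4 -> excluded
  side <- rep(c("figure", "ground"), c(10, 20))  # figure -> left
  resp <- c(rep("hit", 4), rep("error", 6), rep("hit", 16), rep("error", 4))
  tr30 <- make_trials(30L, response = resp, stimulus = side)
  res30 <- session_inclusion(tr30)
  expect_identical(res30$rule, "short")
  expect_false(res30$included)
  # empty -> excluded with a reason
  res0 <- session_inclusion(make_trials(2L, response = rep("miss", 2)))
  expect_false(res0$included)
  expect_match(res0$reason, "no scored")
})

test_that("psychometric fit recovers exact logistic data to 1e-6", {
  lat <- seq(0, 0.2, by = 0.02)
  truth <- c(floor = 0.56, ceiling = 0.88, inflection = 0.11, slope = 60)
  acc <- logistic_accuracy(lat, truth["floor"], truth["ceiling"],
                           truth["inflection"], truth["slope"])
  fit <- fit_psychometric(lat, acc)
  expect_true(fit$converged)
  expect_equal(unname(fit$params), unname(truth), tolerance = 1e-6)

  flat <- fit_psychometric(lat, rep(0.8, length(lat)))
  expect_false(flat$converged)
  expect_match(flat$reason, "flat")
  expect_false(fit_psychometric(lat[1:3], acc[1:3])$converged)
})

test_that("bootstrapped inflection recovers the generated midpoint", {
  trials <- make_behavior_cohort(n_mice = 4L, trials_per_latency = 60L,
                                 inflection = 0.100, seed = 200L)
  res <- bootstrap_inflection(trials, B = 200L, seed = 5L)
  expect_length(res$inflection_boot, 200L)
  expect_lt(abs(res$inflection_mean - 0.100), 0.02)
  expect_gt(res$inflection_sd, 0)
  # determinism under the same seed
  res2 <- bootstrap_inflection(trials, B = 200L, seed = 5L)
  expect_identical(res$inflection_boot, res2$inflection_boot)
})

test_that("repeated-measures ANOVA flags injected onset effects only", {
  onsets <- c("0.00", "0.05", "0.10", "no_laser")
  # null: mouse-specific levels, no onset dependence
  withr::with_seed(31L, {
    base <- runif(6, 0.6, 0.9)
    null_mat <- outer(base, rep(1, 4)) + matrix(rnorm(24, 0, 0.02), 6, 4)
    colnames(null_mat) <- onsets; rownames(null_mat) <- paste0("m", 1:6)
    effect <- c(-0.25, -0.15, -0.05, 0)
    eff_mat <- outer(base, rep(1, 4)) + matrix(effect, 6, 4, byrow = TRUE) +
      matrix(rnorm(24, 0, 0.02), 6, 4)
    colnames(eff_mat) <- onsets; rownames(eff_mat) <- paste0("m", 1:6)
  })
  expect_gt(onset_effect_anova(null_mat)$p, 0.05)
  res <- onset_effect_anova(eff_mat)
  expect_lt(res$p, 0.05)
  expect_identical(res$pairwise$reference[1], "no_laser")
  expect_true(all(res$pairwise$p_bonferroni >= res$pairwise$p_raw))
  # earliest onset must differ most clearly from no-laser
  expect_lt(res$pairwise$p_bonferroni[1], 0.05)
  null_mat[2, 3] <- NA
  expect_error(onset_effect_anova(null_mat), "m2")
})

test_that("reaction-time summaries aggregate within mouse first", {
  tr <- make_trials(3L, response = c("hit", "error", "miss"),
                    reaction_time = c(0.45, 0.45, NA))
  out <- response_summaries(tr)
  expect_equal(out$mean_reaction_time, 0.45)
  expect_equal(out$response_rate, 2 / 3)
  # the mouse, not the trial, is the statistical unit
  a <- make_trials(10L, response = rep("hit", 10), reaction_time = 0.3)
  b <- make_trials(2L, response = rep("hit", 2), reaction_time = 0.9,
                   mouse = "m2")
  b$trial_id <- 11:12
  both <- as_trial_table(rbind(a, b))
  expect_equal(response_summaries(both)$mean_reaction_time, 0.6)
})
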