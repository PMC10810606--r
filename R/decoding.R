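## Pseudo-population decoding of figure vs. ground with a balanced
## bootstrap linear SVM, sliding-window significance, weight extraction,
## and d-prime discriminability including the hit/error comparison.

#' Select neurons eligible for decoding
#'
#' A neuron enters the pseudo-population iff it has at least `min_trials`
#' figure and `min_trials` ground trials (after exclusions) in the given
#' task.
#'
#' @param trial_sets a list per neuron of that neuron's trial table (use
#'   `rep(list(trials), n)` when all neurons share a session), or a single
#'   trial table applied to every neuron.
#' @param neuron_ids character ids aligned with `trial_sets`.
#' @param task restrict to one task (default: all trials in the set).
#' @param min_trials minimum trials per stimulus class (default 5).
#' @return character vector of included ids.
#' @export
select_decoding_neurons <- function(trial_sets, neuron_ids = names(trial_sets),
                                    task = NULL, min_trials = 5L) {
  stopifnot(is.list(trial_sets))
  ok <- vapply(trial_sets, function(tr) {
    tr <- tr[!tr$excluded, , drop = FALSE]
    if (!is.null(task)) tr <- tr[tr$task == task, , drop = FALSE]
    sum(tr$stimulus == "figure") >= min_trials &&
      sum(tr$stimulus == "ground") >= min_trials
  }, logical(1))
  neuron_ids[ok]
}

#' Per-neuron decoding features for one time window
#'
#' Normalised per-trial rates (spike count in the window divided by its
#' width, mapped through each neuron's normalisation constants), split into
#' figure and ground trials.
#'
#' @param neurons list of [neuron_recording()].
#' @param trials trial table (non-excluded trials are used).
#' @param constants data.frame from [normalization_constants()].
#' @param window time window, seconds relative to stimulus onset.
#' @return list per neuron of `list(figure = , ground = )` response
#'   vectors.
#' @export
decoding_features <- function(neurons, trials, constants, window) {
  tr <- trials[!trials$excluded, , drop = FALSE]
  r <- window_rates(neurons, tr, window)
  lapply(seq_along(neurons), function(i) {
    z <- (r[i, ] - constants$baseline[i]) /
      (constants$rmax[i] - constants$baseline[i])
    list(figure = z[tr$stimulus == "figure"],
         ground = z[tr$stimulus == "ground"])
  })
}

# train a linear SVM (cost 1, standardized features) and return the
# prediction for x_test plus weights oriented so that positive weight means
# higher response on figure trials pushes the decision toward "figure"
svm_decide <- function(X, y, x_test) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, `/`)
  fit <- e1071::svm(Xs, factor(y, levels = c("figure", "ground")),
                    kernel = "linear", cost = 1, scale = FALSE)
  w <- as.numeric(crossprod(fit$coefs, fit$SV))
  rho <- fit$rho
  # decision value d(x) = w . x - rho; check which side "figure" lies on
  d_train <- Xs %*% w - rho
  if (mean(d_train[y == "figure"]) < mean(d_train[y == "ground"])) {
    w <- -w; rho <- -rho
  }
  xt <- (x_test - mu) / sdv
  list(pred = if (sum(xt * w) - rho > 0) "figure" else "ground",
       weights = w)
}

#' Balanced bootstrap decoding for one time window
#'
#' Each bootstrap holds out one random trial per neuron of the test class
#' (alternating figure/ground across repeats so test sets stay balanced) to
#' form one test pseudo-trial, draws `n_train` trials of each stimulus type
#' per neuron with replacement from the remaining data as the training set,
#' trains a linear maximum-margin classifier (unit cost, feature
#' standardisation), and classifies the held-out pseudo-trial. Performance
#' is the fraction of correct bootstraps.
#'
#' @param features list per neuron of `list(figure=, ground=)` response
#'   vectors (see [decoding_features()]).
#' @param n_boot bootstrap repetitions (default 2000).
#' @param n_train training pseudo-trials per class (default 10).
#' @param seed integer seed.
#' @return list with `performance`, `correct` (logical per bootstrap),
#'   `weights` (`[n_boot, neurons]`), `n_boot`.
#' @export
decode_bootstrap <- function(features, n_boot = 2000L, n_train = 10L,
                             seed = 1L) {
  nn <- length(features)
  if (nn < 2L) stop("need at least 2 neurons to decode")
  for (i in seq_len(nn)) {
    if (length(features[[i]]$figure) < 2L || length(features[[i]]$ground) < 2L) {
      stop("neuron ", i, " has fewer than 2 trials in a class")
    }
  }
  with_seed_if(seed, {
    correct <- logical(n_boot)
    W <- matrix(NA_real_, n_boot, nn)
    y <- rep(c("figure", "ground"), each = n_train)
    for (b in seq_len(n_boot)) {
      test_class <- if (b %% 2L == 1L) "figure" else "ground"
      x_test <- numeric(nn)
      Xf <- matrix(0, n_train, nn)
      Xg <- matrix(0, n_train, nn)
      for (i in seq_len(nn)) {
        tf <- features[[i]]$figure
        tg <- features[[i]]$ground
        if (test_class == "figure") {
          h <- sample.int(length(tf), 1L); x_test[i] <- tf[h]; tf <- tf[-h]
        } else {
          h <- sample.int(length(tg), 1L); x_test[i] <- tg[h]; tg <- tg[-h]
        }
        Xf[, i] <- tf[sample.int(length(tf), n_train, replace = TRUE)]
        Xg[, i] <- tg[sample.int(length(tg), n_train, replace = TRUE)]
      }
      res <- svm_decide(rbind(Xf, Xg), y, x_test)
      correct[b] <- res$pred == test_class
      W[b, ] <- res$weights
    }
    list(performance = mean(correct), correct = correct, weights = W,
         n_boot = n_boot)
  })
}

#' Sliding windows for decoding
#'
#' @param epoch analysis epoch `c(start, end)`, seconds.
#' @param width window width (default 0.050 s).
#' @param step window step (default 0.010 s).
#' @return data.frame with `start` and `end` per window.
#' @export
decoding_windows <- function(epoch, width = 0.050, step = 0.010) {
  if (diff(epoch) + 1e-9 < width) stop("epoch shorter than one window")
  n <- floor((diff(epoch) - width) / step + 1e-9) + 1L
  starts <- epoch[1] + (seq_len(n) - 1L) * step
  data.frame(start = starts, end = starts + width)
}

#' Sliding-window decoding curve
#'
#' Runs [decode_bootstrap()] in windows of `width` seconds stepped by
#' `step` seconds across the epoch and attaches binomial significance with
#' Bonferroni-Holm correction (see [decode_significance()]).
#'
#' @param neurons list of [neuron_recording()].
#' @param trials trial table.
#' @param constants normalisation constants for these neurons.
#' @param epoch analysis epoch, seconds relative to stimulus onset.
#' @param config an [analysis_config()] (window width/step, n_boot, seed).
#' @param n_boot override for the bootstrap count.
#' @param seed override for the seed.
#' @return object of class `decoding_result`: list with `windows`,
#'   `performance`, `n_correct`, `p_values` (Holm-adjusted), `weights`
#'   (`[windows, neurons]` mean weights), `n_boot`, `neuron_ids`.
#' @export
sliding_window_decode <- function(neurons, trials, constants,
                                  epoch = c(0, 0.25),
                                  config = analysis_config(),
                                  n_boot = config$n_boot_decode,
                                  seed = config$seed) {
  win <- decoding_windows(epoch, config$decode_window_width,
                          config$decode_window_step)
  perf <- numeric(nrow(win))
  ncor <- integer(nrow(win))
  Wm <- matrix(NA_real_, nrow(win), length(neurons))
  for (k in seq_len(nrow(win))) {
    feats <- decoding_features(neurons, trials, constants,
                               c(win$start[k], win$end[k]))
    res <- decode_bootstrap(feats, n_boot = n_boot, seed = seed + k)
    perf[k] <- res$performance
    ncor[k] <- sum(res$correct)
    Wm[k, ] <- colMeans(res$weights)
  }
  out <- list(windows = win, performance = perf, n_correct = ncor,
              n_boot = n_boot, weights = Wm,
              neuron_ids = vapply(neurons, `[[`, character(1), "neuron_id"))
  out$p_values <- decode_significance(out)
  structure(out, class = "decoding_result")
}

#' Binomial significance of decoding performance
#'
#' Two-sided exact binomial test of the per-window bootstrap outcome counts
#' against chance (0.5), Holm step-down adjusted across windows.
#'
#' @param result a `decoding_result` (or any list with `n_correct` and
#'   `n_boot`).
#' @return Holm-adjusted p-value per window.
#' @export
decode_significance <- function(result) {
  p <- vapply(result$n_correct, function(k) {
    binom.test(k, result$n_boot, 0.5, alternative = "two.sided")$p.value
  }, numeric(1))
  p.adjust(p, method = "holm")
}

#' Relative normalised decoder weights
#'
#' Per-neuron weights averaged over bootstraps (and optionally windows),
#' normalised so the population's absolute weights sum to 1.
#'
#' @param result a `decoding_result`, or a numeric matrix of per-bootstrap
#'   weights.
#' @param window_index window to report (default: window of best
#'   performance).
#' @return data.frame with `neuron_id`, `weight` (mean raw weight), and
#'   `relative_weight`.
#' @export
extract_weights <- function(result, window_index = NULL) {
  if (is.matrix(result)) {
    w <- colMeans(result)
    ids <- colnames(result) %||% as.character(seq_along(w))
  } else {
    k <- window_index %||% which.max(result$performance)
    w <- result$weights[k, ]
    ids <- result$neuron_ids
  }
  data.frame(neuron_id = ids, weight = w,
             relative_weight = w / sum(abs(w)),
             stringsAsFactors = FALSE)
}

#' Compare relative decoder weights across groups with a mixed model
#'
#' Fits `relative_weight ~ group + (1 | neuron)` with lme4 and reports the
#' group effect (likelihood-ratio test against the intercept-only model).
#'
#' @param weights data.frame with columns `neuron_id`, `relative_weight`,
#'   and `group` (e.g. task or RF class).
#' @return list with `estimate` (per-group fixed effects), `chisq`, `df`,
#'   `p`.
#' @export
compare_weights <- function(weights) {
  stopifnot(all(c("neuron_id", "relative_weight", "group") %in% names(weights)))
  m1 <- lme4::lmer(relative_weight ~ group + (1 | neuron_id), data = weights,
                   REML = FALSE)
  m0 <- lme4::lmer(relative_weight ~ 1 + (1 | neuron_id), data = weights,
                   REML = FALSE)
  a <- anova(m0, m1)
  list(estimate = lme4::fixef(m1), chisq = a$Chisq[2], df = a$Df[2],
       p = a$`Pr(>Chisq)`[2])
}
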