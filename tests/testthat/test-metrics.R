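make_rate_psth <- function(rate_fn, bin_s = 0.025) {
  # psth_matrix with deterministic mean rate given by rate_fn(t0)
  n_bins <- ceiling(30 / bin_s)
  t0 <- (seq_len(n_bins) - 1) * bin_s
  r <- rate_fn(t0)
  structure(list(counts = matrix(r * bin_s, ncol = 1), bin_s = bin_s,
                 window = c(0, 30), t0 = t0, rate = r),
            class = "psth_matrix")
}

test_that("response amplitude is the baseline-subtracted peak over step epochs", {
  flat <- make_rate_psth(function(t) rep(5, length(t)))
  expect_equal(response_amplitude(flat), 0)
  peaked <- make_rate_psth(function(t) ifelse(t >= 0.1 & t < 0.125, 47, 2))
  expect_equal(response_amplitude(peaked), 45)
  # OFF unit peaking after step offset is captured by the [0, 6) window
  off <- make_rate_psth(function(t) ifelse(t >= 3.2 & t < 3.4, 30, 1))
  expect_equal(response_amplitude(off), 29)
  short <- bin_psth(list(c(0.1)), 0.025, c(0, 10))
  expect_error(response_amplitude(short), "baseline")
})

test_that("Hill fit recovers noise-free parameters", {
  irr <- seq(13, 17, by = 0.8)
  truth <- c(top = 50, bottom = 2, slope = 1.2, ec50 = 15.3)
  a <- truth["bottom"] + (truth["top"] - truth["bottom"]) /
    (1 + 10^(truth["slope"] * (truth["ec50"] - irr)))
  fit <- fit_hill(a, irr)
  expect_equal(fit$ec50_log, 15.3, tolerance = 1e-4)
  expect_equal(fit$slope, 1.2, tolerance = 1e-3)
  expect_gt(fit$r2, 0.999)
  expect_error(fit_hill(c(1, NA, 3, 4), irr[1:4]), "finite")
  expect_error(fit_hill(c(1, 2, 3), c(14, 15, 16)), "levels")
})

test_that("quality index fixed points and small-sample behaviour", {
  tr <- c(0.05, 0.21, 0.22, 0.9, 1.7, 2.5)
  ident <- bin_psth(lapply(1:5, function(i) tr), 0.2, c(0, 3))
  expect_equal(quality_index(ident), 1)
  # all-constant trials: denominator zero -> defined 0
  empty <- bin_psth(lapply(1:4, function(i) numeric(0)), 0.2, c(0, 3))
  expect_equal(quality_index(empty), 0)
  # i.i.d. noise trials: QI ~ 1/n_trials
  set.seed(1)
  qis <- vapply(1:40, function(i) {
    counts <- matrix(rpois(100 * 10, 5), 100, 10)
    psth <- structure(list(counts = counts, bin_s = 0.2, window = c(0, 20),
                           t0 = (0:99) * 0.2, rate = rowMeans(counts) / 0.2),
                      class = "psth_matrix")
    quality_index(psth)
  }, numeric(1))
  expect_equal(mean(qis), 0.1, tolerance = 0.02)
})

test_that("QI rises monotonically with generator reliability", {
  stim <- chirp_1khz(15.95)
  gt <- unit_ground_truth(w_on = 1, transience_tau_s = 0.6, gain = 40,
                          baseline_rate = 3, hill_ec50_log = 15.0)
  r <- rate_model(gt, stim)
  rel <- seq(0.05, 1, length.out = 12)
  qi <- vapply(seq_along(rel), function(i) {
    mean(vapply(1:4, function(s) {
      sp <- sample_spikes(r, 1000, 10, reliability = rel[i],
                          seed = 600 + 50 * s + i)
      quality_index(bin_psth(sp, 0.2, c(0, 30)))
    }, numeric(1)))
  }, numeric(1))
  expect_gt(cor(rel, qi, method = "spearman"), 0.8)
  expect_gt(qi[12], qi[1])
})

test_that("rate matching pairs like with like and flags impossible matchings", {
  m <- match_firing_rate(c(1, 2, 3), c(1, 2, 3))
  expect_equal(length(m$idx_a), 3)
  expect_equal(sort(m$idx_a), 1:3)
  expect_equal(c(1, 2, 3)[m$idx_a], c(1, 2, 3)[m$idx_b])
  expect_warning(m2 <- match_firing_rate(c(1, 1.1), c(50, 60)), "caliper")
  expect_length(m2$idx_a, 0)
  # shifted distributions: matching shrinks the KS distance
  set.seed(2)
  a <- rnorm(150, 10, 2)
  b <- rnorm(150, 13, 2)
  m3 <- match_firing_rate(a, b, caliper_sd = 0.2)
  ks_pre <- suppressWarnings(ks.test(a, b)$statistic)
  ks_post <- suppressWarnings(ks.test(a[m3$idx_a], b[m3$idx_b])$statistic)
  expect_lt(ks_post, ks_pre)
})

test_that("latency finds a clean step onset and rejects flat units", {
  set.seed(3)
  # noiseless step at 30 ms on a quiet baseline
  trials <- lapply(1:20, function(i) seq(0.030, 0.3, by = 0.002) + 1e-4 * i)
  lat <- latency_to_onset(bin_psth(trials, 0.001, c(0, 30)))
  expect_lt(abs(lat - 0.030), 0.010)
  # unit silent around onset but active elsewhere never crosses threshold
  sp <- lapply(1:10, function(i) {
    sort(c(runif(60, 5, 25), runif(5, 29.3, 30)))
  })
  expect_true(is.na(latency_to_onset(bin_psth(sp, 0.001, c(0, 30)))))
})

test_that("bias index spans -1..1 with the 0/0 convention", {
  expect_equal(bias_index(list(c(0.1, 0.2, 0.3))), 1)
  expect_equal(bias_index(list(c(3.1, 3.2, 3.3))), -1)
  expect_equal(bias_index(list(c(0.1, 0.2, 3.1, 3.2))), 0)
  expect_equal(bias_index(list(c(0.1, 0.2, 0.3), c(3.05, 3.1, 3.2, 3.3,
                                                   3.35, 3.4, 3.44, 3.21,
                                                   3.22))), -0.5)
  expect_equal(bias_index(list(numeric(0))), 0)
  expect_equal(bias_index(list(c(1.5, 2.0))), 0)  # outside both windows
})

test_that("transience index integrates the normalized post-step response", {
  sustained <- make_rate_psth(function(t) ifelse(t >= 0 & t < 3, 20, 0))
  expect_equal(transience_index(sustained, bias = 1), 1)
  single_bin <- make_rate_psth(function(t) ifelse(t >= 0 & t < 0.025, 40, 0))
  expect_equal(transience_index(single_bin, bias = 1), 0.025)
  # OFF-polarity units are scored on the post-offset second
  off <- make_rate_psth(function(t) ifelse(t >= 3 & t < 4, 12, 0))
  expect_equal(transience_index(off, bias = -0.5), 1)
  expect_equal(transience_index(off, bias = 0.5), 0)
  silent <- make_rate_psth(function(t) rep(0, length(t)))
  expect_true(is.na(transience_index(silent, bias = 1)))
})

test_that("classification rules partition the bias/transience plane", {
  expect_equal(classify_response(0.81, 0.36), "ON_transient")
  expect_equal(classify_response(0.81, 0.66), "ON_sustained")
  expect_equal(classify_response(-0.9, NA), "OFF")
  expect_equal(classify_response(0, 0.2), "ON_OFF")
  expect_equal(classify_response(-0.33, 0.2), "ON_OFF")
  expect_equal(classify_response(-0.34, 0.2), "OFF")
})

test_that("indices are invariant to uniform time rescaling", {
  trials <- list(c(0.05, 0.3, 3.1), c(0.2, 0.4, 3.2, 3.4))
  b1 <- bias_index(trials, onset_s = 0, offset_s = 3, win_s = 0.5)
  b2 <- bias_index(lapply(trials, `*`, 2), onset_s = 0, offset_s = 6,
                   win_s = 1)
  expect_identical(b1, b2)
  q1 <- quality_index(bin_psth(trials, 0.2, c(0, 4)))
  q2 <- quality_index(bin_psth(lapply(trials, `*`, 2), 0.4, c(0, 8)))
  expect_equal(q1, q2, tolerance = 1e-12)
})
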