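nr_curve <- function(contrast, top, bottom, slope, c50) {
  bottom + (top - bottom) * contrast^slope / (contrast^slope + c50^slope)
}

test_that("contrast profile tracks the stimulus and flags silent units", {
  stim <- chirp_1khz(15.95)
  # rate linear in the stimulus waveform -> amplitude grows with contrast
  lin <- exact_psth(40 * stim$waveform, 0.025)
  cp <- contrast_profile(lin, stim)
  expect_length(cp$contrast, 16)
  expect_true(all(diff(cp$raw_amplitude) > 0))
  expect_equal(cp$contrast[1], 0.03 + 0.94 * 0.25 / 8, tolerance = 1e-9)
  silent <- exact_psth(rep(0, 30000), 0.025)
  expect_true(contrast_profile(silent, stim)$flagged)
})

test_that("Naka-Rushton fit recovers noise-free parameters and rejects flat data", {
  contrast <- seq(0.06, 0.94, length.out = 16)
  prof <- list(contrast = contrast,
               amplitude = nr_curve(contrast, 1, 0.05, 3, 0.5),
               frac_active_bins = 0.5, flagged = FALSE)
  fit <- fit_naka_rushton(prof)
  expect_equal(fit$c50, 0.5, tolerance = 1e-3)
  expect_equal(fit$slope, 3, tolerance = 1e-2)
  expect_true(fit$included)
  flat <- list(contrast = contrast, amplitude = rep(1, 16),
               frac_active_bins = 0.5, flagged = FALSE)
  expect_false(fit_naka_rushton(flat)$included)
  expect_error(fit_naka_rushton(list(contrast = contrast[1:4],
                                     amplitude = rep(1, 4),
                                     frac_active_bins = 0.5,
                                     flagged = FALSE)), "contrast points")
})

test_that("forward-model contrast response half-saturates near the true c50", {
  stim <- chirp_1khz(15.95)
  gt <- unit_ground_truth(w_on = 1, c50_true = 0.45, nr_slope_true = 4,
                          transience_tau_s = 0.4, gain = 50,
                          baseline_rate = 2, hill_ec50_log = 15.0)
  cp <- contrast_profile(exact_psth(rate_model(gt, stim), 0.025), stim)
  fit <- fit_naka_rushton(cp)
  expect_equal(fit$c50, 0.45, tolerance = 0.03)
})

test_that("temporal profile bands are flat for untuned units, peaked for tuned", {
  stim <- chirp_1khz(15.95)
  flat_gt <- unit_ground_truth(w_on = 1, peak_tf_true = 2,
                               tf_spread_true = 50, transience_tau_s = 0.4,
                               gain = 50, baseline_rate = 0,
                               hill_ec50_log = 15.0, phase_sharpness = 1)
  tp <- temporal_profile(exact_psth(rate_model(flat_gt, stim), 0.025), stim)
  expect_length(tp$frequency, 7)
  expect_lt(diff(range(tp$raw_amplitude)) / max(tp$raw_amplitude), 0.25)
  tuned <- unit_ground_truth(w_on = 1, peak_tf_true = 3, tf_spread_true = 0.6,
                             transience_tau_s = 0.4, gain = 50,
                             baseline_rate = 0, hill_ec50_log = 15.0)
  tp2 <- temporal_profile(exact_psth(rate_model(tuned, stim), 0.025), stim)
  expect_true(tp2$frequency[which.max(tp2$raw_amplitude)] > 2 &&
              tp2$frequency[which.max(tp2$raw_amplitude)] < 4)
  silent <- exact_psth(rep(0, 30000), 0.025)
  expect_true(temporal_profile(silent, stim)$flagged)
})

test_that("half-Gaussian fit recovers noise-free parameters and applies rules", {
  freq <- c(1.61, 2.65, 3.63, 4.59, 5.54, 6.48, 7.49)
  hg <- function(f, peak, spread, lo, hi, amp) {
    side <- ifelse(f < peak, lo, hi)
    side + (amp - side) * exp(-(log2(f) - log2(peak))^2 / (2 * spread^2))
  }
  prof <- list(frequency = freq,
               amplitude = hg(freq, 2, 1, 0.1, 0.05, 1),
               frac_active_bins = 0.5, flagged = FALSE)
  fit <- fit_half_gaussian(prof)
  expect_equal(fit$peak_tf, 2, tolerance = 1e-3)
  expect_equal(fit$spread, 1, tolerance = 1e-2)
  expect_true(fit$included)
  # spread at 0.4 octaves is excluded by the > 0.51 rule even when clean
  narrow <- list(frequency = freq,
                 amplitude = hg(freq, 3, 0.4, 0.1, 0.05, 1),
                 frac_active_bins = 0.5, flagged = FALSE)
  nfit <- fit_half_gaussian(narrow)
  expect_false(nfit$included)
  expect_lt(nfit$spread, 0.51)
  expect_error(fit_half_gaussian(list(frequency = freq[1:3],
                                      amplitude = rep(1, 3),
                                      frac_active_bins = 0.5,
                                      flagged = FALSE)), "frequency points")
})

test_that("fits are invariant to uniform scaling of the profile", {
  contrast <- seq(0.06, 0.94, length.out = 16)
  base <- list(contrast = contrast,
               amplitude = nr_curve(contrast, 1, 0.1, 3.5, 0.4),
               frac_active_bins = 0.5, flagged = FALSE)
  scaled <- base
  scaled$amplitude <- base$amplitude * 37
  expect_equal(fit_naka_rushton(base)$c50, fit_naka_rushton(scaled)$c50,
               tolerance = 1e-6)
  freq <- c(1.61, 2.65, 3.63, 4.59, 5.54, 6.48, 7.49)
  amp <- 0.1 + 0.9 * exp(-(log2(freq) - log2(2.5))^2 / 2)
  p1 <- list(frequency = freq, amplitude = amp, frac_active_bins = 0.5,
             flagged = FALSE)
  p2 <- p1
  p2$amplitude <- amp * 21
  expect_equal(fit_half_gaussian(p1)$peak_tf, fit_half_gaussian(p2)$peak_tf,
               tolerance = 1e-6)
})

test_that("bootstrap CIs for c50 and peak TF cover the generating values", {
  stim <- chirp_1khz(15.95)
  covered_c50 <- covered_tf <- 0
  n_units <- 25
  pop <- make_population("brn3c_like", n_units, 10, seed = 8, stim = stim,
                         reliability = 0.9)
  for (u in seq_len(n_units)) {
    ci <- bootstrap_tuning_ci(pop$spikes$units[[u]]$trials, stim,
                              n_boot = 40, seed = 100 + u)
    gt <- pop$ground_truth[u, ]
    if (!anyNA(ci$c50_ci) && gt$c50_true >= ci$c50_ci[1] &&
        gt$c50_true <= ci$c50_ci[2]) {
      covered_c50 <- covered_c50 + 1
    }
    if (!anyNA(ci$peak_tf_ci) && gt$peak_tf_true >= ci$peak_tf_ci[1] &&
        gt$peak_tf_true <= ci$peak_tf_ci[2]) {
      covered_tf <- covered_tf + 1
    }
  }
  # nominal 95% with few replicates and n = 25 units: demand >= 80% each
  expect_gte(covered_c50 / n_units, 0.8)
  expect_gte(covered_tf / n_units, 0.8)
})
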