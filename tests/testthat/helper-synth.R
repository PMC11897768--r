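# Shared fixtures: a 1 kHz chirp and a noiseless PSTH builder used to probe
# analysis stages against the forward model without sampling noise.

chirp_1khz <- function(irradiance_log = 15.95) {
  build_chirp(1000, irradiance_log)
}

# Deterministic psth_matrix holding an exact rate profile (one pseudo-trial
# whose counts are rate * bin_s), for noiseless oracle checks.
exact_psth <- function(rate, bin_s, sample_rate = 1000, duration = 30) {
  n_bins <- ceiling(duration / bin_s)
  idx <- floor((seq_along(rate) - 1) / sample_rate / bin_s) + 1
  r <- as.numeric(tapply(rate, idx, mean))
  structure(
    list(counts = matrix(r * bin_s, ncol = 1), bin_s = bin_s,
         window = c(0, duration), t0 = (seq_len(n_bins) - 1) * bin_s,
         rate = r),
    class = "psth_matrix")
}

# Small random spike sets for oracle-equivalence tests.
random_trials <- function(n_trials, max_spikes, t_max, rng) {
  lapply(seq_len(n_trials), function(i) {
    sort(stats::runif(rng(max_spikes), 0, t_max))
  })
}
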