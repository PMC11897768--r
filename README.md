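# chirpcode

Analysis of single-unit spike trains recorded on multi-electrode arrays
(retina or dLGN) in response to a full-field **chirp stimulus** — the 30 s
sequence of a 3 s light step, an accelerating 1–8 Hz temporal chirp, and a
2 Hz contrast-ramped chirp used to characterize restored or native visual
codes. The package is aimed at researchers quantifying how a manipulation
(optogenetic targeting, degeneration, pharmacology) changes the diversity
of visual response properties across a recorded population.

## What it computes

For each unit, from trial-aligned spike times:

* **Light responsiveness**: mean pairwise Pearson correlation between
  25 ms-binned trials, tested against a circular-shift permutation null
  (`lr_shuffle_test`), with activity-based exclusion rules
  (`exclusion_filter`).
* **Response indices**: baseline-subtracted response amplitude; quality
  index `QI = Var_t[mean_r(C)] / mean_r[Var_t(C)]` on 200 ms bins (0 =
  unrelated trials, 1 = identical trials); latency to step onset
  (zero-phase 10 ms boxcar, mean + 2 SD threshold); ON-OFF bias
  `(ON − OFF)/(ON + OFF)` over 500 ms windows; transience (normalized
  1 s response area); four-way response category.
* **Tuning curves** by bounded multi-start least squares:
  Hill irradiance-response `A(I) = bottom + (top−bottom)/(1+10^(s(EC50−I)))`;
  Naka-Rushton contrast response
  `R(C) = bottom + (top−bottom)·C^n/(C^n + C50^n)` with C50 ∈ [0,1],
  n ∈ (0,10]; half-Gaussian temporal-frequency tuning on a log2 axis with
  side-dependent baselines, peak TF ∈ [1,8] Hz, spread in octaves.
  Inclusion rules: fit R² > 0.5, spiking in > 10% of segment bins, spread
  > 0.51 octaves for temporal fits.
* **Population code structure**: sparse PCA (5 non-zero time bins per
  component) on three chirp segments, consensus Gaussian-mixture
  clustering (BIC + Bayes-factor model selection, co-assignment
  similarity over repeats), Louvain community detection (communities
  < 5 units dropped), and permutation tests on how conditions distribute
  across communities.

A generative twin (`make_population`, `rate_model`, `sample_spikes`)
produces inhomogeneous-Poisson spike trains with known ground truth —
polarity weights, latency, transience constant, C50, peak TF, Hill EC50,
reliability — so every stage is validated by parameter recovery without
recorded data. Presets emulate an ON-bipolar-cell-targeted population
(`grm6_like`: diverse), an RGC-targeted one (`brn3c_like`: ON-biased,
2 Hz bandpass, lower contrast sensitivity) and a wild-type-like one.

## Worked example

```r
library(chirpcode)

stim  <- build_chirp(1000, 15.95)   # 1 kHz waveform at 15.95 log photons
grm6  <- make_population("grm6_like",  n_units = 60, n_trials = 10,
                         seed = 1, stim = stim)
brn3c <- make_population("brn3c_like", n_units = 60, n_trials = 10,
                         seed = 2, stim = stim)

res <- run_chirp_pipeline(list(grm6$spikes, brn3c$spikes),
                          n_shuffles = 999, lr_alpha = 0.01, seed = 1,
                          code_args = list(n_repeats = 10, k_max = 8))
print(res$report$medians, digits = 2)
#>    condition n_lr median_qi median_amplitude median_latency_s median_bias
#> 1 brn3c_like   60      0.46               44            0.034        0.62
#> 2  grm6_like   60      0.37               36            0.044        0.24
#>   median_transience median_c50 median_peak_tf median_mean_rate
#> 1              0.44       0.62            1.9              7.3
#> 2              0.34       0.46            1.8              7.7
print(res$code$condition_distributions)
#>             community
#> condition     1  2  3  4
#>   brn3c_like 29 10  0 21
#>   grm6_like   8 20 30  2
print(res$code$shuffle, digits = 2)
#>   condition_a condition_b statistic p_value n_a n_b
#> 1   grm6_like  brn3c_like      0.67   0.001  60  60
```

Reading the output: every unit in both synthetic populations is light
responsive; the RGC-targeted (`brn3c_like`) population is more ON-biased
(median bias 0.62 vs 0.24), more sustained (transience 0.44 vs 0.34),
faster (34 vs 44 ms latency) and less contrast sensitive (C50 0.62 vs
0.46) than the bipolar-cell-targeted one, and the two populations occupy
the shared response communities very differently (total variation 0.67,
permutation p = 0.001) — with `grm6_like` spread over all four communities
and `brn3c_like` missing community 3 entirely.

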