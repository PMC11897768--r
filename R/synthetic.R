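#' Ground-truth response parameters for one synthetic unit
#'
#' Bundles the generative parameters of the forward model in [rate_model()]:
#' ON/OFF drive weights, response latency, transience time constant,
#' Naka-Rushton contrast transfer (c50, slope), half-Gaussian temporal tuning
#' (peak frequency in Hz, spread in octaves), Hill irradiance transfer,
#' baseline rate, response gain, and trial-to-trial reliability.
#'
#' @param w_on,w_off Non-negative drive weights for intensity increments /
#'   decrements.
#' @param latency_s Response delay, s.
#' @param transience_tau_s Exponential decay constant of the step response, s
#'   (`Inf` = perfectly sustained).
#' @param c50_true Michelson contrast of half-maximal response, in (0, 1].
#' @param nr_slope_true Naka-Rushton exponent, in (0, 10].
#' @param peak_tf_true Preferred temporal frequency, Hz in \[1, 8\].
#' @param tf_spread_true Temporal-tuning spread, octaves (> 0).
#' @param hill_ec50_log Irradiance of half-maximal response, log10
#'   photons/cm^2/s.
#' @param hill_slope Hill exponent (dimensionless).
#' @param baseline_rate Spontaneous rate, spikes/s (>= 0).
#' @param gain Peak stimulus-driven rate, spikes/s (>= 0).
#' @param reliability Trial-to-trial gain coupling in \[0, 1\]: 1 gives the
#'   same expected rate on every trial, 0 gives fully independent trial gains.
#' @param rise_tau_s Activation rise time constant of the step kernel, s.
#' @param phase_sharpness Exponent applied to the rectified sinusoidal drive
#'   (mean-preserving), emulating the burst-like phase locking of ganglion
#'   cells to sinusoidal modulation: spikes concentrate near the preferred
#'   phase without changing the spike count per cycle. 1 = pure rectified
#'   sinusoid.
#' @return A `unit_ground_truth` list.
#' @export
unit_ground_truth <- function(w_on = 1, w_off = 0, latency_s = 0.04,
                              transience_tau_s = 0.5, c50_true = 0.5,
                              nr_slope_true = 3, peak_tf_true = 2,
                              tf_spread_true = 1, hill_ec50_log = 15.5,
                              hill_slope = 1, baseline_rate = 2,
                              gain = 40, reliability = 1,
                              rise_tau_s = 0.01, phase_sharpness = 4) {
  stopifnot(w_on >= 0, w_off >= 0, latency_s >= 0, transience_tau_s > 0,
            c50_true > 0, c50_true <= 1, nr_slope_true > 0,
            nr_slope_true <= 10, peak_tf_true >= 1, peak_tf_true <= 8,
            tf_spread_true > 0, baseline_rate >= 0, gain >= 0,
            reliability >= 0, reliability <= 1, rise_tau_s > 0,
            phase_sharpness >= 1)
  structure(as.list(environment()), class = "unit_ground_truth")
}

naka_rushton_gain <- function(contrast, c50, slope) {
  contrast^slope / (contrast^slope + c50^slope)
}

half_gaussian_gain <- function(freq, peak_tf, spread) {
  exp(-(log2(freq) - log2(peak_tf))^2 / (2 * spread^2))
}

hill_gain <- function(irradiance_log, ec50_log, slope) {
  1 / (1 + 10^(slope * (ec50_log - irradiance_log)))
}

# Rectified-sine drive raised to `p`, renormalized so the mean over a full
# cycle is preserved: same expected spikes per cycle, concentrated into a
# narrower phase window (burst-like phase locking).
sharpen_halfwave <- function(x, p) {
  if (p == 1) return(x)
  u <- pmax(sin(seq(0, 2 * pi, length.out = 2001)), 0)
  x^p * (mean(u) / mean(u^p))
}

# one-pole recursive low-pass of an impulse stream; a = exp(-dt/tau)
exp_filter <- function(x, a) {
  if (a <= 0) return(x)
  stats::filter(x, a, method = "recursive")
}

#' Expected firing rate of a synthetic unit under the chirp
#'
#' Forward model: the slow (per-segment mean) intensity envelope drives ON and
#' OFF excitation through a delayed kernel with finite rise time and
#' exponential decay (`transience_tau_s`), so steps produce transient or
#' sustained responses; during the sinusoidal segments the response follows
#' the (latency-delayed, polarity-rectified) stimulus sinusoid scaled by the
#' unit's Naka-Rushton contrast transfer and half-Gaussian temporal-frequency
#' gain, so the per-cycle modulation amplitude traces the tuning curves the
#' analysis stages estimate. The whole stimulus-driven drive is scaled by the
#' Hill irradiance transfer evaluated at the stimulus irradiance, added to the
#' baseline rate, and rectified at zero.
#'
#' @param gt A [unit_ground_truth()].
#' @param stim A [build_chirp()] stimulus (must carry a finite
#'   `irradiance_log`).
#' @return Numeric vector of expected rate (spikes/s) aligned to `stim$time`.
#' @export
rate_model <- function(gt, stim) {
  stopifnot(inherits(gt, "unit_ground_truth"), inherits(stim, "chirp_stimulus"))
  if (!is.finite(stim$irradiance_log)) {
    stop("stimulus must carry a finite `irradiance_log`")
  }
  sr <- stim$sample_rate
  dt <- 1 / sr
  n <- length(stim$time)
  env <- segment_envelope(stim)
  d <- c(env[1], diff(env))        # pre-stimulus level is dark
  lag <- round(gt$latency_s * sr)
  shift_lag <- function(x) if (lag > 0) c(numeric(lag), x[seq_len(n - lag)]) else x
  # kernel (1 - exp(-u/rise)) * exp(-u/tau) as a difference of exponentials,
  # applied to the signed envelope derivative so ON drive unloads on
  # decrements (and vice versa); rectification then splits the polarities
  a_slow <- exp(-dt / gt$transience_tau_s)
  a_fast <- exp(-dt * (1 / gt$transience_tau_s + 1 / gt$rise_tau_s))
  kern <- function(x) as.numeric(exp_filter(x, a_slow) - exp_filter(x, a_fast))
  y <- kern(shift_lag(d))
  drive <- gt$w_on * pmax(y, 0) + gt$w_off * pmax(-y, 0)

  # temporal chirp: full contrast, frequency sweeps 1 -> 8 Hz. The tuning
  # gain is constant within each cycle (a cycle drives one burst whose size
  # reflects that cycle's frequency), evaluated at the cycle's mean
  # instantaneous frequency.
  seg <- stim$segments["temporal_chirp", ]
  i <- stim$time >= seg["start"] & stim$time < seg["end"]
  tl <- stim$time[i] - seg["start"]
  sv <- ifelse(tl >= gt$latency_s, sin(chirp_phase(tl - gt$latency_s)), 0)
  cyc_bounds <- (8 / 7) * (sqrt(1 + 1.75 * (0:36)) - 1)
  f_cyc <- vapply(seq_len(36), function(k) {
    mean(chirp_instant_freq(cyc_bounds[k:(k + 1)]))
  }, numeric(1))
  cyc <- pmin(pmax(findInterval(tl, cyc_bounds), 1L), 36L)
  g <- naka_rushton_gain(1, gt$c50_true, gt$nr_slope_true) *
    half_gaussian_gain(f_cyc[cyc], gt$peak_tf_true, gt$tf_spread_true)
  drive[i] <- drive[i] +
    g * (gt$w_on * sharpen_halfwave(pmax(sv, 0), gt$phase_sharpness) +
         gt$w_off * sharpen_halfwave(pmax(-sv, 0), gt$phase_sharpness))

  # contrast chirp: 2 Hz carrier, contrast ramps 3 -> 97%; contrast gain is
  # per cycle, at the cycle's mean Michelson contrast
  seg <- stim$segments["contrast_chirp", ]
  i <- stim$time >= seg["start"] & stim$time < seg["end"]
  tl <- stim$time[i] - seg["start"]
  sv <- ifelse(tl >= gt$latency_s, sin(2 * pi * 2 * (tl - gt$latency_s)), 0)
  c_cyc <- contrast_envelope(pmin(floor(tl / 0.5), 15) * 0.5 + 0.25)
  g <- naka_rushton_gain(c_cyc, gt$c50_true, gt$nr_slope_true) *
    half_gaussian_gain(2, gt$peak_tf_true, gt$tf_spread_true)
  drive[i] <- drive[i] +
    g * (gt$w_on * sharpen_halfwave(pmax(sv, 0), gt$phase_sharpness) +
         gt$w_off * sharpen_halfwave(pmax(-sv, 0), gt$phase_sharpness))

  h <- hill_gain(stim$irradiance_log, gt$hill_ec50_log, gt$hill_slope)
  pmax(0, gt$baseline_rate + gt$gain * h * drive)
}

#' Sample spike trains from a rate profile
#'
#' Draws `n_trials` inhomogeneous-Poisson spike trains by thinning against the
#' rate maximum, so output statistics do not depend on the rate sample grid
#' beyond its resolution. `reliability` couples each trial to the stimulus:
#' the per-trial rate is
#' `g * (reliability * rate(t) + (1 - reliability) * mean(rate))` with the
#' trial gain `g = reliability + (1 - reliability) * e`, `e` lognormal of
#' mean 1 (`sdlog = noise_sdlog`). At `reliability = 1` every trial has the
#' identical expected rate; at 0 trials are flat (stimulus-independent) with
#' independent gains.
#'
#' @param rate Non-negative rate vector, spikes/s, sampled at `sample_rate`.
#' @param sample_rate Samples per second of `rate`.
#' @param n_trials Number of trials (>= 1).
#' @param reliability Trial gain coupling in \[0, 1\].
#' @param seed Integer seed; identical seed gives identical spikes.
#' @param noise_sdlog Lognormal sd of the trial gain noise.
#' @return List of `n_trials` sorted spike-time vectors (s).
#' @export
sample_spikes <- function(rate, sample_rate, n_trials, reliability = 1,
                          seed = 1L, noise_sdlog = 0.7) {
  if (any(rate < 0)) stop("`rate` must be non-negative everywhere")
  stopifnot(n_trials >= 1, reliability >= 0, reliability <= 1)
  dur <- length(rate) / sample_rate
  mix <- reliability * rate + (1 - reliability) * mean(rate)
  m <- max(mix)
  with_seed(seed, {
    lapply(seq_len(n_trials), function(tr) {
      if (m == 0) return(numeric(0))
      e <- stats::rlnorm(1, meanlog = -noise_sdlog^2 / 2, sdlog = noise_sdlog)
      g <- reliability + (1 - reliability) * e
      n_cand <- stats::rpois(1, m * g * dur)
      if (n_cand == 0) return(numeric(0))
      times <- stats::runif(n_cand, 0, dur)
      keep <- stats::runif(n_cand) < mix[floor(times * sample_rate) + 1] / m
      sort(times[keep])
    })
  })
}

preset_params <- function(preset, n_units, reliability) {
  draw_clip <- function(n, mean, sd, lo, hi) pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
  loguni <- function(n, lo, hi) exp(stats::runif(n, log(lo), log(hi)))
  if (preset == "brn3c_like") {
    # strongly ON-biased, sustained, low contrast sensitivity, ~2 Hz bandpass
    w_on <- stats::runif(n_units, 0.7, 1)
    data.frame(
      w_on = w_on,
      w_off = w_on * stats::runif(n_units, 0, 0.15),
      latency_s = draw_clip(n_units, 0.030, 0.005, 0.015, 0.06),
      transience_tau_s = loguni(n_units, 0.5, 2.5),
      # concentrated low contrast sensitivity, population median ~0.67
      c50_true = 0.5 + 0.45 * stats::rbeta(n_units, 2, 3),
      nr_slope_true = stats::runif(n_units, 2, 5),
      peak_tf_true = draw_clip(n_units, 2, 0.3, 1.2, 3.5),
      tf_spread_true = stats::runif(n_units, 0.7, 1.2),
      hill_ec50_log = stats::rnorm(n_units, 15.4, 0.15),
      hill_slope = stats::runif(n_units, 0.8, 1.5),
      baseline_rate = stats::runif(n_units, 1, 6),
      gain = stats::runif(n_units, 30, 80),
      reliability = reliability)
  } else if (preset %in% c("grm6_like", "wt_like")) {
    # diverse polarity, kinetics, contrast sensitivity and temporal tuning
    probs <- if (preset == "grm6_like") c(0.5, 0.2, 0.3) else c(0.4, 0.25, 0.35)
    type <- sample(c("ON", "OFF", "ON_OFF"), n_units, replace = TRUE,
                   prob = probs)
    w_on <- ifelse(type == "OFF", stats::runif(n_units, 0, 0.1),
                   stats::runif(n_units, 0.6, 1))
    w_off <- ifelse(type == "ON", stats::runif(n_units, 0, 0.1),
                    stats::runif(n_units, 0.6, 1))
    lat <- if (preset == "grm6_like") {
      draw_clip(n_units, 0.043, 0.008, 0.02, 0.08)
    } else draw_clip(n_units, 0.050, 0.010, 0.025, 0.10)
    ec50 <- if (preset == "grm6_like") stats::rnorm(n_units, 15.6, 0.15)
            else stats::rnorm(n_units, 13.5, 0.2)
    data.frame(
      w_on = w_on, w_off = w_off, latency_s = lat,
      transience_tau_s = loguni(n_units, 0.12, 1.8),
      # broad contrast sensitivity incl. high-sensitivity units, median ~0.45
      c50_true = 0.15 + 0.8 * stats::rbeta(n_units, 1.6, 2.6),
      nr_slope_true = stats::runif(n_units, 2, 5),
      # diverse temporal preference across 1-8 Hz, median ~2 Hz
      peak_tf_true = 2^(3 * stats::rbeta(n_units, 1.2, 2.2)),
      tf_spread_true = stats::runif(n_units, 0.6, 2),
      hill_ec50_log = ec50,
      hill_slope = stats::runif(n_units, 0.8, 1.5),
      baseline_rate = stats::runif(n_units, 1, 6),
      gain = stats::runif(n_units, 30, 80),
      reliability = reliability)
  } else {
    stop("unknown preset: ", preset)
  }
}

#' Generate a synthetic unit population with known ground truth
#'
#' Draws per-unit ground-truth parameters from a population preset, evaluates
#' the forward model for each unit under the chirp, and samples spike trains.
#' Presets emulate the qualitative population structure of the recordings the
#' pipeline targets: `"grm6_like"` (diverse polarity including OFF and ON-OFF
#' units, broad contrast sensitivity including c50 < 0.5, diverse temporal
#' tuning), `"brn3c_like"` (almost exclusively ON-biased, more sustained,
#' contrast c50 concentrated >= 0.6, temporal tuning concentrated near 2 Hz),
#' and `"wt_like"` (diverse, photoreceptor-level irradiance sensitivity).
#'
#' @param preset One of `"grm6_like"`, `"brn3c_like"`, `"wt_like"`.
#' @param n_units,n_trials Population size and trials per unit.
#' @param seed Integer seed (full determinism).
#' @param stim Chirp stimulus; defaults to 1 kHz at 15.95 log photons/cm^2/s.
#' @param reliability Trial-to-trial reliability for all units.
#' @return List with `spikes` (a `spike_train_set`) and `ground_truth`
#'   (data.frame, one row per unit).
#' @examples
#' pop <- make_population("grm6_like", n_units = 5, n_trials = 4, seed = 1)
#' pop$ground_truth[, c("w_on", "w_off", "c50_true", "peak_tf_true")]
#' @export
make_population <- function(preset = c("grm6_like", "brn3c_like", "wt_like"),
                            n_units, n_trials, seed,
                            stim = build_chirp(1000, 15.95),
                            reliability = 0.8) {
  preset <- match.arg(preset)
  stopifnot(n_units >= 1, n_trials >= 1)
  gt <- with_seed(seed, preset_params(preset, n_units, reliability))
  gt$unit_id <- sprintf("%s_%03d", preset, seq_len(n_units))
  units <- vector("list", n_units)
  for (u in seq_len(n_units)) {
    p <- as.list(gt[u, setdiff(names(gt), "unit_id")])
    g <- do.call(unit_ground_truth, p[setdiff(names(p), "reliability")])
    rate <- rate_model(g, stim)
    units[[u]] <- list(
      unit_id = gt$unit_id[u], condition = preset, tissue = "retina",
      trials = sample_spikes(rate, stim$sample_rate, n_trials,
                             reliability = reliability,
                             seed = seed + 1000L + u))
  }
  spikes <- structure(
    list(units = units, stimulus = stim, n_trials = n_trials,
         rng_seed = seed),
    class = "spike_train_set")
  list(spikes = spikes, ground_truth = gt)
}

#' @export
print.spike_train_set <- function(x, ...) {
  cat("Spike train set:", length(x$units), "units x", x$n_trials,
      "trials; irradiance", x$stimulus$irradiance_log, "log photons\n")
  invisible(x)
}

#' Read/write spike sets as CSV
#'
#' Long-format CSV with columns `unit_id`, `condition`, `tissue`, `trial`,
#' `spike_time_s`. Trials with no spikes are preserved via `n_trials`.
#'
#' @param x A `spike_train_set`.
#' @param path CSV path.
#' @export
write_spike_set <- function(x, path) {
  stopifnot(inherits(x, "spike_train_set"))
  rows <- do.call(rbind, lapply(x$units, function(u) {
    do.call(rbind, lapply(seq_along(u$trials), function(tr) {
      st <- u$trials[[tr]]
      if (length(st) == 0) return(NULL)
      data.frame(unit_id = u$unit_id, condition = u$condition,
                 tissue = u$tissue, trial = tr, spike_time_s = st)
    }))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spike_set
#' @param n_trials Trial count of the recording (restores empty trials).
#' @param stim Stimulus to attach.
#' @export
read_spike_set <- function(path, n_trials, stim = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ids <- unique(df$unit_id)
  units <- lapply(ids, function(id) {
    d <- df[df$unit_id == id, ]
    trials <- lapply(seq_len(n_trials),
                     function(tr) sort(d$spike_time_s[d$trial == tr]))
    list(unit_id = id, condition = d$condition[1], tissue = d$tissue[1],
         trials = trials)
  })
  structure(list(units = units, stimulus = stim, n_trials = n_trials,
                 rng_seed = NA_integer_),
            class = "spike_train_set")
}

#' Write a ground-truth table as JSON
#' @param gt Ground-truth data.frame from [make_population()].
#' @param path Output path.
#' @export
write_ground_truth <- function(gt, path) {
  jsonlite::write_json(gt, path, dataframe = "rows", digits = NA,
                       pretty = TRUE)
  invisible(path)
}
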