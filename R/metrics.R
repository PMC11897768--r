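#' Baseline-subtracted response amplitude to the light step
#'
#' Baseline is the mean firing rate during 2 s of darkness preceding step
#' onset; since trials are presented back-to-back the dark tail of the chirp
#' (\[28, 30) s) serves as that baseline by default. Amplitude is the maximum
#' of (mean rate - baseline) over the step and the 3 s after it, capturing
#' both ON and OFF excitation.
#'
#' @param psth A [bin_psth()] matrix (25 ms) covering both windows.
#' @param response_window Window searched for the peak, default `[0, 6)` s.
#' @param baseline_window Baseline window, default `[28, 30)` s.
#' @return Amplitude in spikes/s.
#' @export
response_amplitude <- function(psth, response_window = c(0, 6),
                               baseline_window = c(28, 30)) {
  stopifnot(inherits(psth, "psth_matrix"))
  in_win <- function(w) psth$t0 >= w[1] & psth$t0 < w[2]
  if (!any(in_win(baseline_window))) stop("baseline window not covered")
  if (!any(in_win(response_window))) stop("response window not covered")
  baseline <- mean(psth$rate[in_win(baseline_window)])
  max(psth$rate[in_win(response_window)] - baseline)
}

#' Fit an irradiance-response (Hill) curve
#'
#' Least-squares fit of
#' `A(I) = bottom + (top - bottom) / (1 + 10^(slope * (ec50_log - I)))`
#' with four free parameters (top, bottom, slope, EC50), used to estimate
#' photosensitivity from response amplitudes across the irradiance ladder.
#'
#' @param amplitudes Mean response amplitudes per irradiance (spikes/s).
#' @param irradiances Irradiances, log10 photons/cm^2/s (>= 4 levels).
#' @return A `hill_fit` list: `top`, `bottom`, `slope`, `ec50_log`, `r2`.
#' @export
fit_hill <- function(amplitudes, irradiances) {
  if (length(amplitudes) != length(irradiances) || length(amplitudes) < 4) {
    stop("need >= 4 matched irradiance levels")
  }
  if (!all(is.finite(amplitudes)) || !all(is.finite(irradiances))) {
    stop("non-finite inputs")
  }
  y <- amplitudes
  rng <- diff(range(y))
  model <- function(p, x) {
    p[["bottom"]] + (p[["top"]] - p[["bottom"]]) /
      (1 + 10^(p[["slope"]] * (p[["ec50_log"]] - x)))
  }
  lower <- c(top = min(y) - rng, bottom = min(y) - rng, slope = 0.05,
             ec50_log = min(irradiances) - 3)
  upper <- c(top = max(y) + 2 * rng + 1e-6, bottom = max(y) + rng + 1e-6,
             slope = 10, ec50_log = max(irradiances) + 3)
  mids <- stats::quantile(irradiances, c(0.25, 0.5, 0.75))
  starts <- lapply(c(mids, mean(irradiances), stats::median(irradiances)),
                   function(m) c(top = max(y), bottom = min(y), slope = 1,
                                 ec50_log = unname(m)))
  fit <- fit_bounded_ls(starts, function(p) y - model(p, irradiances),
                        lower, upper, y)
  if (is.null(fit$par)) stop("Hill fit failed")
  structure(list(top = unname(fit$par[["top"]]),
                 bottom = unname(fit$par[["bottom"]]),
                 slope = unname(fit$par[["slope"]]),
                 ec50_log = unname(fit$par[["ec50_log"]]),
                 r2 = fit$r2),
            class = "hill_fit")
}

#' Quality index of response reproducibility
#'
#' `QI = Var_time[ mean_repeats(counts) ] / mean_repeats[ Var_time(counts) ]`
#' on a time-bins x repeats spike-count matrix (200 ms bins by convention).
#' Population variances are used in both numerator and denominator. The index
#' runs from 0 (activity unrelated across trials) to 1 (identical response on
#' every trial); it is defined as 0 when every trial is constant over time.
#'
#' @param psth A [bin_psth()] matrix with >= 2 trials.
#' @return QI in \[0, 1\].
#' @export
quality_index <- function(psth) {
  stopifnot(inherits(psth, "psth_matrix"), ncol(psth$counts) >= 2)
  m <- psth$counts
  denom <- mean(apply(m, 2, pop_var))
  if (denom == 0) return(0)
  pop_var(rowMeans(m)) / denom
}

#' Greedy firing-rate matching between two unit groups
#'
#' Pairs units across groups by nearest mean firing rate, without
#' replacement, accepting only pairs closer than `caliper_sd` pooled standard
#' deviations. Used to compare reproducibility between populations while
#' controlling for firing rate. A two-sample KS test on the matched rates is
#' reported as a self-check (p should exceed ~0.2).
#'
#' @param rates_a,rates_b Mean chirp firing rates (spikes/s) per unit.
#' @param caliper_sd Maximum pair distance in pooled-SD units.
#' @return List: `idx_a`, `idx_b` (matched indices, equal length), `ks_p`.
#'   Empty matching (with a warning) when no pair is within the caliper.
#' @export
match_firing_rate <- function(rates_a, rates_b, caliper_sd = 0.2) {
  stopifnot(length(rates_a) >= 1, length(rates_b) >= 1)
  tol <- caliper_sd * stats::sd(c(rates_a, rates_b))
  if (!is.finite(tol)) tol <- 0
  d <- abs(outer(rates_a, rates_b, "-"))
  idx_a <- integer(0)
  idx_b <- integer(0)
  while (TRUE) {
    k <- which.min(d)
    if (length(k) == 0 || d[k] > tol) break
    i <- (k - 1) %% nrow(d) + 1
    j <- (k - 1) %/% nrow(d) + 1
    idx_a <- c(idx_a, i)
    idx_b <- c(idx_b, j)
    d[i, ] <- Inf
    d[, j] <- Inf
    if (all(!is.finite(d))) break
  }
  if (length(idx_a) == 0) {
    warning("no rate pairs within caliper; returning empty matching")
    return(list(idx_a = integer(0), idx_b = integer(0), ks_p = NA_real_))
  }
  ks_p <- if (length(idx_a) >= 3) {
    suppressWarnings(stats::ks.test(rates_a[idx_a], rates_b[idx_b])$p.value)
  } else NA_real_
  list(idx_a = idx_a, idx_b = idx_b, ks_p = ks_p)
}

#' Latency of the response to step onset
#'
#' The 1 ms mean-rate PSTH is smoothed with a 10 ms boxcar applied
#' forward-backward (zero phase). The threshold is the mean plus 2 standard
#' deviations of the smoothed trace over 300 ms of pre-onset baseline (the
#' dark tail of the preceding trial by default); latency is the time of the
#' first bin in (0, 0.3\] s exceeding it. Units that never exceed threshold
#' (e.g. OFF units) return `NA`.
#'
#' @param psth A [bin_psth()] matrix at 1 ms covering `[0, 30)` s.
#' @param search_s Search horizon after onset, s.
#' @param baseline_window 300 ms baseline window, default `[29.7, 30)` s.
#' @return Latency in s, or `NA` if threshold is never exceeded.
#' @export
latency_to_onset <- function(psth, search_s = 0.3,
                             baseline_window = c(29.7, 30)) {
  stopifnot(inherits(psth, "psth_matrix"))
  k <- max(1L, round(0.010 / psth$bin_s))
  sm <- as.numeric(signal::filtfilt(rep(1 / k, k), 1, psth$rate))
  base <- sm[psth$t0 >= baseline_window[1] & psth$t0 < baseline_window[2]]
  if (length(base) < 2) stop("baseline window not covered")
  thr <- mean(base) + 2 * stats::sd(base)
  i <- which(psth$t0 > 0 & psth$t0 <= search_s & sm > thr)
  if (length(i) == 0) return(NA_real_)
  psth$t0[min(i)]
}

#' ON-OFF bias index
#'
#' `(ON - OFF) / (ON + OFF)` where ON and OFF are the total spike counts in
#' the 500 ms after step onset and step offset respectively; ranges from -1
#' (firing to OFF only) through 0 (equal) to 1 (ON only). 0/0 is defined as 0.
#'
#' @param trials List of per-trial spike-time vectors.
#' @param onset_s,offset_s Step onset/offset times, s.
#' @param win_s Window length after each event, s.
#' @return Bias index in \[-1, 1\].
#' @export
bias_index <- function(trials, onset_s = 0, offset_s = 3, win_s = 0.5) {
  st <- all_spikes(trials)
  on <- sum(st >= onset_s & st < onset_s + win_s)
  off <- sum(st >= offset_s & st < offset_s + win_s)
  if (on + off == 0) return(0)
  (on - off) / (on + off)
}

#' Transience index
#'
#' The 25 ms mean PSTH is normalized to the maximum firing rate over the step
#' epoch (\[0, 4) s, covering the step and the 1 s post-offset window so both
#' polarities normalize within range). The index is the mean of the
#' normalized trace over 1 s after stimulus onset for ON units (bias index
#' > -0.33) or 1 s after offset for OFF units: 0 = highly transient,
#' 1 = sustained with identical response across all bins.
#'
#' @param psth A [bin_psth()] matrix at 25 ms covering `[0, 4)` s.
#' @param bias Bias index from [bias_index()].
#' @param onset_s,offset_s Step timing, s.
#' @param off_threshold Bias below which the unit is treated as OFF.
#' @return Index in \[0, 1\], or `NA` if the unit is silent during the step
#'   epoch.
#' @export
transience_index <- function(psth, bias, onset_s = 0, offset_s = 3,
                             off_threshold = -0.33) {
  stopifnot(inherits(psth, "psth_matrix"))
  norm_win <- c(onset_s, offset_s + 1)
  in_win <- function(w) psth$t0 >= w[1] & psth$t0 < w[2]
  mx <- max(psth$rate[in_win(norm_win)])
  if (mx == 0) return(NA_real_)
  w <- if (bias > off_threshold) c(onset_s, onset_s + 1)
       else c(offset_s, offset_s + 1)
  mean(psth$rate[in_win(w)]) / mx
}

#' Response-category classification
#'
#' OFF if bias < -`bias_threshold`; ON-OFF if |bias| <= `bias_threshold`;
#' otherwise ON, split into transient vs sustained at
#' `transience_threshold`.
#'
#' @param bias Bias index.
#' @param transience Transience index (may be `NA` for OFF/ON-OFF calls).
#' @param bias_threshold,transience_threshold Classification cutoffs.
#' @return One of `"OFF"`, `"ON_OFF"`, `"ON_transient"`, `"ON_sustained"`.
#' @export
classify_response <- function(bias, transience, bias_threshold = 0.33,
                              transience_threshold = 0.5) {
  if (bias < -bias_threshold) return("OFF")
  if (abs(bias) <= bias_threshold) return("ON_OFF")
  if (!is.na(transience) && transience >= transience_threshold) {
    "ON_sustained"
  } else {
    "ON_transient"
  }
}
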