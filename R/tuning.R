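#' Contrast-response profile from the contrast chirp
#'
#' The contrast chirp presents each Michelson contrast for one 0.5 s cycle of
#' its 2 Hz carrier (16 cycles over 17-25 s). Response amplitude per cycle is
#' max - min of the mean firing rate (25 ms bins) within the cycle,
#' normalized by the same measure over the 0.5 s immediately before chirp
#' onset, and paired with the cycle's mean Michelson contrast from the
#' stimulus envelope.
#'
#' @param psth A [bin_psth()] matrix at 25 ms covering `[16.5, 25)` s.
#' @param stim The [build_chirp()] stimulus.
#' @return List: `contrast`, `amplitude` (normalized), `raw_amplitude`,
#'   `normalizer`, `frac_active_bins` (trial-summed active-bin fraction over
#'   the segment), `flagged` (TRUE when the normalizer is zero).
#' @export
contrast_profile <- function(psth, stim) {
  stopifnot(inherits(psth, "psth_matrix"), inherits(stim, "chirp_stimulus"))
  seg <- stim$segments["contrast_chirp", ]
  cyc_starts <- seq(seg[["start"]], seg[["end"]] - 0.5, by = 0.5)
  amp_in <- function(w1, w2) {
    r <- psth$rate[psth$t0 >= w1 & psth$t0 < w2]
    max(r) - min(r)
  }
  raw <- vapply(cyc_starts, function(s) amp_in(s, s + 0.5), numeric(1))
  contrast <- contrast_envelope(cyc_starts - seg[["start"]] + 0.25)
  normalizer <- amp_in(seg[["start"]] - 0.5, seg[["start"]])
  in_seg <- psth$t0 >= seg[["start"]] & psth$t0 < seg[["end"]]
  frac <- mean(rowSums(psth$counts[in_seg, , drop = FALSE]) >= 1)
  flagged <- normalizer == 0
  list(contrast = contrast,
       amplitude = if (flagged) rep(NA_real_, length(raw)) else raw / normalizer,
       raw_amplitude = raw, normalizer = normalizer,
       frac_active_bins = frac, flagged = flagged)
}

#' Fit a Naka-Rushton contrast-response function
#'
#' `R(C) = bottom + (top - bottom) * C^n / (C^n + c50^n)` fitted by bounded
#' least squares with C50 constrained to \[0, 1\] and slope to \[0, 10\].
#' Inclusion requires fit R^2 > 0.5 and spiking in more than 10% of the
#' contrast-chirp bins.
#'
#' @param profile Output of [contrast_profile()].
#' @param n_starts Number of seeded multi-start initializations.
#' @return A `naka_rushton_fit`: `top`, `bottom`, `slope`, `c50`, `r2`,
#'   `included`.
#' @export
fit_naka_rushton <- function(profile, n_starts = 5) {
  y <- profile$amplitude
  x <- profile$contrast
  if (isTRUE(profile$flagged) || any(!is.finite(y))) {
    return(structure(list(top = NA_real_, bottom = NA_real_, slope = NA_real_,
                          c50 = NA_real_, r2 = NA_real_, included = FALSE),
                     class = "naka_rushton_fit"))
  }
  if (length(y) < 6) stop("need >= 6 contrast points")
  model <- function(p, x) {
    p[["bottom"]] + (p[["top"]] - p[["bottom"]]) *
      x^p[["slope"]] / (x^p[["slope"]] + p[["c50"]]^p[["slope"]])
  }
  rng <- max(diff(range(y)), 1e-9)
  lower <- c(top = min(y) - rng, bottom = min(y) - rng, slope = 1e-2,
             c50 = 1e-3)
  upper <- c(top = max(y) + 2 * rng, bottom = max(y) + rng, slope = 10,
             c50 = 1)
  c50_grid <- seq(0.1, 0.9, length.out = n_starts)
  starts <- lapply(c50_grid, function(cc) {
    c(top = max(y), bottom = min(y), slope = 3, c50 = cc)
  })
  fit <- fit_bounded_ls(starts, function(p) y - model(p, x), lower, upper,
                        y, prefer = "c50")
  if (is.null(fit$par)) {
    return(structure(list(top = NA_real_, bottom = NA_real_, slope = NA_real_,
                          c50 = NA_real_, r2 = NA_real_, included = FALSE),
                     class = "naka_rushton_fit"))
  }
  r2 <- fit$r2
  structure(list(top = unname(fit$par[["top"]]),
                 bottom = unname(fit$par[["bottom"]]),
                 slope = unname(fit$par[["slope"]]),
                 c50 = unname(fit$par[["c50"]]), r2 = r2,
                 included = isTRUE(r2 > 0.5) &&
                   profile$frac_active_bins > 0.10),
            class = "naka_rushton_fit")
}

#' Temporal-frequency response profile from the temporal chirp
#'
#' Cycle boundaries are computed analytically from the chirp phase (36 cycles
#' over 7-15 s, instantaneous frequency 1-8 Hz). Per-cycle amplitudes
#' (max - min of mean rate, 25 ms bins) are grouped into the seven integer
#' frequency bands 1-2, ..., 7-8 Hz by each cycle's mean instantaneous
#' frequency, averaged per band, and paired with the band's mean frequency.
#' Amplitudes are normalized by the max - min over the 0.5 s before chirp
#' onset.
#'
#' @param psth A [bin_psth()] matrix at 25 ms covering `[6.5, 15)` s.
#' @param stim The [build_chirp()] stimulus.
#' @return List: `frequency` (Hz), `amplitude` (normalized band means),
#'   `frac_active_bins`, `flagged`.
#' @export
temporal_profile <- function(psth, stim) {
  stopifnot(inherits(psth, "psth_matrix"), inherits(stim, "chirp_stimulus"))
  seg <- stim$segments["temporal_chirp", ]
  # local times where the phase completes m cycles: 2pi m = phase(t)
  m <- 0:36
  tl <- (8 / 7) * (sqrt(1 + 1.75 * m) - 1)  # root of 7t^2/16 + t - m = 0
  bounds <- seg[["start"]] + tl
  amp_in <- function(w1, w2) {
    r <- psth$rate[psth$t0 >= w1 & psth$t0 < w2]
    if (length(r) == 0) return(NA_real_)
    max(r) - min(r)
  }
  cyc_amp <- vapply(seq_len(36), function(k) amp_in(bounds[k], bounds[k + 1]),
                    numeric(1))
  f_mid <- vapply(seq_len(36), function(k) {
    mean(chirp_instant_freq(c(tl[k], tl[k + 1])))
  }, numeric(1))
  band <- pmin(floor(f_mid), 7)
  freq <- vapply(1:7, function(b) mean(f_mid[band == b]), numeric(1))
  raw <- vapply(1:7, function(b) mean(cyc_amp[band == b], na.rm = TRUE),
                numeric(1))
  normalizer <- amp_in(seg[["start"]] - 0.5, seg[["start"]])
  in_seg <- psth$t0 >= seg[["start"]] & psth$t0 < seg[["end"]]
  frac <- mean(rowSums(psth$counts[in_seg, , drop = FALSE]) >= 1)
  flagged <- is.na(normalizer) || normalizer == 0
  list(frequency = freq,
       amplitude = if (flagged) rep(NA_real_, 7) else raw / normalizer,
       raw_amplitude = raw, normalizer = normalizer,
       frac_active_bins = frac, flagged = flagged)
}

#' Fit a half-Gaussian temporal-frequency tuning curve
#'
#' `A(f) = b(f) + (peak_amp - b(f)) * exp(-(log2 f - log2 peak_tf)^2 /
#' (2 spread^2))` where the baseline `b(f)` is `low_baseline` below the peak
#' and `high_baseline` at or above it — five free parameters on a log2
#' frequency axis, so `spread` is in octaves. Peak TF is constrained to
#' \[1, 8\] Hz. Inclusion requires R^2 > 0.5, spiking in more than 10% of
#' bins, and spread > 0.51 octaves.
#'
#' @param profile Output of [temporal_profile()].
#' @param n_starts Number of multi-start initializations.
#' @return A `half_gaussian_fit`: `low_baseline`, `high_baseline`, `spread`,
#'   `peak_amp`, `peak_tf`, `r2`, `included`.
#' @export
fit_half_gaussian <- function(profile, n_starts = 5) {
  y <- profile$amplitude
  x <- profile$frequency
  empty <- structure(list(low_baseline = NA_real_, high_baseline = NA_real_,
                          spread = NA_real_, peak_amp = NA_real_,
                          peak_tf = NA_real_, r2 = NA_real_,
                          included = FALSE),
                     class = "half_gaussian_fit")
  if (isTRUE(profile$flagged) || any(!is.finite(y))) return(empty)
  if (length(y) < 5) stop("need >= 5 frequency points")
  # internally peak_amp = max(baselines) + peak_excess (>= 0), so the fitted
  # curve always has its maximum at peak_tf (no inverted-Gaussian solutions)
  model <- function(p, x) {
    side <- ifelse(x < p[["peak_tf"]], p[["low_baseline"]],
                   p[["high_baseline"]])
    pk <- max(p[["low_baseline"]], p[["high_baseline"]]) + p[["peak_excess"]]
    side + (pk - side) *
      exp(-(log2(x) - log2(p[["peak_tf"]]))^2 / (2 * p[["spread"]]^2))
  }
  rng <- max(diff(range(y)), 1e-9)
  lower <- c(low_baseline = min(y) - rng, high_baseline = min(y) - rng,
             spread = 0.05, peak_excess = 0, peak_tf = 1)
  upper <- c(low_baseline = max(y) + rng, high_baseline = max(y) + rng,
             spread = 6, peak_excess = 3 * rng, peak_tf = 8)
  tf_grid <- 2^seq(0.2, 2.8, length.out = n_starts)
  starts <- lapply(tf_grid, function(tf) {
    c(low_baseline = min(y), high_baseline = min(y), spread = 1,
      peak_excess = diff(range(y)), peak_tf = tf)
  })
  fit <- fit_bounded_ls(starts, function(p) y - model(p, x), lower, upper, y)
  if (is.null(fit$par)) return(empty)
  r2 <- fit$r2
  structure(list(low_baseline = unname(fit$par[["low_baseline"]]),
                 high_baseline = unname(fit$par[["high_baseline"]]),
                 spread = unname(fit$par[["spread"]]),
                 peak_amp = unname(max(fit$par[["low_baseline"]],
                                       fit$par[["high_baseline"]]) +
                                   fit$par[["peak_excess"]]),
                 peak_tf = unname(fit$par[["peak_tf"]]), r2 = r2,
                 included = isTRUE(r2 > 0.5) &&
                   profile$frac_active_bins > 0.10 &&
                   isTRUE(fit$par[["spread"]] > 0.51)),
            class = "half_gaussian_fit")
}

#' Bootstrap confidence intervals for tuning parameters
#'
#' Resamples trials with replacement, recomputes the contrast and
#' temporal-frequency profiles and their fits, and returns percentile
#' confidence intervals for C50 and peak temporal frequency.
#'
#' @param trials List of per-trial spike-time vectors.
#' @param stim The [build_chirp()] stimulus.
#' @param n_boot Bootstrap replicates.
#' @param level Confidence level.
#' @param seed Integer seed.
#' @return List with `c50_ci`, `peak_tf_ci` (length-2 numeric), and the
#'   bootstrap `draws` data frame.
#' @export
bootstrap_tuning_ci <- function(trials, stim, n_boot = 200, level = 0.95,
                                seed = 1L) {
  stopifnot(length(trials) >= 2, n_boot >= 10)
  idx <- with_seed(seed, {
    matrix(sample.int(length(trials), n_boot * length(trials),
                      replace = TRUE), nrow = n_boot)
  })
  draws <- do.call(rbind, lapply(seq_len(n_boot), function(b) {
    psth <- bin_psth(trials[idx[b, ]], 0.025, c(0, stim$total_duration_s))
    nr <- fit_naka_rushton(contrast_profile(psth, stim))
    hg <- fit_half_gaussian(temporal_profile(psth, stim))
    data.frame(c50 = nr$c50, peak_tf = hg$peak_tf)
  }))
  a <- (1 - level) / 2
  ci <- function(x) {
    x <- x[is.finite(x)]
    if (length(x) < 10) return(c(NA_real_, NA_real_))
    unname(stats::quantile(x, c(a, 1 - a)))
  }
  list(c50_ci = ci(draws$c50), peak_tf_ci = ci(draws$peak_tf), draws = draws)
}
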