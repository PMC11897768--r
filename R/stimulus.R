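#' Build the full-field chirp stimulus
#'
#' Constructs the 30 s chirp used throughout the pipeline: a 3 s step from
#' dark to full intensity, 2 s dark, 2 s at 50% intensity, an 8 s temporal
#' chirp (full-contrast sinusoid accelerating from 1 to 8 Hz), 2 s at 50%,
#' an 8 s contrast chirp (2 Hz sinusoid whose Michelson contrast ramps
#' linearly from 3% to 97%), 2 s at 50%, and 3 s dark.
#'
#' The waveform is normalized relative intensity in \[0, 1\]; irradiance is
#' carried as metadata (log10 photons/cm^2/s at 100% intensity) and never
#' rescales the waveform. Each sinusoidal segment starts at phase 0 (value
#' 0.5, rising). Segment intervals are half-open \[start, end) in seconds
#' with stimulus onset at t = 0.
#'
#' @param sample_rate Samples per second; must be >= 200 so the 8 Hz end of
#'   the temporal chirp is resolved with at least 25 samples per cycle.
#' @param irradiance_log Irradiance at 100% intensity, log10 photons/cm^2/s.
#' @return An object of class `chirp_stimulus`: list with `sample_rate`,
#'   `time` (s), `waveform`, `segments` (named 2-column matrix of
#'   \[start, end) in s), `irradiance_log`, `total_duration_s`.
#' @examples
#' stim <- build_chirp(1000, 16.97)
#' stim$segments["temporal_chirp", ]
#' @export
build_chirp <- function(sample_rate, irradiance_log = NA_real_) {
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 ||
      !is.finite(sample_rate) || sample_rate < 200) {
    stop("`sample_rate` must be a single number >= 200 samples/s")
  }
  durs <- c(step = 3, dark1 = 2, plateau1 = 2, temporal_chirp = 8,
            plateau2 = 2, contrast_chirp = 8, plateau3 = 2, dark2 = 3)
  ends <- cumsum(durs)
  starts <- ends - durs
  segments <- cbind(start = starts, end = ends)
  rownames(segments) <- names(durs)
  total <- unname(ends[length(ends)])

  n <- round(total * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  w <- numeric(n)

  seg_idx <- function(name) {
    t >= segments[name, "start"] & t < segments[name, "end"]
  }
  w[seg_idx("step")] <- 1
  w[seg_idx("plateau1")] <- 0.5
  w[seg_idx("plateau2")] <- 0.5
  w[seg_idx("plateau3")] <- 0.5
  # temporal chirp: instantaneous frequency ramps linearly 1 -> 8 Hz over 8 s
  i <- seg_idx("temporal_chirp")
  tl <- t[i] - segments["temporal_chirp", "start"]
  w[i] <- 0.5 + 0.5 * sin(chirp_phase(tl))
  # contrast chirp: 2 Hz carrier, Michelson contrast ramps 3% -> 97%
  i <- seg_idx("contrast_chirp")
  tl <- t[i] - segments["contrast_chirp", "start"]
  w[i] <- 0.5 + 0.5 * contrast_envelope(tl) * sin(2 * pi * 2 * tl)

  structure(
    list(sample_rate = sample_rate, time = t, waveform = w,
         segments = segments, irradiance_log = irradiance_log,
         total_duration_s = total),
    class = "chirp_stimulus")
}

#' Instantaneous phase and frequency of the temporal chirp
#'
#' The temporal chirp sweeps from 1 Hz to 8 Hz over its 8 s, so
#' f(t) = 1 + (7/8) t (t local to the segment) and the phase is the integral
#' phi(t) = 2 pi (t + 7 t^2 / 16), giving 36 full cycles.
#'
#' @param t_local Time in seconds from temporal-chirp start.
#' @return `chirp_phase`: phase in radians; `chirp_instant_freq`: Hz.
#' @keywords internal
chirp_phase <- function(t_local) 2 * pi * (t_local + 7 * t_local^2 / 16)

#' @rdname chirp_phase
#' @keywords internal
chirp_instant_freq <- function(t_local) 1 + 7 * t_local / 8

#' Michelson contrast of the contrast chirp at local time t
#' @param t_local Time in seconds from contrast-chirp start.
#' @keywords internal
contrast_envelope <- function(t_local) 0.03 + (0.97 - 0.03) * t_local / 8

#' Irradiance ladder
#'
#' Ascending list of stimulus irradiances, stepped in decades from the dimmest
#' level; the final value is capped at `max_log` (stimuli are presented from
#' lowest to brightest intensity).
#'
#' @param min_log,max_log Range in log10 photons/cm^2/s; `min_log < max_log`.
#' @param step_log Step between levels in decades (> 0).
#' @return Numeric vector of irradiances, ascending, last element `max_log`.
#' @examples
#' irradiance_ladder(12.99, 16.97, 1.0)
#' @export
irradiance_ladder <- function(min_log, max_log, step_log = 1.0) {
  if (!is.finite(min_log) || !is.finite(max_log) || min_log >= max_log) {
    stop("`min_log` must be strictly below `max_log`")
  }
  if (!is.finite(step_log) || step_log <= 0) {
    stop("`step_log` must be positive")
  }
  out <- seq(min_log, max_log, by = step_log)
  if (max_log - out[length(out)] > 1e-9) out <- c(out, max_log)
  out[length(out)] <- max_log
  out
}

#' Write a chirp stimulus to disk
#'
#' Writes the sampled waveform as a two-column CSV (`time_s`,
#' `relative_intensity`) and a JSON sidecar holding the segment table,
#' sample rate and irradiance.
#'
#' @param stim A `chirp_stimulus`.
#' @param csv_path,json_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_stimulus <- function(stim, csv_path, json_path) {
  stopifnot(inherits(stim, "chirp_stimulus"))
  utils::write.csv(
    data.frame(time_s = stim$time, relative_intensity = stim$waveform),
    csv_path, row.names = FALSE)
  side <- list(
    sample_rate = stim$sample_rate,
    total_duration_s = stim$total_duration_s,
    irradiance_log = stim$irradiance_log,
    segments = as.data.frame(stim$segments))
  jsonlite::write_json(side, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(c(csv_path, json_path))
}

#' @export
print.chirp_stimulus <- function(x, ...) {
  cat("Chirp stimulus:", x$total_duration_s, "s at", x$sample_rate,
      "samples/s; irradiance", x$irradiance_log, "log photons/cm^2/s\n")
  print(x$segments)
  invisible(x)
}

# Piecewise-constant segment envelope (mean level per segment): the slow
# intensity transitions that drive step-like ON/OFF excitation, with the
# sinusoidal modulations removed.
segment_envelope <- function(stim) {
  lev <- c(step = 1, dark1 = 0, plateau1 = 0.5, temporal_chirp = 0.5,
           plateau2 = 0.5, contrast_chirp = 0.5, plateau3 = 0.5, dark2 = 0)
  e <- numeric(length(stim$time))
  for (nm in rownames(stim$segments)) {
    i <- stim$time >= stim$segments[nm, "start"] &
      stim$time < stim$segments[nm, "end"]
    e[i] <- lev[[nm]]
  }
  e
}
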