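#' Bin one unit's spike trains into a PSTH matrix
#'
#' Counts spikes in half-open bins `[t, t + bin_s)` tiling the window
#' `[window[1], window[2])`; a spike exactly at the window end is excluded.
#' The number of bins is `ceiling((window[2] - window[1]) / bin_s)`.
#'
#' @param trials List of per-trial spike-time vectors (s, stimulus onset = 0).
#' @param bin_s Bin width, s (25 ms for responsiveness/indices, 200 ms for the
#'   quality index, 1 ms for latency, 50 ms for population features).
#' @param window Length-2 numeric, `[start, end)` in s.
#' @return A `psth_matrix`: list with `counts` (bins x trials), `bin_s`,
#'   `window`, `t0` (bin left edges) and `rate` (mean rate over trials,
#'   spikes/s).
#' @examples
#' psth <- bin_psth(list(c(0.01, 0.012, 0.03)), 0.025, c(0, 0.075))
#' psth$counts
#' @export
bin_psth <- function(trials, bin_s, window = c(0, 30)) {
  stopifnot(is.list(trials), length(trials) >= 1, bin_s > 0)
  if (window[2] <= window[1]) stop("empty window")
  n_bins <- ceiling((window[2] - window[1]) / bin_s)
  counts <- vapply(trials, function(st) {
    st <- st[st >= window[1] & st < window[2]]
    idx <- pmin(floor((st - window[1]) / bin_s) + 1L, n_bins)
    tabulate(idx, nbins = n_bins)
  }, integer(n_bins))
  counts <- matrix(counts, nrow = n_bins)
  structure(
    list(counts = counts, bin_s = bin_s, window = window,
         t0 = window[1] + (seq_len(n_bins) - 1) * bin_s,
         rate = rowMeans(counts) / bin_s),
    class = "psth_matrix")
}

#' Unit exclusion filter
#'
#' Applies the activity criteria used before any response analysis: a unit is
#' dropped if fewer than 10% of its (trial-summed) PSTH bins contain at least
#' one spike, or if fewer than `min_trials` trials contain any spike.
#'
#' @param psth A [bin_psth()] matrix at 25 ms over the full chirp.
#' @param min_frac_active Minimum fraction of trial-summed bins with spikes.
#' @param min_trials Minimum number of trials with any spike.
#' @return List: `keep` (logical), `frac_active_bins`, `n_active_trials`,
#'   `reasons` (character vector, possibly empty).
#' @export
exclusion_filter <- function(psth, min_frac_active = 0.10, min_trials = 8) {
  stopifnot(inherits(psth, "psth_matrix"))
  frac <- mean(rowSums(psth$counts) >= 1)
  n_act <- sum(colSums(psth$counts) >= 1)
  reasons <- character(0)
  if (frac < min_frac_active) reasons <- c(reasons, "low_rate")
  if (n_act < min_trials) reasons <- c(reasons, "few_trials")
  list(keep = length(reasons) == 0, frac_active_bins = frac,
       n_active_trials = n_act, reasons = reasons)
}

# mean pairwise Pearson correlation across trial columns; zero-variance
# columns contribute correlation 0 to every pair they appear in.
mean_intertrial_cor <- function(counts) {
  b <- nrow(counts)
  t <- ncol(counts)
  z <- standardize_cols(counts)
  p <- t * (t - 1) / 2
  (sum(rowSums(z)^2) - sum(z^2)) / (2 * (b - 1) * p)
}

standardize_cols <- function(counts) {
  mu <- colMeans(counts)
  cent <- sweep(counts, 2, mu)
  sdv <- sqrt(colSums(cent^2) / (nrow(counts) - 1))
  sdv[sdv == 0] <- Inf  # zero-variance trials become all-zero columns
  sweep(cent, 2, sdv, "/")
}

#' Shuffle test for light responsiveness
#'
#' Tests whether a unit's response is locked to the chirp by comparing the
#' mean pairwise Pearson correlation between its 25 ms-binned trials against
#' a null built by independently circularly shifting each trial's bin vector
#' by a uniform random offset. Circular shifts preserve each trial's rate and
#' autocorrelation, destroying only the alignment to the stimulus. The
#' p-value is `(1 + #{null >= observed}) / (n_shuffles + 1)`; a unit is light
#' responsive (LR) when `p < alpha` (default 1e-4, which requires
#' `n_shuffles >= 10000` to be attainable). Zero-variance trial vectors are
#' assigned pairwise correlation 0, a conservative convention.
#'
#' @param psth A [bin_psth()] matrix over the full chirp (>= 2 trials).
#' @param n_shuffles Number of circular-shift permutations.
#' @param seed Integer seed for the shift offsets.
#' @param alpha Significance threshold on the permutation p-value.
#' @return List of class `lr_result`: `statistic`, `p_value`, `n_shuffles`,
#'   `is_lr`.
#' @export
lr_shuffle_test <- function(psth, n_shuffles = 10000, seed = 1L,
                            alpha = 1e-4) {
  stopifnot(inherits(psth, "psth_matrix"))
  counts <- psth$counts
  b <- nrow(counts)
  t <- ncol(counts)
  if (t < 2) stop("need at least 2 trials")
  z <- standardize_cols(counts)
  p_pairs <- t * (t - 1) / 2
  denom <- 2 * (b - 1) * p_pairs
  sumsq <- sum(z^2)
  obs <- (sum(rowSums(z)^2) - sumsq) / denom
  offsets <- with_seed(seed, matrix(sample.int(b, n_shuffles * t,
                                               replace = TRUE) - 1L,
                                    nrow = n_shuffles))
  null_ss <- cpp_shift_null(z, offsets)
  null_stat <- (null_ss - sumsq) / denom
  pval <- (1 + sum(null_stat >= obs - 1e-12)) / (n_shuffles + 1)
  structure(list(statistic = obs, p_value = pval, n_shuffles = n_shuffles,
                 is_lr = pval < alpha),
            class = "lr_result")
}
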