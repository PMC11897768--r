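#' Per-unit analysis: responsiveness, indices and tuning fits
#'
#' Runs the full single-unit chain for every unit of a spike set: 25 ms PSTH
#' and exclusion filter, light-responsiveness shuffle test, response
#' amplitude, quality index (200 ms PSTH), latency (1 ms PSTH), ON-OFF bias,
#' transience, response category, contrast (Naka-Rushton) and
#' temporal-frequency (half-Gaussian) tuning fits. Metrics downstream of the
#' LR test are only computed for units that pass the exclusion filter and are
#' light responsive; others carry `NA`.
#'
#' @param spikes A `spike_train_set`.
#' @param n_shuffles Shuffles for the LR test.
#' @param lr_alpha LR significance threshold (1e-4 needs >= 10000 shuffles).
#' @param seed Integer seed.
#' @return Data frame, one row per unit: identifiers, filter diagnostics, LR
#'   statistics, response metrics and tuning parameters.
#' @export
analyze_units <- function(spikes, n_shuffles = 10000, lr_alpha = 1e-4,
                          seed = 1L) {
  stopifnot(inherits(spikes, "spike_train_set"))
  stim <- spikes$stimulus
  dur <- stim$total_duration_s
  rows <- lapply(seq_along(spikes$units), function(u) {
    unit <- spikes$units[[u]]
    psth25 <- bin_psth(unit$trials, 0.025, c(0, dur))
    filt <- exclusion_filter(psth25)
    out <- data.frame(
      unit_id = unit$unit_id, condition = unit$condition,
      tissue = unit$tissue, n_trials = length(unit$trials),
      frac_active_bins = filt$frac_active_bins,
      n_active_trials = filt$n_active_trials, keep = filt$keep,
      lr_statistic = NA_real_, lr_p = NA_real_, is_lr = FALSE,
      mean_rate = length(all_spikes(unit$trials)) /
        (dur * length(unit$trials)),
      amplitude = NA_real_, qi = NA_real_, latency_s = NA_real_,
      bias = NA_real_, transience = NA_real_, category = NA_character_,
      c50 = NA_real_, nr_slope = NA_real_, nr_r2 = NA_real_,
      nr_included = FALSE, peak_tf = NA_real_, tf_spread = NA_real_,
      hg_r2 = NA_real_, hg_included = FALSE)
    if (!filt$keep) return(out)
    lr <- lr_shuffle_test(psth25, n_shuffles = n_shuffles,
                          seed = seed + 17L * u, alpha = lr_alpha)
    out$lr_statistic <- lr$statistic
    out$lr_p <- lr$p_value
    out$is_lr <- lr$is_lr
    if (!lr$is_lr) return(out)
    out$amplitude <- response_amplitude(psth25)
    out$qi <- quality_index(bin_psth(unit$trials, 0.2, c(0, dur)))
    out$latency_s <- latency_to_onset(bin_psth(unit$trials, 0.001, c(0, dur)))
    out$bias <- bias_index(unit$trials)
    out$transience <- transience_index(psth25, out$bias)
    out$category <- classify_response(out$bias, out$transience)
    cp <- contrast_profile(psth25, stim)
    nr <- fit_naka_rushton(cp)
    out$c50 <- nr$c50
    out$nr_slope <- nr$slope
    out$nr_r2 <- nr$r2
    out$nr_included <- nr$included
    tp <- temporal_profile(psth25, stim)
    hg <- fit_half_gaussian(tp)
    out$peak_tf <- hg$peak_tf
    out$tf_spread <- hg$spread
    out$hg_r2 <- hg$r2
    out$hg_included <- hg$included
    out
  })
  do.call(rbind, rows)
}

#' Population PSTH matrix
#'
#' Mean firing rate over trials per unit, binned over the full chirp:
#' units x time-bins, the input to [segment_psth_features()].
#'
#' @param spikes A `spike_train_set`.
#' @param bin_s Bin width, s (50 ms for community detection).
#' @param unit_ids Optional subset/order of unit ids.
#' @return Numeric matrix with unit ids as rownames.
#' @export
population_psth <- function(spikes, bin_s = 0.05, unit_ids = NULL) {
  stopifnot(inherits(spikes, "spike_train_set"))
  dur <- spikes$stimulus$total_duration_s
  ids <- vapply(spikes$units, function(u) u$unit_id, character(1))
  if (is.null(unit_ids)) unit_ids <- ids
  idx <- match(unit_ids, ids)
  if (anyNA(idx)) stop("unknown unit ids")
  m <- t(vapply(spikes$units[idx], function(u) {
    bin_psth(u$trials, bin_s, c(0, dur))$rate
  }, numeric(ceiling(dur / bin_s))))
  rownames(m) <- unit_ids
  m
}

#' Population code structure: sparse PCs, consensus GMM, communities
#'
#' Characterizes the population "visual code": balanced downsampling across
#' conditions, sparse PCA on the three chirp segments, consensus
#' Gaussian-mixture clustering into a co-assignment similarity matrix,
#' Louvain community detection with small communities dropped, and shuffle
#' tests comparing community distributions between conditions.
#'
#' @param psth_pop Units x time matrix from [population_psth()] (50 ms bins).
#' @param condition Condition label per unit (row).
#' @param seed Integer seed for the whole stage.
#' @param n_repeats,k_max Consensus-clustering settings.
#' @param min_size Minimum retained community size.
#' @param n_shuffles Shuffles for the distribution test.
#' @param downsample Balance conditions to equal n before clustering.
#' @return List of class `code_structure_result`: `spca`, `similarity`,
#'   `k_selected`, `communities`, `community_sizes`,
#'   `condition_distributions`, `shuffle` (data frame), `index` (row indices
#'   of `psth_pop` analyzed), `condition`.
#' @export
run_code_structure <- function(psth_pop, condition, seed = 1L,
                               n_repeats = 50, k_max = 20, min_size = 5,
                               n_shuffles = 999, downsample = TRUE) {
  stopifnot(is.matrix(psth_pop), nrow(psth_pop) == length(condition))
  idx <- seq_len(nrow(psth_pop))
  if (downsample && length(unique(condition)) >= 2) {
    idx <- downsample_balanced(condition, seed = seed)
  }
  m <- psth_pop[idx, , drop = FALSE]
  cond <- condition[idx]
  segs <- segment_psth_features(m)
  spca <- sparse_pca(segs)
  cons <- consensus_cluster(spca$scores, n_repeats = n_repeats,
                            k_max = k_max, seed = seed + 1000L)
  comm <- detect_communities(cons$similarity, min_size = min_size,
                             seed = seed + 2000L)
  dist_tab <- table(condition = cond, community = comm, useNA = "no")
  shuffle <- if (length(unique(cond)) >= 2 && sum(!is.na(comm)) > 0) {
    distribution_shuffle_test(comm, cond, n_shuffles = n_shuffles,
                              seed = seed + 3000L)
  }
  structure(
    list(spca = spca, similarity = cons$similarity,
         k_selected = cons$k_selected, communities = comm,
         community_sizes = table(comm),
         condition_distributions = dist_tab, shuffle = shuffle,
         index = idx, condition = cond),
    class = "code_structure_result")
}

#' Full pipeline on one or more populations
#'
#' Convenience wrapper: per-unit analysis for each spike set, then code
#' structure on the pooled light-responsive units, then the summary report.
#'
#' @param spike_sets List of `spike_train_set`s (e.g. one per condition).
#' @param n_shuffles,lr_alpha LR-test settings (scaled runs can lower both).
#' @param seed Integer seed.
#' @param code_args List of extra arguments to [run_code_structure()].
#' @return List: `units` (combined per-unit data frame), `code`
#'   (`code_structure_result` or NULL if too few LR units), `report`.
#' @export
run_chirp_pipeline <- function(spike_sets, n_shuffles = 10000,
                               lr_alpha = 1e-4, seed = 1L,
                               code_args = list()) {
  if (inherits(spike_sets, "spike_train_set")) spike_sets <- list(spike_sets)
  units <- do.call(rbind, lapply(seq_along(spike_sets), function(i) {
    analyze_units(spike_sets[[i]], n_shuffles = n_shuffles,
                  lr_alpha = lr_alpha, seed = seed + 100000L * i)
  }))
  lr_ids <- units$unit_id[units$is_lr]
  code <- NULL
  if (length(lr_ids) >= 10) {
    pops <- lapply(spike_sets, function(s) {
      ids <- vapply(s$units, function(u) u$unit_id, character(1))
      population_psth(s, unit_ids = intersect(ids, lr_ids))
    })
    psth_pop <- do.call(rbind, pops)
    cond <- units$condition[match(rownames(psth_pop), units$unit_id)]
    code <- do.call(run_code_structure,
                    c(list(psth_pop = psth_pop, condition = cond,
                           seed = seed + 5L), code_args))
  }
  list(units = units, code = code, report = make_report(units))
}
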