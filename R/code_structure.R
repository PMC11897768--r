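#' Segment-wise population feature matrices
#'
#' Cuts a population PSTH (units x time, 50 ms bins over the full chirp, mean
#' over trials) into the three analysis windows — step at \[0.5, 4.5) s,
#' temporal chirp at \[6.5, 15.5) s, contrast chirp at \[17.5, 24.5) s — and
#' mean-centers each time bin within each segment. Widths are 80, 180 and 140
#' bins.
#'
#' @param psth_pop Numeric matrix, units x 600 time bins (50 ms over 30 s);
#'   rownames are unit ids.
#' @param bin_s Bin width of `psth_pop` (s).
#' @param normalize If `"max"` (default), each unit's PSTH is divided by its
#'   maximum before segmentation, so clustering reflects response shape
#'   rather than firing-rate scale; `"none"` keeps raw rates.
#' @return Named list of three centered matrices (`step`, `temporal_chirp`,
#'   `contrast_chirp`), same row order.
#' @export
segment_psth_features <- function(psth_pop, bin_s = 0.05,
                                  normalize = c("max", "none")) {
  stopifnot(is.matrix(psth_pop))
  normalize <- match.arg(normalize)
  if (normalize == "max") {
    mx <- apply(psth_pop, 1, max)
    psth_pop <- psth_pop / pmax(mx, 1e-12)
  }
  t0 <- (seq_len(ncol(psth_pop)) - 1) * bin_s
  windows <- list(step = c(0.5, 4.5), temporal_chirp = c(6.5, 15.5),
                  contrast_chirp = c(17.5, 24.5))
  out <- lapply(windows, function(w) {
    m <- psth_pop[, t0 >= w[1] & t0 < w[2], drop = FALSE]
    sweep(m, 2, colMeans(m))
  })
  if (ncol(out$step) == 0) stop("population PSTH does not cover the chirp")
  out
}

# Rank-1 sparse PC by truncated power iteration: keep the `card` largest
# absolute loadings each iteration, renormalize, repeat to convergence.
tpower_component <- function(x, card, max_iter = 200, tol = 1e-8) {
  v <- svd(x, nu = 0, nv = 1)$v[, 1]
  truncate <- function(v) {
    keep <- order(abs(v), decreasing = TRUE)[seq_len(min(card, length(v)))]
    w <- numeric(length(v))
    w[keep] <- v[keep]
    n <- sqrt(sum(w^2))
    if (n == 0) w else w / n
  }
  v <- truncate(v)
  for (i in seq_len(max_iter)) {
    v_new <- drop(crossprod(x, x %*% v))
    n <- sqrt(sum(v_new^2))
    if (n == 0) break
    v_new <- truncate(v_new / n)
    if (sum((v_new - v)^2) < tol) {
      v <- v_new
      break
    }
    v <- v_new
  }
  v
}

#' Sparse principal components of the chirp segments
#'
#' Extracts cardinality-constrained principal components (exactly `sparsity`
#' non-zero time bins each) per segment via truncated power iteration with
#' projection deflation, then concatenates across segments. Components
#' explaining less than `min_var` of the total (all-segment) variance are
#' discarded. Scores are the projections of the (centered) segment data onto
#' each component.
#'
#' @param segments Output of [segment_psth_features()].
#' @param sparsity Non-zero time bins per component.
#' @param min_var Minimum fraction of total variance retained per component.
#' @param max_per_segment Cap on components extracted per segment.
#' @return List: `loadings` (components x total bins, zero outside the
#'   component's segment), `scores` (units x components),
#'   `variance_explained` (fraction of total variance), `segment` (segment of
#'   each component).
#' @export
sparse_pca <- function(segments, sparsity = 5, min_var = 0.01,
                       max_per_segment = 25) {
  stopifnot(is.list(segments), nrow(segments[[1]]) >= 2)
  n_units <- nrow(segments[[1]])
  total_var <- sum(vapply(segments, function(m) sum(m^2), numeric(1))) /
    n_units
  if (total_var == 0) stop("degenerate input: zero total variance")
  widths <- vapply(segments, ncol, integer(1))
  offsets <- cumsum(c(0, widths[-length(widths)]))
  names(offsets) <- names(segments)
  loadings <- list()
  scores <- list()
  varex <- numeric(0)
  seg_of <- character(0)
  for (s in names(segments)) {
    x <- segments[[s]]
    x_orig <- x
    for (k in seq_len(min(max_per_segment, nrow(x) - 1, ncol(x)))) {
      if (sum(x^2) < 1e-12) break
      v <- tpower_component(x, sparsity)
      sc <- drop(x_orig %*% v)
      ve <- sum((x %*% v)^2) / n_units / total_var
      if (ve < min_var) break
      full <- numeric(sum(widths))
      full[offsets[[s]] + seq_len(widths[[s]])] <- v
      loadings[[length(loadings) + 1]] <- full
      scores[[length(scores) + 1]] <- sc
      varex <- c(varex, ve)
      seg_of <- c(seg_of, s)
      x <- x - (x %*% v) %*% t(v)   # projection deflation
    }
  }
  if (length(loadings) == 0) {
    stop("no components retained at min_var = ", min_var)
  }
  list(loadings = do.call(rbind, loadings),
       scores = do.call(cbind, scores),
       variance_explained = varex, segment = seg_of)
}

#' Balanced downsampling across conditions
#'
#' Uniform random subsample of each condition to the size of the smallest
#' condition, so community distributions are compared at equal n.
#'
#' @param condition Character/factor vector, one entry per unit.
#' @param seed Integer seed.
#' @return Integer vector of retained unit indices (sorted).
#' @export
downsample_balanced <- function(condition, seed = 1L) {
  tab <- table(condition)
  if (length(tab) < 2) stop("need >= 2 conditions")
  if (any(tab == 0)) stop("empty condition")
  n_min <- min(tab)
  idx <- with_seed(seed, {
    unlist(lapply(names(tab), function(cc) {
      i <- which(condition == cc)
      if (length(i) > n_min) sample(i, n_min) else i
    }))
  })
  sort(idx)
}

# parsimony rule on mclust BIC (higher = better in mclust's convention):
# take the best-BIC k, then prefer the smallest k whose Bayes factor against
# that best model, exp((BIC_best - BIC_k)/2), is below `bf_threshold`.
select_k_bic <- function(bic, bf_threshold = 6) {
  ok <- which(is.finite(bic))
  if (length(ok) == 0) return(1L)
  best <- ok[which.max(bic[ok])]
  for (k in ok) {
    if (k >= best) break
    if (exp((bic[best] - bic[k]) / 2) < bf_threshold) return(k)
  }
  best
}

#' Consensus Gaussian-mixture clustering
#'
#' Repeats GMM clustering `n_repeats` times with random initialization
#' (random-subset hierarchical initialization per repeat). Each repeat fits
#' k = 1..`k_max` components, selects k by lowest BIC with a Bayes-factor
#' parsimony rule (a more complex model is kept only when its Bayes factor,
#' `exp(dBIC/2)`, against the simpler candidate is at least `bf_threshold`),
#' and records the assignment. The consensus similarity is the fraction of
#' repeats co-assigning each unit pair.
#'
#' @param scores Units x features matrix (e.g. sparse-PC scores).
#' @param n_repeats Clustering repeats.
#' @param k_max Maximum number of mixture components.
#' @param seed Integer seed.
#' @param model_names mclust covariance models to consider.
#' @param bf_threshold Bayes-factor threshold for accepting added complexity.
#' @return List: `similarity` (units x units, in \[0,1\], diagonal 1),
#'   `labels` (repeats x units), `k_selected` (per repeat).
#' @export
consensus_cluster <- function(scores, n_repeats = 50, k_max = 20, seed = 1L,
                              model_names = c("EII", "VII", "VVI"),
                              bf_threshold = 6) {
  stopifnot(is.matrix(scores), all(is.finite(scores)), k_max >= 2)
  n <- nrow(scores)
  labels <- matrix(NA_integer_, n_repeats, n)
  k_sel <- integer(n_repeats)
  co <- matrix(0, n, n)
  for (r in seq_len(n_repeats)) {
    sub <- with_seed(seed + r,
                     sample.int(n, min(n, max(50L, ceiling(n / 2)))))
    bic <- suppressWarnings(suppressMessages(
      mclust::mclustBIC(scores, G = 1:k_max, modelNames = model_names,
                        initialization = list(subset = sub),
                        verbose = FALSE)))
    # best BIC per G across the allowed models, then the parsimony rule
    bic_g <- rep(NA_real_, k_max)
    row_best <- apply(bic, 1, function(row) {
      if (all(is.na(row))) NA_real_ else max(row, na.rm = TRUE)
    })
    bic_g[as.integer(rownames(bic))] <- row_best
    g <- select_k_bic(bic_g, bf_threshold)
    model_g <- colnames(bic)[which.max(bic[as.character(g), ])]
    fit <- suppressWarnings(suppressMessages(
      mclust::Mclust(scores, G = g, modelNames = model_g,
                     initialization = list(subset = sub), verbose = FALSE)))
    if (is.null(fit)) stop("mixture fitting failed on repeat ", r)
    cl <- fit$classification
    labels[r, ] <- cl
    k_sel[r] <- length(unique(cl))
    co <- co + outer(cl, cl, "==")
  }
  sim <- co / n_repeats
  diag(sim) <- 1
  list(similarity = sim, labels = labels, k_selected = k_sel)
}

#' Community detection on a consensus similarity matrix
#'
#' Weighted-modularity (Louvain) community detection on the similarity graph,
#' taking the best-modularity partition over `n_restarts` seeded runs.
#' Communities with fewer than `min_size` members are dropped and their units
#' marked unassigned (`NA`). Communities are renumbered by decreasing size.
#'
#' @param similarity Symmetric units x units matrix in \[0, 1\].
#' @param min_size Minimum retained community size.
#' @param seed Integer seed.
#' @param n_restarts Louvain restarts.
#' @return Integer vector of community ids (NA = unassigned).
#' @export
detect_communities <- function(similarity, min_size = 5, seed = 1L,
                               n_restarts = 20) {
  stopifnot(is.matrix(similarity), nrow(similarity) == ncol(similarity))
  if (max(abs(similarity - t(similarity))) > 1e-8) {
    stop("similarity must be symmetric")
  }
  n <- nrow(similarity)
  if (all(similarity[upper.tri(similarity)] == 0)) {
    warning("all-zero similarity; returning a single community")
    return(rep(1L, n))
  }
  g <- igraph::graph_from_adjacency_matrix(similarity, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  best <- NULL
  best_q <- -Inf
  for (r in seq_len(n_restarts)) {
    cl <- with_seed(seed + r, igraph::cluster_louvain(g))
    q <- igraph::modularity(g, igraph::membership(cl),
                            weights = igraph::E(g)$weight)
    if (q > best_q) {
      best_q <- q
      best <- as.integer(igraph::membership(cl))
    }
  }
  tab <- table(best)
  keep <- as.integer(names(tab)[tab >= min_size])
  out <- ifelse(best %in% keep, best, NA_integer_)
  # renumber by decreasing size
  kept_tab <- sort(table(out), decreasing = TRUE)
  map <- stats::setNames(seq_along(kept_tab), names(kept_tab))
  ifelse(is.na(out), NA_integer_, as.integer(map[as.character(out)]))
}

#' Shuffle test on community distributions between conditions
#'
#' For each pair of conditions, compares the distribution of (assigned) units
#' across communities using total variation distance
#' `0.5 * sum |p1 - p2|`, against a null built by permuting condition labels
#' across units; `p = (1 + #{null >= observed}) / (n_shuffles + 1)`.
#' Unassigned units (NA community) are excluded.
#'
#' @param communities Integer community ids (NA allowed).
#' @param condition Condition label per unit.
#' @param n_shuffles Number of label permutations.
#' @param seed Integer seed.
#' @return Data frame: `condition_a`, `condition_b`, `statistic`, `p_value`,
#'   `n_a`, `n_b`.
#' @export
distribution_shuffle_test <- function(communities, condition,
                                      n_shuffles = 999, seed = 1L) {
  stopifnot(length(communities) == length(condition))
  keep <- !is.na(communities)
  comm <- communities[keep]
  cond <- as.character(condition[keep])
  conds <- unique(cond)
  if (length(conds) < 2) stop("need >= 2 conditions with assigned units")
  if (any(table(cond) == 0)) stop("condition with zero assigned units")
  tv <- function(c1, c2, comm_levels) {
    p1 <- tabulate(c1, nbins = comm_levels) / length(c1)
    p2 <- tabulate(c2, nbins = comm_levels) / length(c2)
    0.5 * sum(abs(p1 - p2))
  }
  levels_n <- max(comm)
  pairs <- utils::combn(conds, 2)
  out <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]
    b <- pairs[2, j]
    ia <- cond == a
    ib <- cond == b
    x <- comm[ia | ib]
    lab <- cond[ia | ib]
    obs <- tv(x[lab == a], x[lab == b], levels_n)
    null <- with_seed(seed + j, {
      vapply(seq_len(n_shuffles), function(s) {
        perm <- sample(lab)
        tv(x[perm == a], x[perm == b], levels_n)
      }, numeric(1))
    })
    data.frame(condition_a = a, condition_b = b, statistic = obs,
               p_value = (1 + sum(null >= obs - 1e-12)) / (n_shuffles + 1),
               n_a = sum(ia), n_b = sum(ib))
  })
  do.call(rbind, out)
}
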