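fake_pop <- function(n_units, rate_fns, bin_s = 0.05) {
  # units x 600 matrix from deterministic rate functions (recycled)
  t0 <- (seq_len(600) - 1) * bin_s
  m <- t(vapply(seq_len(n_units), function(i) {
    rate_fns[[(i - 1) %% length(rate_fns) + 1]](t0)
  }, numeric(600)))
  rownames(m) <- sprintf("u%03d", seq_len(n_units))
  m
}

on_fn <- function(t0) ifelse(t0 >= 0 & t0 < 3, 30, 2)
off_fn <- function(t0) ifelse(t0 >= 3 & t0 < 4, 30, 2)

test_that("segment windows have the canonical widths and preserve unit order", {
  m <- fake_pop(6, list(on_fn, off_fn))
  segs <- segment_psth_features(m)
  expect_equal(vapply(segs, ncol, integer(1)),
               c(step = 80, temporal_chirp = 180, contrast_chirp = 140))
  expect_true(all(vapply(segs, nrow, integer(1)) == 6))
  # centering: column means vanish
  expect_lt(max(abs(colMeans(segs$step))), 1e-12)
  # constant-rate population is all zero after normalization + centering
  const <- fake_pop(4, list(function(t0) rep(7, 600)))
  expect_lt(max(abs(unlist(segment_psth_features(const)))), 1e-12)
})

test_that("sparse components have exactly 5 non-zero bins and separate archetypes", {
  set.seed(1)
  m <- fake_pop(40, list(on_fn, off_fn))
  m <- m + matrix(rnorm(length(m), 0, 0.1), nrow(m))
  segs <- segment_psth_features(m)
  sp <- sparse_pca(segs)
  expect_true(all(rowSums(sp$loadings != 0) == 5))
  expect_true(all(sp$variance_explained >= 0.01))
  # first step-segment component separates ON from OFF archetypes
  k <- which(sp$segment == "step")[1]
  sc <- sp$scores[, k]
  grp <- rep(c(1, 2), 20)
  expect_true(min(abs(outer(sc[grp == 1], sc[grp == 2], "-"))) >
              max(dist(sc[grp == 1])) / 2)
  # duplicated units land on identical scores
  m2 <- rbind(m, m[1, , drop = FALSE])
  sp2 <- sparse_pca(segment_psth_features(m2))
  expect_equal(sp2$scores[41, ], sp2$scores[1, ], tolerance = 1e-8)
  expect_error(sparse_pca(segs, min_var = 1.0), "retained")
})

test_that("balanced downsampling equalizes condition sizes deterministically", {
  cond <- rep(c("a", "b", "c"), c(9, 7, 12))
  idx <- downsample_balanced(cond, seed = 3)
  expect_equal(as.integer(table(cond[idx])), rep(7L, 3))
  expect_identical(idx, downsample_balanced(cond, seed = 3))
  eq <- rep(c("a", "b"), each = 5)
  expect_identical(downsample_balanced(eq, seed = 1), 1:10)
  expect_error(downsample_balanced(rep("a", 5), seed = 1), "conditions")
})

test_that("consensus clustering is deterministic and finds one blob as k = 1", {
  set.seed(2)
  x <- matrix(rnorm(80 * 3), 80)
  c1 <- consensus_cluster(x, n_repeats = 5, k_max = 4, seed = 9)
  c2 <- consensus_cluster(x, n_repeats = 5, k_max = 4, seed = 9)
  expect_identical(c1$similarity, c2$similarity)
  expect_true(all(c1$k_selected == 1))
  expect_true(all(c1$similarity == 1))
})

test_that("similarity entries are exact co-assignment fractions", {
  set.seed(4)
  x <- rbind(matrix(rnorm(60 * 3, 0), 60), matrix(rnorm(60 * 3, 3), 60))
  cc <- consensus_cluster(x, n_repeats = 8, k_max = 5, seed = 1)
  n <- nrow(x)
  recount <- matrix(0, n, n)
  for (r in seq_len(nrow(cc$labels))) {
    recount <- recount + outer(cc$labels[r, ], cc$labels[r, ], "==")
  }
  recount <- recount / nrow(cc$labels)
  diag(recount) <- 1
  expect_equal(cc$similarity, recount, tolerance = 1e-12)
})

test_that("community detection respects block structure and the size floor", {
  blocks <- c(8, 6, 5)
  sim <- matrix(0.05, sum(blocks), sum(blocks))
  start <- cumsum(c(0, blocks))
  for (b in seq_along(blocks)) {
    i <- (start[b] + 1):start[b + 1]
    sim[i, i] <- 0.95
  }
  diag(sim) <- 1
  comm <- detect_communities(sim, min_size = 5, seed = 1)
  expect_equal(length(unique(comm)), 3)
  expect_true(all(table(comm) == sort(blocks, decreasing = TRUE)))
  # a 4-member block falls below the floor and is unassigned
  blocks2 <- c(8, 6, 4)
  sim2 <- matrix(0.05, 18, 18)
  start2 <- cumsum(c(0, blocks2))
  for (b in seq_along(blocks2)) {
    i <- (start2[b] + 1):start2[b + 1]
    sim2[i, i] <- 0.95
  }
  diag(sim2) <- 1
  comm2 <- detect_communities(sim2, min_size = 5, seed = 1)
  expect_true(all(is.na(comm2[15:18])))
  expect_equal(sum(is.na(comm2)), 4)
  expect_warning(detect_communities(matrix(0, 6, 6), seed = 1), "all-zero")
})

test_that("noisy planted two-block similarity is recovered almost exactly", {
  set.seed(6)
  n <- 40
  truth <- rep(1:2, each = n / 2)
  sim <- matrix(0.1, n, n)
  sim[truth == 1, truth == 1] <- 0.9
  sim[truth == 2, truth == 2] <- 0.9
  sim <- sim + matrix(runif(n * n, -0.05, 0.05), n)
  sim <- (sim + t(sim)) / 2
  diag(sim) <- 1
  comm <- detect_communities(sim, min_size = 5, seed = 2)
  expect_gt(mclust::adjustedRandIndex(comm, truth), 0.95)
})

test_that("distribution shuffle test: extremes and error handling", {
  # one condition in a single community vs a uniform one -> minimal p
  comm <- c(rep(1, 50), rep(1:5, 10))
  cond <- rep(c("conc", "unif"), each = 50)
  res <- distribution_shuffle_test(comm, cond, n_shuffles = 199, seed = 1)
  expect_equal(res$p_value, 1 / 200)
  expect_equal(res$statistic, 0.8)
  expect_error(distribution_shuffle_test(rep(1, 10), rep("a", 10), 99, 1),
               "conditions")
  # unassigned units are excluded
  comm2 <- c(NA, comm)
  cond2 <- c("conc", cond)
  res2 <- distribution_shuffle_test(comm2, cond2, n_shuffles = 199, seed = 1)
  expect_equal(res2$n_a, 50)
})
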