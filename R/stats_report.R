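#' Between-group comparison
#'
#' Two-sided comparison of two unit groups: Mann-Whitney U (rank-sum;
#' medians reported) or two-sample Kolmogorov-Smirnov (D reported). Exact
#' versus asymptotic computation follows the default small-sample switching
#' of the underlying tests.
#'
#' @param a,b Numeric vectors (each n >= 3).
#' @param test `"mann_whitney_u"` or `"ks"`.
#' @return A `comparison_result`: `test`, `statistic`, `p_value`,
#'   `n_per_group`, `medians`.
#' @export
compare_groups <- function(a, b, test = c("mann_whitney_u", "ks")) {
  test <- match.arg(test)
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  if (length(a) < 3 || length(b) < 3) stop("each group needs n >= 3")
  res <- if (test == "mann_whitney_u") {
    suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
  } else {
    suppressWarnings(stats::ks.test(a, b, alternative = "two.sided"))
  }
  structure(list(test = test, statistic = unname(res$statistic),
                 p_value = res$p.value,
                 n_per_group = c(length(a), length(b)),
                 medians = c(stats::median(a), stats::median(b))),
            class = "comparison_result")
}

#' Within-unit paired correlation across conditions
#'
#' Pearson correlation between per-unit values measured in two conditions
#' (same units, paired order), as used to ask whether a response property is
#' preserved within units across photoreceptor-driven and optogenetically
#' driven conditions.
#'
#' @param x,y Paired per-unit values (n >= 10).
#' @return A `comparison_result` with `r` in place of medians; `r` is `NA`
#'   (flagged) if either vector has zero variance.
#' @export
paired_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 10) stop("need >= 10 paired values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(structure(list(test = "pearson", statistic = NA_real_,
                          p_value = NA_real_, n_per_group = length(x),
                          r = NA_real_, flagged = TRUE),
                     class = "comparison_result"))
  }
  res <- stats::cor.test(x, y, method = "pearson")
  structure(list(test = "pearson", statistic = unname(res$statistic),
                 p_value = res$p.value, n_per_group = length(x),
                 r = unname(res$estimate), flagged = FALSE),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %s)\n", x$test,
              x$statistic, x$p_value, paste(x$n_per_group, collapse = "/")))
  invisible(x)
}

#' Summary report across conditions
#'
#' Collates per-unit metrics and tuning fits into per-condition median
#' tables, inclusion counts at each filter, and pairwise Mann-Whitney
#' comparisons of every numeric metric. Output ordering and formatting are
#' deterministic.
#'
#' @param units Per-unit data frame from [analyze_units()] (must contain a
#'   `condition` column).
#' @param comparisons Character vector of metric columns to compare between
#'   conditions.
#' @return List of data frames: `medians`, `counts`, `comparisons`.
#' @export
make_report <- function(units,
                        comparisons = c("qi", "amplitude", "latency_s",
                                        "bias", "transience", "c50",
                                        "peak_tf", "mean_rate")) {
  need <- c("condition", "is_lr")
  miss <- setdiff(need, names(units))
  if (length(miss) > 0) stop("missing columns: ", paste(miss, collapse = ", "))
  comparisons <- intersect(comparisons, names(units))
  conds <- sort(unique(units$condition))
  lr <- units[units$is_lr %in% TRUE, , drop = FALSE]
  med_tab <- do.call(rbind, lapply(conds, function(cc) {
    d <- lr[lr$condition == cc, , drop = FALSE]
    row <- data.frame(condition = cc, n_lr = nrow(d))
    for (m in comparisons) {
      row[[paste0("median_", m)]] <-
        if (nrow(d) > 0) stats::median(d[[m]], na.rm = TRUE) else NA_real_
    }
    row
  }))
  counts <- do.call(rbind, lapply(conds, function(cc) {
    d <- units[units$condition == cc, , drop = FALSE]
    data.frame(condition = cc, n_total = nrow(d),
               n_pass_exclusion = sum(d$keep %in% TRUE),
               n_lr = sum(d$is_lr %in% TRUE),
               n_nr_included = sum(d$nr_included %in% TRUE),
               n_hg_included = sum(d$hg_included %in% TRUE))
  }))
  comp <- NULL
  if (length(conds) >= 2 && nrow(lr) > 0) {
    prs <- utils::combn(conds, 2)
    comp <- do.call(rbind, lapply(seq_len(ncol(prs)), function(j) {
      a_c <- prs[1, j]
      b_c <- prs[2, j]
      do.call(rbind, lapply(comparisons, function(m) {
        a <- lr[[m]][lr$condition == a_c]
        b <- lr[[m]][lr$condition == b_c]
        a <- a[is.finite(a)]
        b <- b[is.finite(b)]
        if (length(a) < 3 || length(b) < 3) return(NULL)
        r <- compare_groups(a, b, "mann_whitney_u")
        data.frame(metric = m, condition_a = a_c, condition_b = b_c,
                   test = r$test, statistic = r$statistic,
                   p_value = r$p_value, median_a = r$medians[1],
                   median_b = r$medians[2])
      }))
    }))
  }
  if (nrow(lr) == 0) {
    message("no light-responsive units to report")
  }
  list(medians = med_tab, counts = counts, comparisons = comp,
       n_tests = if (is.null(comp)) 0L else nrow(comp))
}

#' Write a report to CSV/JSON
#' @param report Output of [make_report()].
#' @param dir Output directory (created if needed).
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(report$medians, file.path(dir, "medians.csv"),
                   row.names = FALSE)
  utils::write.csv(report$counts, file.path(dir, "counts.csv"),
                   row.names = FALSE)
  if (!is.null(report$comparisons)) {
    utils::write.csv(report$comparisons, file.path(dir, "comparisons.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       dataframe = "rows", digits = NA, pretty = TRUE)
  invisible(dir)
}
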