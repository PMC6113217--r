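#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum distance between the two empirical CDFs; the p-value
#' comes from the asymptotic two-sided KS distribution by default, which
#' is appropriate at the sample sizes this pipeline compares (hundreds of
#' seed genes against thousands of background genes). Ties are handled by
#' evaluating the ECDFs directly, with no further correction.
#'
#' @param x,y Non-empty numeric samples.
#' @param exact Use the exact small-sample p-value instead (passed to
#'   [stats::ks.test()]).
#' @return List with `d` and `p`.
#' @export
ks_two_sample <- function(x, y, exact = FALSE) {
  if (length(x) == 0 || length(y) == 0) stop("samples must be non-empty")
  res <- suppressWarnings(stats::ks.test(x, y, exact = exact))
  list(d = unname(res$statistic), p = unname(res$p.value))
}

#' KS comparison of every feature between seed and background genes
#'
#' For each feature column of the table, compares its distribution in the
#' positive (seed) rows against the unlabeled rows and reports the KS
#' statistic, p-value, group sizes and group means -- the screen used to
#' establish that seed genes sit at the network center and share
#' annotations.
#'
#' @param features A feature table from [assemble_features()] or
#'   [topology_table()]; must contain a `label` column with both classes.
#' @param columns Feature columns to test (default: all numeric columns
#'   except `degree2`, matching the classifier's feature set; pass
#'   explicitly to override).
#' @param exact Passed to [ks_two_sample()].
#' @return data.frame with one row per feature: `feature`, `d_stat`,
#'   `p_value`, `n_pos`, `n_neg`, `mean_pos`, `mean_neg`.
#' @export
compare_groups <- function(features, columns = NULL, exact = FALSE) {
  stopifnot("label" %in% names(features))
  pos <- features$label == "positive"
  if (!any(pos) || all(pos)) {
    stop("need at least one positive and one unlabeled row")
  }
  if (is.null(columns)) {
    num <- vapply(features, is.numeric, logical(1))
    columns <- setdiff(names(features)[num], "degree2")
  }
  rows <- lapply(columns, function(cn) {
    x <- features[[cn]][pos]
    y <- features[[cn]][!pos]
    ks <- ks_two_sample(x, y, exact = exact)
    data.frame(feature = cn, d_stat = ks$d, p_value = ks$p,
               n_pos = sum(pos), n_neg = sum(!pos),
               mean_pos = mean(x), mean_neg = mean(y),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cumulative frequency curve of a sample
#'
#' The empirical CDF evaluated either at the sample's own points or on an
#' even grid spanning its range -- the curves used to visualize how seed
#' genes' feature distributions shift right of the background.
#'
#' @param values Non-empty numeric sample.
#' @param grid Number of evenly spaced thresholds; `NULL` (default)
#'   evaluates at the sorted unique sample values.
#' @return data.frame with `threshold` and `cum_freq` (fraction of values
#'   `<=` threshold), non-decreasing and ending at 1.
#' @export
cumulative_frequency <- function(values, grid = NULL) {
  if (length(values) == 0) stop("sample must be non-empty")
  thr <- if (is.null(grid)) {
    sort(unique(values))
  } else {
    seq(min(values), max(values), length.out = grid)
  }
  f <- stats::ecdf(values)
  data.frame(threshold = thr, cum_freq = f(thr))
}
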