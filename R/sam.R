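#' Two-class permutation Wilcoxon differential abundance (SAM-style)
#'
#' Per feature, the standardized Wilcoxon rank-sum statistic comparing
#' the two classes; the null distribution comes from label permutations
#' (all distinct assignments when fewer than `n_perms` exist, otherwise
#' `n_perms` random draws from the given seed). q-values use the plug-in
#' FDR estimator: at the threshold set by each feature's |statistic|,
#' q = (expected number of null exceedances across permutations) /
#' (number of observed exceedances), capped at 1 and monotonized so q
#' never decreases as the threshold loosens. The null counts are averaged
#' across permutations by default; `null_summary = "median"` gives the
#' median-count variant, which is anti-conservative at extreme
#' thresholds in small discrete designs (the median collapses to zero
#' where the mean is ~1), so the mean is the default.
#'
#' @param matrix abundance [matrix_table()] (RPM scale for the fold
#'   changes to be meaningful), features x samples.
#' @param labels two-class sample labels (vector or factor, length
#'   `ncol(matrix)`).
#' @param n_perms permutation budget (default 1000).
#' @param seed RNG seed for sampling permutations.
#' @param pseudo_count added to cluster means for fold changes
#'   (default 0.5).
#' @param null_summary how null exceedance counts are pooled across
#'   permutations: `"mean"` (default) or `"median"`.
#' @return a `sam_result` data.frame: feature_id, mean_rpm_c1,
#'   mean_rpm_c2, fold_change (signed: ratios below 1 reported as the
#'   negative reciprocal), statistic, q_value; attribute `"classes"`
#'   records the class order, `"n_perms"` the permutations used.
#' @export
sam_wilcoxon <- function(matrix, labels, n_perms = 1000L, seed = 1L,
                         pseudo_count = 0.5,
                         null_summary = c("mean", "median")) {
  null_summary <- match.arg(null_summary)
  m <- unclass(matrix)
  cls <- factor(labels)
  if (nlevels(cls) != 2) fs_stopf("labels must have exactly two classes")
  n1 <- sum(cls == levels(cls)[1]); n2 <- sum(cls == levels(cls)[2])
  if (min(n1, n2) < 2) fs_stopf("each class needs >=2 samples")
  ns <- ncol(m)
  ranks <- t(apply(m, 1, rank))
  mu <- n2 * (ns + 1) / 2
  sigma <- sqrt(n1 * n2 * (ns + 1) / 12)
  stat <- (ranks %*% (cls == levels(cls)[2]) - mu) / sigma
  stat <- drop(stat)

  n_distinct <- choose(ns, n2)
  if (n_distinct <= n_perms) {
    sel <- utils::combn(ns, n2)
    z <- matrix(0, ns, ncol(sel))
    z[cbind(as.vector(sel), rep(seq_len(ncol(sel)), each = n2))] <- 1
  } else {
    set.seed(seed)
    z <- vapply(seq_len(n_perms), function(p) {
      zz <- numeric(ns)
      zz[sample.int(ns, n2)] <- 1
      zz
    }, numeric(ns))
  }
  perm_stat <- abs((ranks %*% z - mu) / sigma)

  a <- abs(stat)
  ord <- order(-a, rownames(m))
  cuts <- a[ord]
  # observed and median-null exceedance counts at each feature's threshold;
  # per-column sorted search keeps this O(P * F log F). The 1e-9 guard is
  # far below the statistic's granularity (1/sigma), so >= ties are exact.
  sorted_a <- sort(a)
  obs_exceed <- length(a) - findInterval(cuts - 1e-9, sorted_a)
  null_counts <- apply(perm_stat, 2, function(col) {
    s <- sort(col)
    length(s) - findInterval(cuts - 1e-9, s)
  })
  if (!is.matrix(null_counts))
    null_counts <- matrix(null_counts, nrow = length(cuts))
  null_exceed <- if (null_summary == "mean") rowMeans(null_counts)
  else apply(null_counts, 1, stats::median)
  q_sorted <- pmin(1, null_exceed / obs_exceed)
  # monotone: each feature gets the best FDR over thresholds including it
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(length(a))
  q[ord] <- q_sorted

  lev <- levels(cls)
  m1 <- rowMeans(m[, cls == lev[1], drop = FALSE])
  m2 <- rowMeans(m[, cls == lev[2], drop = FALSE])
  ratio <- (m2 + pseudo_count) / (m1 + pseudo_count)
  fc <- ifelse(ratio >= 1, ratio, -1 / ratio)
  out <- data.frame(feature_id = rownames(m), mean_rpm_c1 = m1,
                    mean_rpm_c2 = m2, fold_change = fc,
                    statistic = stat, q_value = q,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "classes") <- lev
  attr(out, "n_perms") <- ncol(z)
  class(out) <- c("sam_result", "data.frame")
  out
}

#' @export
print.sam_result <- function(x, ...) {
  cat(sprintf("<sam_result: %d features, %d at q<0.05 (classes %s vs %s, %d perms)>\n",
              nrow(x), sum(x$q_value < 0.05),
              attr(x, "classes")[1], attr(x, "classes")[2],
              attr(x, "n_perms")))
  invisible(x)
}

#' Filter differential features by FDR, fold change, and abundance
#'
#' A feature passes when its q-value is below `fdr`, its absolute fold
#' change reaches `min_abs_fc`, and its mean RPM reaches `min_rpm` in at
#' least one of the two clusters. Also returns the largest
#' `top_n_per_direction` positive and negative fold changes among
#' passers.
#'
#' @param features a `sam_result` (or compatible data.frame).
#' @param fdr q-value ceiling (default 0.05).
#' @param min_abs_fc fold-change floor (default 1.5).
#' @param min_rpm cluster-mean RPM floor (default 25).
#' @param top_n_per_direction size of the two top lists (default 25).
#' @return list: `all` (input with `passes_filters` column), `passing`,
#'   `top_positive`, `top_negative`.
#' @export
filter_differential <- function(features, fdr = 0.05, min_abs_fc = 1.5,
                                min_rpm = 25, top_n_per_direction = 25L) {
  f <- as.data.frame(features)
  f$passes_filters <- f$q_value < fdr &
    abs(f$fold_change) >= min_abs_fc &
    pmax(f$mean_rpm_c1, f$mean_rpm_c2) >= min_rpm
  pass <- f[f$passes_filters, , drop = FALSE]
  up <- pass[pass$fold_change > 0, , drop = FALSE]
  dn <- pass[pass$fold_change < 0, , drop = FALSE]
  up <- up[order(-up$fold_change, up$feature_id), , drop = FALSE]
  dn <- dn[order(dn$fold_change, dn$feature_id), , drop = FALSE]
  list(all = f, passing = pass,
       top_positive = utils::head(up, top_n_per_direction),
       top_negative = utils::head(dn, top_n_per_direction))
}
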