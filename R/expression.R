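#' Upper-quartile normalization
#'
#' Divides each sample column by its 75th percentile computed over the
#' sample's nonzero values, then rescales by the median of those
#' per-sample upper quartiles so magnitudes stay comparable across the
#' cohort. After the operation every sample has the same nonzero upper
#' quartile.
#'
#' @param matrix a count [matrix_table()].
#' @return a `uq_normalized` [matrix_table()].
#' @export
upper_quartile_normalize <- function(matrix) {
  uq <- apply(matrix, 2, function(col) {
    nz <- col[col > 0]
    if (!length(nz)) NA_real_ else stats::quantile(nz, 0.75, names = FALSE)
  })
  if (anyNA(uq))
    fs_stopf("all-zero sample(s): %s",
             paste(colnames(matrix)[is.na(uq)], collapse = ", "))
  scaled <- sweep(unclass(matrix), 2, uq, "/") * stats::median(uq)
  matrix_table(scaled, "uq_normalized")
}

#' Reads-per-million normalization
#'
#' Scales each sample column to sum to one million.
#'
#' @param counts a count [matrix_table()].
#' @return an `rpm` [matrix_table()].
#' @export
rpm_normalize <- function(counts) {
  tot <- colSums(counts)
  if (any(tot == 0))
    fs_stopf("all-zero sample(s): %s",
             paste(colnames(counts)[tot == 0], collapse = ", "))
  matrix_table(sweep(unclass(counts), 2, tot, "/") * 1e6, "rpm")
}

#' Keep microRNAs expressed above an RPM floor in enough libraries
#'
#' A mature strand survives when its RPM reaches `min_mean_rpm` in at
#' least `min_libraries` samples.
#'
#' @param matrix an rpm [matrix_table()].
#' @param min_mean_rpm RPM floor (default 1).
#' @param min_libraries library count floor (default 10).
#' @return filtered [matrix_table()].
#' @export
filter_expressed_mirs <- function(matrix, min_mean_rpm = 1,
                                  min_libraries = 10L) {
  keep <- rowSums(unclass(matrix) >= min_mean_rpm) >= min_libraries
  if (!any(keep)) fs_stopf("no features pass the expression filter")
  matrix_table(unclass(matrix)[keep, , drop = FALSE], value_kind(matrix))
}

#' Select the most variable features
#'
#' Ranks features by variance across samples and returns the top
#' `fraction` (or top `n`); ties break by feature id.
#'
#' @param matrix a [matrix_table()].
#' @param fraction fraction of features to keep (default 0.25).
#' @param n absolute count overriding `fraction`.
#' @return character vector of feature ids.
#' @export
select_variable_features <- function(matrix, fraction = 0.25, n = NULL) {
  v <- apply(unclass(matrix), 1, stats::var)
  k <- if (!is.null(n)) as.integer(n) else max(1L, round(fraction * nrow(matrix)))
  if (k > nrow(matrix)) fs_stopf("requested %d of %d features", k, nrow(matrix))
  ord <- order(-v, rownames(matrix))
  rownames(matrix)[ord[seq_len(k)]]
}

#' Nearest-centroid subtype assignment
#'
#' Assigns each sample to the nearest of two (or more) labeled centroid
#' vectors, by Spearman dissimilarity (1 - rank correlation) or Euclidean
#' distance. Centroids are user-supplied (e.g. published active/inactive
#' or tumor-likeness centroids) or derived from a cohort's own consensus
#' clusters via [derive_centroids()]. Exact ties go to the
#' lexicographically first label and are flagged.
#'
#' @param sample_profile named numeric vector for one sample.
#' @param centroids numeric matrix, features x labeled subtypes.
#' @param distance `"spearman"` or `"euclidean"`.
#' @return a `subtype_call`: list with `subtype`, named `distances`,
#'   `tied`.
#' @export
assign_subtype <- function(sample_profile,
                           centroids, distance = c("spearman", "euclidean")) {
  distance <- match.arg(distance)
  feats <- intersect(rownames(centroids), names(sample_profile))
  if (length(feats) < 0.5 * nrow(centroids))
    fs_stopf("only %d/%d centroid features present in sample",
             length(feats), nrow(centroids))
  x <- sample_profile[feats]
  d <- vapply(colnames(centroids), function(lab) {
    cvec <- centroids[feats, lab]
    if (distance == "spearman")
      1 - stats::cor(x, cvec, method = "spearman")
    else sqrt(sum((x - cvec)^2))
  }, numeric(1))
  labs <- sort(colnames(centroids))
  d <- d[labs]
  best <- labs[which.min(d)]
  tied <- sum(abs(d - min(d)) < 1e-12) > 1
  out <- list(subtype = best, distances = d, tied = tied)
  class(out) <- "subtype_call"
  out
}

#' @export
print.subtype_call <- function(x, ...) {
  cat(sprintf("<subtype_call: %s%s (distances: %s)>\n", x$subtype,
              if (x$tied) " [tie]" else "",
              paste(sprintf("%s=%.3f", names(x$distances), x$distances),
                    collapse = ", ")))
  invisible(x)
}

#' Derive per-cluster mean centroids from a labeling
#'
#' @param matrix a [matrix_table()].
#' @param labels named (or column-ordered) cluster labels.
#' @return features x labels centroid matrix.
#' @export
derive_centroids <- function(matrix, labels) {
  labels <- as.character(labels)
  stopifnot(length(labels) == ncol(matrix))
  vapply(sort(unique(labels)), function(lab)
    rowMeans(unclass(matrix)[, labels == lab, drop = FALSE]),
    numeric(nrow(matrix)))
}

#' Concordance between two 2-cluster labelings
#'
#' Fraction of samples agreeing, maximized over the label permutation
#' (cluster names are arbitrary), so identical and fully swapped
#' labelings both score 1.
#'
#' @param labels_a,labels_b equal-length label vectors (two clusters).
#' @return fraction in \[0, 1\].
#' @export
cluster_concordance <- function(labels_a, labels_b) {
  stopifnot(length(labels_a) == length(labels_b))
  a <- as.integer(factor(labels_a)); b <- as.integer(factor(labels_b))
  if (max(a) > 2 || max(b) > 2)
    fs_stopf("cluster_concordance is defined for two-cluster labelings")
  max(mean(a == b), mean(a != b))
}

#' Row-scaled log abundance for heatmap export
#'
#' log10(RPM + 1), then each row standardized to mean 0, sd 1 (constant
#' rows to 0).
#'
#' @param matrix an rpm [matrix_table()].
#' @return plain numeric matrix.
#' @export
heatmap_scale <- function(matrix) {
  lg <- log10(unclass(matrix) + 1)
  t(apply(lg, 1, function(r) {
    s <- stats::sd(r)
    if (s == 0) rep(0, length(r)) else (r - mean(r)) / s
  }))
}
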