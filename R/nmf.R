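#' Non-negative matrix factorization (Brunet KL variant)
#'
#' Multiplicative-update NMF minimizing the generalized Kullback-Leibler
#' divergence D(V || WH), the update rules of the Brunet algorithm.
#' Factors are initialized uniformly at random from the given seed;
#' iteration stops when the relative change of the objective falls below
#' `tol` (checked every 10 iterations) or at `max_iter`. Columns of `W`
#' are scaled to sum 1 (scale absorbed into `H`), and a sample's cluster
#' label is the argmax over the rows of `H`.
#'
#' @param matrix non-negative numeric matrix (features x samples).
#' @param k factorization rank (>= 1).
#' @param seed RNG seed for the initialization.
#' @param max_iter iteration cap (default 2000).
#' @param tol relative-objective convergence tolerance (default 1e-6).
#' @return list with `W` (features x k), `H` (k x samples), `labels`
#'   (per-sample argmax cluster), `objective` (KL divergence trace,
#'   one value per check), `iterations`.
#' @export
nmf_factorize <- function(matrix, k, seed = 1L, max_iter = 2000L,
                          tol = 1e-6) {
  v <- unclass(matrix)
  if (any(v < 0)) fs_stopf("NMF requires a non-negative matrix")
  if (k < 1 || k > min(dim(v)))
    fs_stopf("rank k=%d outside 1..min(dim) = %d", k, min(dim(v)))
  nf <- nrow(v); ns <- ncol(v)
  set.seed(seed)
  w <- matrix(stats::runif(nf * k, 0.1, 1), nf, k)
  h <- matrix(stats::runif(k * ns, 0.1, 1), k, ns)
  eps <- .Machine$double.eps
  kl <- function(wh) sum(ifelse(v > 0, v * log(v / (wh + eps)), 0) - v + wh)
  obj <- kl(w %*% h)
  trace <- obj
  it <- 0L
  while (it < max_iter) {
    for (step in seq_len(10L)) {
      it <- it + 1L
      wh <- w %*% h + eps
      h <- h * (t(w) %*% (v / wh)) / (colSums(w) + eps)
      wh <- w %*% h + eps
      w <- w * ((v / wh) %*% t(h)) / matrix(rowSums(h), nf, k, byrow = TRUE)
      if (it >= max_iter) break
    }
    new_obj <- kl(w %*% h)
    trace <- c(trace, new_obj)
    if (abs(obj - new_obj) <= tol * max(abs(obj), eps)) {
      obj <- new_obj
      break
    }
    obj <- new_obj
  }
  scale <- colSums(w) + eps
  w <- sweep(w, 2, scale, "/")
  h <- sweep(h, 1, scale, "*")
  labels <- apply(h, 2, which.max)
  names(labels) <- colnames(v)
  list(W = w, H = h, labels = labels, objective = trace, iterations = it)
}

#' NMF consensus clustering with rank survey
#'
#' For each rank `k`, repeats [nmf_factorize()] from independent
#' sub-seeds and records, for every sample pair, the fraction of runs in
#' which the pair lands in the same NMF cluster (the consensus matrix).
#' Final assignments cut an average-linkage hierarchical tree of
#' `1 - consensus` into `k` groups; silhouette widths are computed from
#' the consensus matrix. The survey rank range uses `runs_survey` runs
#' per k; the chosen rank(s) in `k_final` are re-run with `runs_final`
#' runs.
#'
#' @param matrix non-negative feature x sample matrix.
#' @param k_range ranks surveyed (default 2:15, ranks beyond the sample
#'   count are skipped with a warning).
#' @param k_final rank(s) given the full run count (default 2).
#' @param runs_survey,runs_final NMF restarts per rank (defaults 30 and
#'   500).
#' @param seed master seed; each restart uses a derived sub-seed.
#' @param max_iter,tol passed to [nmf_factorize()].
#' @return named list of `consensus_result`s (one per rank): `k`,
#'   `assignments`, `consensus_matrix`, `silhouette_widths`, `n_runs`,
#'   plus a `rank_survey` data.frame attribute summarizing mean
#'   silhouette and consensus dispersion per rank.
#' @export
consensus_cluster <- function(matrix, k_range = 2:15, k_final = 2L,
                              runs_survey = 30L, runs_final = 500L,
                              seed = 1L, max_iter = 2000L, tol = 1e-6) {
  v <- unclass(matrix)
  ns <- ncol(v)
  results <- list()
  survey <- list()
  ks <- sort(unique(c(k_range, k_final)))
  for (k in ks) {
    if (k > ns) {
      fs_warnf("skipping k=%d: only %d samples", k, ns)
      next
    }
    n_runs <- if (k %in% k_final) runs_final else runs_survey
    co <- matrix(0, ns, ns)
    for (r in seq_len(n_runs)) {
      fit <- nmf_factorize(v, k, seed = patient_seed(seed, k * 100000L + r),
                           max_iter = max_iter, tol = tol)
      co <- co + outer(fit$labels, fit$labels, "==")
    }
    consensus <- co / n_runs
    dimnames(consensus) <- list(colnames(v), colnames(v))
    hc <- stats::hclust(stats::as.dist(1 - consensus), method = "average")
    assignments <- stats::cutree(hc, k = k)
    sil <- silhouette_from_consensus(consensus, assignments)
    res <- list(k = k, assignments = assignments,
                consensus_matrix = consensus,
                silhouette_widths = sil, n_runs = n_runs)
    class(res) <- "consensus_result"
    results[[as.character(k)]] <- res
    survey[[as.character(k)]] <- data.frame(
      k = k, n_runs = n_runs, mean_silhouette = mean(sil),
      consensus_dispersion = mean((consensus - 0.5)^2) * 4)
  }
  if (!length(results)) fs_stopf("no feasible rank in k_range")
  attr(results, "rank_survey") <- do.call(rbind, survey)
  results
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf(paste0("<consensus_result: k=%d over %d runs, cluster sizes ",
                     "%s, mean silhouette %.3f>\n"),
              x$k, x$n_runs,
              paste(table(x$assignments), collapse = "/"),
              mean(x$silhouette_widths)))
  invisible(x)
}

#' @export
plot.consensus_result <- function(x, ...) {
  ord <- order(x$assignments, -x$silhouette_widths)
  graphics::image(x$consensus_matrix[ord, ord], useRaster = TRUE,
                  main = sprintf("Consensus matrix, k=%d", x$k),
                  xaxt = "n", yaxt = "n", ...)
  invisible(x)
}

#' Silhouette widths from a consensus matrix
#'
#' Standard silhouette widths with the dissimilarity
#' `d(i, j) = 1 - consensus[i, j]`: for sample i, `a` is its mean
#' dissimilarity to its own cluster (excluding itself), `b` the smallest
#' mean dissimilarity to any other cluster, and the width is
#' `(b - a) / max(a, b)`. Samples in singleton clusters get width 0.
#'
#' @param consensus_matrix symmetric co-clustering fraction matrix in
#'   \[0, 1\] with unit diagonal.
#' @param assignments per-sample cluster labels.
#' @return numeric vector of widths in \[-1, 1\].
#' @export
silhouette_from_consensus <- function(consensus_matrix, assignments) {
  d <- 1 - consensus_matrix
  n <- nrow(d)
  stopifnot(length(assignments) == n)
  widths <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(assignments == assignments[i])
    own <- setdiff(own, i)
    if (!length(own)) {
      widths[i] <- 0
      next
    }
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(unique(assignments), assignments[i]),
                    function(cl) mean(d[i, assignments == cl]), numeric(1)))
    widths[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  names(widths) <- rownames(consensus_matrix)
  widths
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions; 1 for identical
#' partitions (up to label names), ~0 for independent ones.
#'
#' @param a,b equal-length label vectors.
#' @return numeric ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(length(a))
  expected <- sum_a * sum_b / n
  denom <- (sum_a + sum_b) / 2 - expected
  if (denom == 0) return(1)
  (sum_ij - expected) / denom
}
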