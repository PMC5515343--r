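#' Select tumor-differential methylation probes
#'
#' Ranks probes by the difference of mean beta value, tumor minus normal,
#' and returns the `n_hyper` most hyper-methylated (largest positive
#' difference) and `n_hypo` most hypo-methylated probes. Probes with a
#' zero difference carry no direction and are never selected. Ties are
#' broken by probe id (lexicographic), so the selection is deterministic.
#'
#' @param tumor_matrix,normal_matrix beta [matrix_table()]s over a shared
#'   probe universe.
#' @param n_hyper,n_hypo number of probes per direction.
#' @return a `probe_set`: list with `hyper_probes`, `hypo_probes`, and
#'   the named per-probe `diff_scores`.
#' @export
select_differential_probes <- function(tumor_matrix, normal_matrix,
                                       n_hyper = 500L, n_hypo = 500L) {
  shared <- intersect(rownames(tumor_matrix), rownames(normal_matrix))
  if (length(shared) < n_hyper + n_hypo)
    fs_stopf("only %d shared probes; %d requested", length(shared),
             n_hyper + n_hypo)
  d <- rowMeans(tumor_matrix[shared, , drop = FALSE], na.rm = TRUE) -
    rowMeans(normal_matrix[shared, , drop = FALSE], na.rm = TRUE)
  d <- d[order(-d, names(d))]
  pos <- d[d > 0]
  neg <- d[d < 0]
  if (length(pos) < n_hyper || length(neg) < n_hypo)
    fs_stopf(paste0("not enough signed differences: %d hyper available ",
                    "(%d requested), %d hypo available (%d requested)"),
             length(pos), n_hyper, length(neg), n_hypo)
  neg <- neg[order(neg, names(neg))]   # most negative first
  out <- list(hyper_probes = names(pos)[seq_len(n_hyper)],
              hypo_probes = names(neg)[seq_len(n_hypo)],
              diff_scores = d)
  class(out) <- "probe_set"
  out
}

#' @export
print.probe_set <- function(x, ...) {
  cat(sprintf("<probe_set: %d hyper, %d hypo probes (diff range %.3f..%.3f)>\n",
              length(x$hyper_probes), length(x$hypo_probes),
              min(x$diff_scores), max(x$diff_scores)))
  invisible(x)
}

#' Regress adjacent-normal methylation on matched tumor methylation
#'
#' Ordinary least squares of the adjacent beta values on the tumor beta
#' values across the tumor-hypermethylated probes. A linear relationship
#' (high slope, small residual scatter) in the adjacent tissue is read as
#' the signature of occult tumor cells: a cell fraction `f` of tumor mixed
#' into normal tissue produces adjacent ~ f * tumor + const.
#'
#' @param adjacent_betas,tumor_betas named beta vectors for one patient.
#' @param probes a `probe_set` from [select_differential_probes()]; the
#'   regression uses its `hyper_probes` only.
#' @param sample_id optional label carried into the result.
#' @return an `occult_fit` with `slope`, `intercept`, `residual_se`
#'   (= sqrt(RSS / (n - 2))), `n_probes`, and unset `category`.
#' @export
fit_occult_regression <- function(adjacent_betas, tumor_betas, probes,
                                  sample_id = NA_character_) {
  pr <- probes$hyper_probes
  x <- tumor_betas[pr]
  y <- adjacent_betas[pr]
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 10) fs_stopf("fewer than 10 usable probes (%d)", n)
  if (stats::var(x) == 0) fs_stopf("zero variance in tumor betas; slope undefined")
  fit <- stats::lm.fit(cbind(1, x), y)
  rss <- sum(fit$residuals^2)
  out <- list(sample_id = sample_id,
              slope = unname(fit$coefficients[2]),
              intercept = unname(fit$coefficients[1]),
              residual_se = sqrt(rss / (n - 2)),
              n_probes = n, category = NA_character_)
  class(out) <- "occult_fit"
  out
}

#' @export
coef.occult_fit <- function(object, ...)
  c(intercept = object$intercept, slope = object$slope)

#' @export
print.occult_fit <- function(x, ...) {
  cat(sprintf("<occult_fit%s: slope %.3f, intercept %.3f, rse %.4f, n=%d%s>\n",
              if (is.na(x$sample_id)) "" else paste0(" ", x$sample_id),
              x$slope, x$intercept, x$residual_se, x$n_probes,
              if (is.na(x$category)) "" else paste0(", ", x$category)))
  invisible(x)
}

#' Classify a methylation regression as occult tumor, field effect, or normal
#'
#' A slope strictly above `slope_threshold` marks altered methylation;
#' among those, residual standard error strictly below `rse_threshold`
#' indicates occult tumor cells (a tight linear relationship), while a
#' large residual scatter indicates a field-cancerization effect.
#' Anything else is normal.
#'
#' @param result an `occult_fit`.
#' @param slope_threshold slope cut (default 0.4).
#' @param rse_threshold residual-s.e. cut (default 1.0).
#' @return the `occult_fit` with `category` set.
#' @export
classify_methylation <- function(result, slope_threshold = 0.4,
                                 rse_threshold = 1.0) {
  stopifnot(is.finite(result$slope), is.finite(result$residual_se))
  result$category <-
    if (result$slope > slope_threshold) {
      if (result$residual_se < rse_threshold) "occult_tumor" else "field_effect"
    } else "normal"
  result
}

#' Rank samples from high to low occult tumor probability
#'
#' Orders fits by slope descending, then residual s.e. ascending, then
#' sample id.
#'
#' @param results list of `occult_fit`s.
#' @return data.frame, one ranked row per sample.
#' @export
rank_samples <- function(results) {
  df <- data.frame(sample_id = vapply(results, `[[`, character(1), "sample_id"),
                   slope = vapply(results, `[[`, numeric(1), "slope"),
                   intercept = vapply(results, `[[`, numeric(1), "intercept"),
                   residual_se = vapply(results, `[[`, numeric(1), "residual_se"),
                   n_probes = vapply(results, `[[`, numeric(1), "n_probes"),
                   category = vapply(results, function(r)
                     r$category %||% NA_character_, character(1)),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$slope, df$residual_se, df$sample_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Check that hypermethylation signal is not confounded by cellularity
#'
#' Computes, per sample, the median beta over the hyper-methylated probe
#' set, and correlates it (Pearson) with an external tumor-cellularity
#' estimate. Absence of correlation argues the occult-tumor regression is
#' not simply tracking cellularity.
#'
#' @param adjacent_matrix beta [matrix_table()] of adjacent samples.
#' @param probes a `probe_set`.
#' @param cellularity named per-sample numeric.
#' @return list with `pearson_r`, `p_value`, `n`.
#' @export
cellularity_confound_check <- function(adjacent_matrix, probes, cellularity) {
  med <- apply(adjacent_matrix[probes$hyper_probes, , drop = FALSE], 2,
               stats::median, na.rm = TRUE)
  shared <- intersect(names(med), names(cellularity))
  cellu <- cellularity[shared]
  med <- med[shared]
  keep <- is.finite(cellu) & is.finite(med)
  if (sum(keep) < 3) fs_stopf("need >=3 samples with cellularity")
  if (stats::sd(med[keep]) == 0 || stats::sd(cellu[keep]) == 0)
    fs_stopf("constant vector; correlation undefined")
  ct <- stats::cor.test(med[keep], cellu[keep], method = "pearson")
  list(pearson_r = unname(ct$estimate), p_value = ct$p.value, n = sum(keep))
}

#' Run the occult-methylation analysis over a cohort
#'
#' Convenience wrapper: selects differential probes from the tumor vs
#' reference-normal matrices, fits and classifies the regression for every
#' adjacent sample, and returns the ranked table.
#'
#' @param tumor_matrix,adjacent_matrix beta [matrix_table()]s with matched
#'   sample columns.
#' @param normal_matrix reference-normal panel for probe selection
#'   (defaults to the adjacent cohort itself).
#' @param slope_threshold,rse_threshold classification cuts.
#' @param n_hyper,n_hypo probe counts for selection.
#' @return ranked data.frame as from [rank_samples()], with the
#'   `probe_set` attached as attribute `"probes"`.
#' @export
methylation_screen <- function(tumor_matrix, adjacent_matrix,
                               normal_matrix = adjacent_matrix,
                               slope_threshold = 0.4, rse_threshold = 1.0,
                               n_hyper = 500L, n_hypo = 500L) {
  probes <- select_differential_probes(tumor_matrix, normal_matrix,
                                       n_hyper, n_hypo)
  samples <- intersect(colnames(tumor_matrix), colnames(adjacent_matrix))
  fits <- lapply(samples, function(s) {
    fit <- fit_occult_regression(adjacent_matrix[, s], tumor_matrix[, s],
                                 probes, sample_id = s)
    classify_methylation(fit, slope_threshold, rse_threshold)
  })
  out <- rank_samples(fits)
  attr(out, "probes") <- probes
  out
}
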