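#' Construct a validated feature-by-sample matrix table
#'
#' Thin wrapper around a numeric matrix (features in rows, samples in
#' columns) that records what kind of value it holds and enforces the
#' invariants of that kind: methylation beta values must lie in \[0, 1\],
#' counts must be non-negative, and feature/sample identifiers must be
#' unique.
#'
#' @param values numeric matrix with rownames (feature ids) and colnames
#'   (sample ids).
#' @param value_kind one of `"beta"`, `"count"`, `"rpm"`,
#'   `"uq_normalized"`, `"log_scaled"`.
#' @return a `matrix_table`: the input matrix with a `value_kind`
#'   attribute.
#' @export
matrix_table <- function(values,
                         value_kind = c("beta", "count", "rpm",
                                        "uq_normalized", "log_scaled")) {
  value_kind <- match.arg(value_kind)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    fs_stopf("matrix_table requires feature rownames and sample colnames")
  dup_f <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_f))
    fs_stopf("duplicated feature id(s): %s", paste(dup_f, collapse = ", "))
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s))
    fs_stopf("duplicated sample id(s): %s", paste(dup_s, collapse = ", "))
  ok <- values[!is.na(values)]
  if (value_kind == "beta" && length(ok) && (min(ok) < 0 || max(ok) > 1))
    fs_stopf("beta values outside [0, 1] (range %.4g..%.4g)", min(ok), max(ok))
  if (value_kind %in% c("count", "rpm", "uq_normalized") &&
      length(ok) && min(ok) < 0)
    fs_stopf("%s values must be non-negative", value_kind)
  structure(values, value_kind = value_kind,
            class = c("matrix_table", "matrix", "array"))
}

#' @export
print.matrix_table <- function(x, ...) {
  cat(sprintf("<matrix_table: %d features x %d samples, kind '%s'>\n",
              nrow(x), ncol(x), attr(x, "value_kind")))
  invisible(x)
}

value_kind <- function(x) attr(x, "value_kind") %||% "count"

#' Read a feature-by-sample TSV matrix
#'
#' Expects a rectangular tab-separated file: first column feature ids,
#' first row sample ids. Cells with NA are handled per `na_action`:
#' `"drop_feature"` removes any feature with a missing cell (logged with a
#' count), `"error"` aborts.
#'
#' @param path TSV file.
#' @param value_kind declared content kind (see [matrix_table()]).
#' @param na_action `"drop_feature"` or `"error"`.
#' @return a [matrix_table()].
#' @export
read_matrix <- function(path, value_kind = "count",
                        na_action = c("drop_feature", "error")) {
  na_action <- match.arg(na_action)
  if (!file.exists(path)) fs_stopf("file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) fs_stopf("matrix file needs id column plus >=1 sample: %s", path)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (anyNA(m)) {
    if (na_action == "error") fs_stopf("NA cells in matrix %s", path)
    bad <- rowSums(is.na(m)) > 0
    message(sprintf("read_matrix: dropping %d/%d features with NA cells",
                    sum(bad), nrow(m)))
    m <- m[!bad, , drop = FALSE]
  }
  matrix_table(m, value_kind)
}

#' Write a matrix table as TSV
#' @param x a [matrix_table()] (or plain named matrix).
#' @param path output file.
#' @param id_col name for the feature-id column.
#' @export
write_matrix <- function(x, path, id_col = "feature_id") {
  df <- data.frame(rownames(x), as.data.frame(unclass(x), check.names = FALSE),
                   check.names = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a SEG copy-number segment file
#'
#' Parses the tab-separated SEG dialect (Sample, Chromosome, Start, End,
#' optional Num_Probes, Segment_Mean). Coordinates are normalized to
#' 0-based half-open regardless of the input dialect, so segment length is
#' always `end - start`. Chromosome names lose any leading `"chr"`.
#'
#' @param path SEG file with a header row.
#' @param dialect `"one_closed"` (1-based closed, the common SEG export)
#'   or `"zero_half_open"`.
#' @return data.frame with columns sample, chrom, start, end, seg_mean,
#'   sorted by (sample, chrom, start), class `seg_table`.
#' @export
read_seg <- function(path, dialect = c("one_closed", "zero_half_open")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) fs_stopf("file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) < 5) fs_stopf("SEG file needs >=5 columns: %s", path)
  # last column is the segment mean whether or not Num_Probes is present
  out <- data.frame(sample = as.character(df[[1]]),
                    chrom = normalize_chrom(df[[2]]),
                    start = suppressWarnings(as.numeric(df[[3]])),
                    end = suppressWarnings(as.numeric(df[[4]])),
                    seg_mean = suppressWarnings(as.numeric(df[[ncol(df)]])),
                    stringsAsFactors = FALSE)
  bad <- which(!is.finite(out$start) | !is.finite(out$end) |
                 !is.finite(out$seg_mean))
  if (length(bad))
    fs_stopf("malformed SEG row at line %d of %s", bad[1] + 1L, path)
  if (dialect == "one_closed") out$start <- out$start - 1
  bad <- which(out$start >= out$end)
  if (length(bad))
    fs_stopf("segment with start >= end at line %d of %s", bad[1] + 1L, path)
  out <- out[order(out$sample, out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  ov <- 0L
  for (key in unique(paste(out$sample, out$chrom))) {
    s <- out[paste(out$sample, out$chrom) == key, , drop = FALSE]
    if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)])) ov <- ov + 1L
  }
  if (ov) fs_warnf("read_seg: overlapping segments within %d sample/chrom group(s)", ov)
  class(out) <- c("seg_table", "data.frame")
  out
}

#' Write segments as a SEG file
#' @param seg data.frame as returned by [read_seg()] (0-based half-open).
#' @param path output file.
#' @param dialect coordinate dialect to emit.
#' @export
write_seg <- function(seg, path, dialect = c("one_closed", "zero_half_open")) {
  dialect <- match.arg(dialect)
  start <- if (dialect == "one_closed") seg$start + 1 else seg$start
  df <- data.frame(Sample = seg$sample, Chromosome = seg$chrom,
                   Start = start, End = seg$end, Segment_Mean = seg$seg_mean)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

variant_cols <- c("patient", "chrom", "pos", "ref", "alt",
                  "t_ref", "t_alt", "b_ref", "b_alt", "n_ref", "n_alt",
                  "rna_ref", "rna_alt")

#' Read a somatic-variant pileup table
#'
#' Tab-separated table with one row per tumor-derived SNV and per-sample
#' ref/alt read counts: `t_*` tumor, `b_*` blood, `n_*` adjacent normal,
#' `rna_*` RNA-seq evidence at the locus. An optional `gene` column is
#' kept for recurrence reporting. VAFs are derived as alt/(ref+alt).
#'
#' @param path TSV file.
#' @return data.frame of variants with derived `t_vaf`, `b_vaf`, `n_vaf`
#'   columns, class `variant_table`.
#' @export
read_variants <- function(path) {
  if (!file.exists(path)) fs_stopf("file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  missing_cols <- setdiff(variant_cols, names(df))
  if (length(missing_cols))
    fs_stopf("variant table missing column(s): %s",
             paste(missing_cols, collapse = ", "))
  df$chrom <- normalize_chrom(df$chrom)
  cnt <- variant_cols[6:13]
  for (cc in cnt) {
    df[[cc]] <- as.integer(df[[cc]])
    if (any(is.na(df[[cc]]) | df[[cc]] < 0))
      fs_stopf("negative or missing read count in column %s", cc)
  }
  as_variant_table(df)
}

as_variant_table <- function(df) {
  vaf <- function(alt, ref) ifelse(alt + ref > 0, alt / (alt + ref), NA_real_)
  df$t_vaf <- vaf(df$t_alt, df$t_ref)
  df$b_vaf <- vaf(df$b_alt, df$b_ref)
  df$n_vaf <- vaf(df$n_alt, df$n_ref)
  class(df) <- c("variant_table", "data.frame")
  df
}

#' Write a variant pileup table as TSV
#' @param variants data.frame with the pileup columns.
#' @param path output file.
#' @export
write_variants <- function(variants, path) {
  keep <- intersect(c(variant_cols, "gene"), names(variants))
  utils::write.table(variants[, keep, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

clinical_levels <- list(
  er_status = c("positive", "negative", "unknown"),
  age_decade = c("<40", "40-49", "50-59", "60-69", "70+"),
  stage = c("I", "II", "III/IV"),
  t_size = c("T1", "T2", "T3", "T4"),
  node_status = c("negative", "positive"),
  tumor_subtype = c("LumA", "LumB", "HER2", "Basal", "unknown")
)

#' Read a clinical covariate table
#'
#' Tab-separated, one row per patient: patient_id, er_status, age_decade,
#' stage, t_size, node_status, tumor_subtype, time_years, event.
#' Categorical fields are validated against their closed level sets; an
#' optional raw `stage_raw` column (e.g. "IV") is preserved for
#' sensitivity analyses.
#'
#' @param path TSV file.
#' @return data.frame with factor covariates, class `clinical_table`.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) fs_stopf("file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("patient_id", names(clinical_levels), "time_years", "event")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    fs_stopf("clinical table missing column(s): %s",
             paste(missing_cols, collapse = ", "))
  for (v in names(clinical_levels)) {
    bad <- setdiff(unique(df[[v]]), clinical_levels[[v]])
    if (length(bad))
      fs_stopf("invalid %s level(s): %s", v, paste(bad, collapse = ", "))
    df[[v]] <- factor(df[[v]], levels = clinical_levels[[v]])
  }
  df$time_years <- as.numeric(df$time_years)
  if (any(!is.finite(df$time_years) | df$time_years < 0))
    fs_stopf("time_years must be finite and >= 0")
  df$event <- as.logical(df$event)
  class(df) <- c("clinical_table", "data.frame")
  df
}

#' Write a clinical covariate table as TSV
#' @param clinical data.frame as from [read_clinical()].
#' @param path output file.
#' @export
write_clinical <- function(clinical, path) {
  utils::write.table(clinical, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
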