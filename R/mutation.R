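#' Two-sided Fisher exact p-value for 2x2 tables
#'
#' Exact hypergeometric-sum p-value for the table
#' `rbind(c(a, b), c(c, d))`: all tables with the same margins whose
#' probability does not exceed that of the observed table (to within a
#' 1e-7 relative tolerance) contribute. Vectorised over the four count
#' vectors; used to test tumor alt/ref counts against blood.
#'
#' @param a,b,c,d non-negative integer vectors (recycled).
#' @return p-values in (0, 1].
#' @export
fisher_exact_p <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(a, n); b <- rep_len(b, n)
  c <- rep_len(c, n); d <- rep_len(d, n)
  vapply(seq_len(n), function(i) {
    m1 <- a[i] + c[i]            # first-column margin (alt reads)
    m2 <- b[i] + d[i]            # second-column margin (ref reads)
    k <- a[i] + b[i]             # first-row margin (tumor depth)
    support <- max(0L, k - m2):min(k, m1)
    dens <- stats::dhyper(support, m1, m2, k)
    obs <- stats::dhyper(a[i], m1, m2, k)
    sum(dens[dens <= obs * (1 + 1e-7)])
  }, numeric(1))
}

#' Somatic SNV filter cascade
#'
#' Keeps tumor-derived SNVs that are measurable in all three compartments
#' and credibly somatic: depth at least `min_cov` in tumor, blood, and
#' adjacent; tumor VAF strictly above `min_tumor_vaf`; two-sided Fisher
#' exact p below `max_p` for tumor alt/ref vs blood alt/ref; and blood VAF
#' strictly below `max_blood_vaf`. Variants are annotated, not silently
#' dropped: `passes_somatic_filter` and a `filter_reason` column record
#' the outcome (zero depth gives reason `"insufficient_coverage"`).
#'
#' @param variants a `variant_table` (see [read_variants()]).
#' @param min_cov minimum depth in all three DNA samples (default 20).
#' @param min_tumor_vaf tumor VAF floor (default 0.10, strict).
#' @param max_p Fisher p ceiling (default 0.05).
#' @param max_blood_vaf blood VAF ceiling (default 0.05).
#' @return the table with `fisher_p`, `passes_somatic_filter`,
#'   `filter_reason` columns set.
#' @export
filter_somatic_snvs <- function(variants, min_cov = 20, min_tumor_vaf = 0.10,
                                max_p = 0.05, max_blood_vaf = 0.05) {
  v <- variants
  td <- v$t_ref + v$t_alt; bd <- v$b_ref + v$b_alt; nd <- v$n_ref + v$n_alt
  v$fisher_p <- fisher_exact_p(v$t_alt, v$t_ref, v$b_alt, v$b_ref)
  reason <- rep(NA_character_, nrow(v))
  pass <- rep(TRUE, nrow(v))
  fail <- function(cond, why) {
    hit <- cond & pass
    reason[hit] <<- why
    pass <<- pass & !cond
  }
  fail(td == 0 | bd == 0 | nd == 0, "insufficient_coverage")
  fail(td < min_cov | bd < min_cov | nd < min_cov, "insufficient_coverage")
  fail(!is.na(v$t_vaf) & v$t_vaf <= min_tumor_vaf, "low_tumor_vaf")
  fail(v$fisher_p >= max_p, "not_significant")
  fail(!is.na(v$b_vaf) & v$b_vaf >= max_blood_vaf, "present_in_blood")
  v$passes_somatic_filter <- pass
  v$filter_reason <- reason
  v
}

#' Classify adjacent-normal mutation burden
#'
#' Among filter-passing somatic SNVs, a variant counts as detected in the
#' adjacent normal when it has at least `detection_floor_alt_reads` alt
#' reads there. With `frac` the fraction of detected variants whose
#' adjacent VAF exceeds 1%: fewer than 2 detected variants is `none`;
#' `frac >= 0.5` is `high`; `frac <= 0.1` is `low`; anything between is
#' `moderate`. (The printed tier definitions overlap as written; this
#' precedence — none, high, low, moderate — maps every case to exactly one
#' class.)
#'
#' @param variants filtered `variant_table` (rows failing
#'   `passes_somatic_filter` are ignored when the column is present).
#' @param detection_floor_alt_reads adjacent alt-read floor (default 2).
#' @param vaf_cut adjacent VAF threshold defining the fraction
#'   (default 0.01, strict).
#' @param patient_id carried into the call.
#' @return a `burden_call`: list with `patient_id`, `n_detected`,
#'   `frac_vaf_gt_1pct`, `category`.
#' @export
classify_exome_burden <- function(variants, detection_floor_alt_reads = 2L,
                                  vaf_cut = 0.01, patient_id = NA_character_) {
  v <- variants
  if (!is.null(v$passes_somatic_filter))
    v <- v[v$passes_somatic_filter, , drop = FALSE]
  det <- v[v$n_alt >= detection_floor_alt_reads, , drop = FALSE]
  n_det <- nrow(det)
  frac <- if (n_det) mean(det$n_vaf > vaf_cut, na.rm = TRUE) else NA_real_
  category <- if (n_det < 2) "none"
  else if (frac >= 0.5) "high"
  else if (frac <= 0.1) "low"
  else "moderate"
  out <- list(patient_id = patient_id, n_detected = n_det,
              frac_vaf_gt_1pct = frac, category = category)
  class(out) <- "burden_call"
  out
}

#' @export
print.burden_call <- function(x, ...) {
  cat(sprintf("<burden_call%s: %d detected, frac VAF>1%% = %s -> %s>\n",
              if (is.na(x$patient_id)) "" else paste0(" ", x$patient_id),
              x$n_detected,
              if (is.na(x$frac_vaf_gt_1pct)) "NA"
              else sprintf("%.2f", x$frac_vaf_gt_1pct),
              x$category))
  invisible(x)
}

#' Score RNA-level expression of tumor mutations
#'
#' A tumor somatic locus is "expressed" in the adjacent tissue when its
#' RNA depth reaches `min_rna_depth`; an expressed locus is "present" when
#' at least `min_var_reads` RNA reads support the variant allele. A sample
#' is positive when at least two loci are present.
#'
#' @param variants `variant_table` with `rna_ref`/`rna_alt` columns
#'   (filter-passing rows used when the flag column is present).
#' @param min_rna_depth minimum RNA coverage (default 10).
#' @param min_var_reads variant-read floor (default 2).
#' @return list `expressed_fraction`, `mutant_expressed_fraction`,
#'   `n_present`, `positive`, `undefined` (TRUE when no locus reaches
#'   `min_rna_depth`).
#' @export
rna_mutation_score <- function(variants, min_rna_depth = 10L,
                               min_var_reads = 2L) {
  v <- variants
  if (!is.null(v$passes_somatic_filter))
    v <- v[v$passes_somatic_filter, , drop = FALSE]
  rd <- v$rna_ref + v$rna_alt
  expressed <- rd >= min_rna_depth
  present <- expressed & v$rna_alt >= min_var_reads
  n_present <- sum(present)
  if (!nrow(v) || !any(expressed)) {
    return(list(expressed_fraction = NA_real_,
                mutant_expressed_fraction = NA_real_,
                n_present = 0L, positive = FALSE, undefined = TRUE))
  }
  list(expressed_fraction = mean(expressed),
       mutant_expressed_fraction = n_present / sum(expressed),
       n_present = n_present,
       positive = n_present >= 2L, undefined = FALSE)
}

#' Per-gene recurrence of tumor mutations in adjacent normal
#'
#' Groups filter-passing somatic variants by gene and reports, per gene,
#' the tumor mutation count, how many of those were detected in the
#' adjacent normal (alt reads at or above the detection floor), the
#' maximum adjacent VAF, and how many detected variants stayed under 1%
#' VAF.
#'
#' @param variants `variant_table` with a `gene` column.
#' @param detection_floor_alt_reads adjacent alt-read floor (default 2).
#' @return data.frame with one row per gene, sorted by n_tumor
#'   descending.
#' @export
tumor_gene_recurrence_report <- function(variants,
                                         detection_floor_alt_reads = 2L) {
  v <- variants
  if (is.null(v$gene)) fs_stopf("variant table lacks a 'gene' column")
  if (!is.null(v$passes_somatic_filter))
    v <- v[v$passes_somatic_filter, , drop = FALSE]
  v <- v[!is.na(v$gene) & nzchar(v$gene), , drop = FALSE]
  if (!nrow(v))
    return(data.frame(gene = character(), n_tumor = integer(),
                      n_detected_in_adjacent = integer(),
                      max_adjacent_vaf = numeric(),
                      n_vaf_lt_1pct = integer(), stringsAsFactors = FALSE))
  rows <- lapply(split(v, v$gene), function(g) {
    det <- g$n_alt >= detection_floor_alt_reads
    data.frame(gene = g$gene[1], n_tumor = nrow(g),
               n_detected_in_adjacent = sum(det),
               max_adjacent_vaf = if (any(det)) max(g$n_vaf[det]) else NA_real_,
               n_vaf_lt_1pct = sum(det & g$n_vaf < 0.01),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$n_tumor, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mutation-burden screen over a cohort variant table
#'
#' Applies [filter_somatic_snvs()] then classifies burden and RNA
#' positivity per patient.
#'
#' @param variants cohort `variant_table` with a `patient` column.
#' @param ... passed to [filter_somatic_snvs()].
#' @return data.frame with one row per patient.
#' @export
mutation_screen <- function(variants, ...) {
  filt <- filter_somatic_snvs(variants, ...)
  rows <- lapply(split(filt, filt$patient), function(v) {
    b <- classify_exome_burden(v, patient_id = v$patient[1])
    r <- rna_mutation_score(v)
    data.frame(patient_id = v$patient[1],
               n_pass_filter = sum(v$passes_somatic_filter),
               n_detected = b$n_detected,
               frac_vaf_gt_1pct = b$frac_vaf_gt_1pct,
               burden = b$category,
               rna_n_present = r$n_present,
               rna_positive = r$positive, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
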