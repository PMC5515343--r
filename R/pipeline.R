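#' Run the full multi-platform analysis on a simulated or loaded cohort
#'
#' Chains every analysis stage: the occult-methylation screen (tumor vs
#' reference-normal probe selection, per-sample regression and
#' classification), the copy-number reciprocal-overlap screen with blood
#' exclusion, the somatic mutation filter/burden/RNA screen, miR RPM
#' normalization with expression and variance filtering, NMF consensus
#' clustering of miR and mRNA matrices with consensus silhouettes, SAM
#' Wilcoxon differential abundance between the two miR clusters,
#' mRNA-miR cluster concordance, defect integration, and Kaplan-Meier /
#' Cox survival models among ER-positive patients.
#'
#' Cluster labels are arbitrary under NMF; the two mRNA consensus
#' clusters are mapped to active/inactive by higher overall expression of
#' the cluster's own differential features (the active stroma signature),
#' falling back to cluster order on ties.
#'
#' @param cohort a cohort list from [simulate_cohort()] (or assembled
#'   from the readers with the same shape).
#' @param k number of expression clusters (default 2).
#' @param runs_survey,runs_final NMF restarts (defaults 10 and 100, the
#'   reduced schedule; raise to 30/500 for a full run).
#' @param n_perms SAM permutations (default 1000).
#' @param seed seed for clustering restarts and permutations.
#' @param censor_at survival censoring horizon (years).
#' @param out_dir optional directory for TSV reports.
#' @return a `fieldscape_report` list with elements `methylation`,
#'   `cnv`, `mutations`, `mir_consensus`, `mrna_consensus`,
#'   `differential`, `concordance`, `subtype`, `defects`, `km`, `cox`,
#'   `associations`.
#' @export
run_pipeline <- function(cohort, k = 2L, runs_survey = 10L,
                         runs_final = 100L, n_perms = 1000L, seed = 1L,
                         censor_at = 10, out_dir = NULL) {
  meth <- methylation_screen(cohort$methylation$tumor,
                             cohort$methylation$adjacent,
                             normal_matrix = cohort$methylation$normal)
  cnv <- cnv_screen(cohort$segments, mode = "triplet")
  mut <- mutation_screen(cohort$variants)

  cluster_matrix <- function(counts, sub_seed) {
    rpm <- rpm_normalize(counts)
    expressed <- filter_expressed_mirs(rpm)
    feats <- select_variable_features(expressed, fraction = 0.25)
    sel <- matrix_table(unclass(expressed)[feats, , drop = FALSE], "rpm")
    cons <- consensus_cluster(sel, k_range = k, k_final = k,
                              runs_survey = runs_survey,
                              runs_final = runs_final, seed = sub_seed)
    list(matrix = sel, result = cons[[as.character(k)]])
  }
  mir <- cluster_matrix(cohort$expression$mir, patient_seed(seed, 11L))
  mrna <- cluster_matrix(cohort$expression$mrna, patient_seed(seed, 12L))

  sam <- sam_wilcoxon(mir$matrix, mir$result$assignments, n_perms = n_perms,
                      seed = patient_seed(seed, 13L))
  diff <- filter_differential(sam)

  concordance <- cluster_concordance(mir$result$assignments,
                                     mrna$result$assignments)

  # orient mRNA clusters: the cluster with higher overall abundance of the
  # variance-selected features is called active (the active stroma signature
  # up-regulates them); cluster order breaks exact ties
  lab <- mrna$result$assignments
  mean_by <- vapply(sort(unique(lab)), function(cl)
    mean(unclass(mrna$matrix)[, lab == cl, drop = FALSE]), numeric(1))
  active_cl <- sort(unique(lab))[which.max(mean_by)]
  subtype <- ifelse(lab == active_cl, "active", "inactive")
  names(subtype) <- names(lab)

  clinical <- cohort$expression$clinical
  defect_inputs <- data.frame(patient_id = clinical$patient_id,
                              stringsAsFactors = FALSE)
  idx <- function(tab, key, col)
    tab[[col]][match(defect_inputs$patient_id, tab[[key]])]
  defects <- integrate_defects(
    patient_id = defect_inputs$patient_id,
    methylation_category = idx(meth, "sample_id", "category"),
    cn_category = idx(cnv, "sample_id", "category"),
    exome_category = idx(mut, "patient_id", "burden"),
    rna_positive = idx(mut, "patient_id", "rna_positive"))

  surv_df <- as.data.frame(clinical)
  surv_df$subtype <- subtype[surv_df$patient_id]
  surv_df$any_defect <- defects$any_defect[match(surv_df$patient_id,
                                                 defects$patient_id)]
  er <- surv_df[surv_df$er_status == "positive" & !is.na(surv_df$subtype), ]
  km <- km_fit(er, er$subtype, censor_at = censor_at)
  cox <- tryCatch(
    cox_fit(er, er_filter = TRUE, censor_at = censor_at),
    error = function(e) {
      message("full Cox model infeasible (", conditionMessage(e),
              "); fitting subtype + node_status + any_defect")
      cox_fit(er, covariates = c("subtype", "node_status", "any_defect"),
              er_filter = TRUE, censor_at = censor_at)
    })
  assoc <- association_tests(er, er$subtype)

  report <- list(methylation = meth, cnv = cnv, mutations = mut,
                 mir_consensus = mir$result, mrna_consensus = mrna$result,
                 differential = diff, concordance = concordance,
                 subtype = subtype, defects = defects, km = km, cox = cox,
                 associations = assoc)
  class(report) <- "fieldscape_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.fieldscape_report <- function(x, ...) {
  prev <- function(tab, col, val) mean(tab[[col]] == val, na.rm = TRUE)
  cat("<fieldscape_report>\n")
  cat(sprintf("  methylation: %.0f%% occult, %.0f%% field effect\n",
              100 * prev(x$methylation, "category", "occult_tumor"),
              100 * prev(x$methylation, "category", "field_effect")))
  cat(sprintf("  copy number: %.0f%% evidence of tumor\n",
              100 * prev(x$cnv, "category", "evidence_of_tumor")))
  cat(sprintf("  mutations:   %.0f%% moderate/high burden, %.0f%% RNA positive\n",
              100 * mean(x$mutations$burden %in% c("moderate", "high")),
              100 * mean(x$mutations$rna_positive)))
  cat(sprintf("  any defect:  %.0f%%\n",
              100 * mean(x$defects$any_defect, na.rm = TRUE)))
  cat(sprintf("  miR/mRNA cluster concordance: %.2f\n", x$concordance))
  hr <- x$cox$terms[grepl("^subtype", x$cox$terms$term), ]
  if (nrow(hr))
    cat(sprintf("  Cox HR (active vs inactive, ER+): %.2f [%.2f, %.2f]\n",
                hr$hazard_ratio[1], hr$ci_low[1], hr$ci_high[1]))
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name)
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  w(report$methylation, "methylation_calls.tsv")
  w(report$cnv, "cnv_calls.tsv")
  w(report$mutations, "mutation_burden.tsv")
  w(report$differential$all, "differential_mirs.tsv")
  w(as.data.frame(report$defects), "defect_profile.tsv")
  w(report$km$curves, "km_curves.tsv")
  w(report$cox$terms, "cox_terms.tsv")
  w(report$associations, "association_tests.tsv")
  w(data.frame(sample_id = names(report$subtype),
               subtype = unname(report$subtype),
               mir_cluster = unname(report$mir_consensus$assignments),
               silhouette = unname(report$mir_consensus$silhouette_widths)),
    "subtypes.tsv")
  utils::write.table(
    report$mir_consensus$consensus_matrix,
    file.path(out_dir, "mir_consensus_matrix.tsv"),
    sep = "\t", quote = FALSE, col.names = NA)
  invisible(out_dir)
}
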