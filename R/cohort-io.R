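#' Load a cohort directory written by [simulate_cohort()]
#'
#' Reads the on-disk cohort layout (beta matrices, per-compartment SEG
#' files, variant and clinical TSVs, count matrices) back into the
#' in-memory cohort shape consumed by [run_pipeline()]. The ground-truth
#' table is attached when present but never used by the analysis stages.
#'
#' @param dir cohort directory.
#' @return cohort list (`methylation`, `segments`, `variants`,
#'   `expression`, optional `truth`).
#' @export
read_cohort <- function(dir) {
  p <- function(...) file.path(dir, ...)
  need <- c("methylation_tumor.tsv", "methylation_normal.tsv",
            "methylation_adjacent.tsv", "segments_tumor.seg",
            "segments_adjacent.seg", "variants.tsv", "mrna_counts.tsv",
            "mir_counts.tsv", "clinical.tsv")
  absent <- need[!file.exists(p(need))]
  if (length(absent))
    fs_stopf("cohort directory %s is missing: %s", dir,
             paste(absent, collapse = ", "))
  methylation <- list(tumor = read_matrix(p("methylation_tumor.tsv"), "beta"),
                      normal = read_matrix(p("methylation_normal.tsv"), "beta"),
                      adjacent = read_matrix(p("methylation_adjacent.tsv"), "beta"))
  read_seg_grouped <- function(path) {
    if (!file.exists(path)) return(list())
    seg <- suppressWarnings(read_seg(path))
    split(as.data.frame(seg), seg$sample)
  }
  tum <- read_seg_grouped(p("segments_tumor.seg"))
  bld <- read_seg_grouped(p("segments_blood.seg"))
  adj <- read_seg_grouped(p("segments_adjacent.seg"))
  pids <- colnames(methylation$adjacent)
  segments <- lapply(pids, function(pid)
    list(tumor = tum[[pid]] %||% empty_seg(),
         blood = bld[[pid]] %||% empty_seg(),
         adjacent = adj[[pid]] %||% empty_seg()))
  names(segments) <- pids
  clinical <- read_clinical(p("clinical.tsv"))
  expression <- list(mrna = read_matrix(p("mrna_counts.tsv"), "count"),
                     mir = read_matrix(p("mir_counts.tsv"), "count"),
                     clinical = clinical)
  cohort <- list(methylation = methylation, segments = segments,
                 variants = read_variants(p("variants.tsv")),
                 expression = expression)
  if (file.exists(p("truth.tsv")))
    cohort$truth <- utils::read.delim(p("truth.tsv"),
                                      stringsAsFactors = FALSE)
  cohort
}
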