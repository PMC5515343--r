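#' Simulation configuration for a tumor/blood/adjacent-normal cohort
#'
#' Builds the full set of ground-truth parameters for a synthetic cohort.
#' Per-patient parameters (`occult_fractions`, `field_effect_flags`,
#' `cn_contamination`, `adjacent_vaf_scale`) may be supplied as vectors
#' (recycled scalars allowed); when left `NULL` they default to a cohort
#' layout emulating the prevalences reported for cancer-adjacent breast
#' tissue: ~10% of patients carry heavy occult contamination detectable on
#' copy-number arrays (contamination 1, VAF scale 0.5), a further ~5% carry
#' occult methylation signal only (fraction drawn in \[0.4, 0.8\]), a further
#' ~15% carry a low-VAF mutation burden (scale 0.1, giving adjacent VAFs
#' typically below 5%), and ~36% of the remaining patients show a sparse
#' field-cancerization methylation shift.
#'
#' @param n_patients cohort size.
#' @param n_probes methylation probes per sample.
#' @param occult_fractions per-patient occult tumor-cell fraction in \[0,1\].
#' @param field_effect_flags per-patient logical; sparse probe-subset shift.
#' @param probe_noise_sd Gaussian noise sd added to adjacent betas.
#' @param n_segments somatic copy-number segments per tumor.
#' @param cn_contamination per-patient probability a tumor segment is
#'   copied into the adjacent profile.
#' @param n_somatic_snvs somatic SNVs per patient (default 30, the
#'   typical whole-exome burden of a breast tumor at ~1 mutation/Mb).
#' @param adjacent_vaf_scale per-patient scaling of tumor VAF (and of the
#'   copied segment log2 ratio) in the adjacent tissue.
#' @param depth_mean mean DNA sequencing depth (Poisson).
#' @param rna_depth_mean mean RNA depth at variant loci (Poisson).
#' @param n_mrna_features,n_mir_features expression feature counts.
#' @param subtype_effect_log2 log2 shift of affected features between
#'   expression subtypes.
#' @param affected_fraction fraction of features carrying the subtype
#'   effect.
#' @param p_active probability a patient has the active subtype.
#' @param mir_concordance probability the miR subtype label equals the
#'   mRNA label.
#' @param survival_log_hr log hazard ratio of active vs inactive subtype.
#' @param baseline_hazard exponential baseline hazard (/year).
#' @param censor_time administrative censoring time (years).
#' @param seg_len_min,seg_len_max tumor segment length bounds (bp).
#' @param germline_cnv inject one germline CNV into all three profiles
#'   (negative control for the blood-exclusion rule).
#' @param seed master seed; fixes the whole cohort deterministically.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_patients = 102, n_probes = 2000,
                       occult_fractions = NULL, field_effect_flags = NULL,
                       probe_noise_sd = 0.03,
                       n_segments = 10, cn_contamination = NULL,
                       n_somatic_snvs = 30, adjacent_vaf_scale = NULL,
                       depth_mean = 500, rna_depth_mean = 50,
                       n_mrna_features = 2000, n_mir_features = 1212,
                       subtype_effect_log2 = 1.0, affected_fraction = 0.10,
                       p_active = 0.6, mir_concordance = 0.90,
                       survival_log_hr = log(3), baseline_hazard = 0.05,
                       censor_time = 10,
                       seg_len_min = 5e4, seg_len_max = 2e6,
                       germline_cnv = FALSE, seed = 1L) {
  stopifnot(n_patients >= 1, n_probes >= 1000, n_segments >= 0,
            n_somatic_snvs >= 0, probe_noise_sd >= 0,
            p_active >= 0, p_active <= 1,
            mir_concordance >= 0, mir_concordance <= 1,
            baseline_hazard > 0, censor_time > 0,
            seg_len_min > 0, seg_len_max >= seg_len_min)
  n <- as.integer(n_patients)
  set.seed(patient_seed(seed, 0L))
  if (is.null(occult_fractions) || is.null(cn_contamination) ||
      is.null(adjacent_vaf_scale) || is.null(field_effect_flags)) {
    n_heavy <- ceiling(0.10 * n)              # CN-visible occult contamination
    n_occ_only <- ceiling(0.05 * n)           # methylation-only occult signal
    n_lowvaf <- ceiling(0.15 * n)             # low-VAF mutation burden
    heavy <- seq_len(n) <= n_heavy
    occ_only <- seq_len(n) > n_heavy & seq_len(n) <= n_heavy + n_occ_only
    lowvaf <- seq_len(n) > n_heavy + n_occ_only &
      seq_len(n) <= n_heavy + n_occ_only + n_lowvaf
    def_f <- ifelse(heavy | occ_only, stats::runif(n, 0.4, 0.8), 0)
    def_cn <- ifelse(heavy, 1, 0)
    def_scale <- ifelse(heavy, 0.5, ifelse(lowvaf, 0.1, 0))
    rest <- !(heavy | occ_only)
    def_field <- rest & (seq_along(rest) %% 100 < 36)  # ~36% of the rest
    if (is.null(occult_fractions)) occult_fractions <- def_f
    if (is.null(cn_contamination)) cn_contamination <- def_cn
    if (is.null(adjacent_vaf_scale)) adjacent_vaf_scale <- def_scale
    if (is.null(field_effect_flags)) field_effect_flags <- def_field
  }
  rec <- function(x) rep_len(as.numeric(x), n)
  cfg <- list(n_patients = n, n_probes = as.integer(n_probes),
              occult_fractions = rec(occult_fractions),
              field_effect_flags = rep_len(as.logical(field_effect_flags), n),
              probe_noise_sd = probe_noise_sd,
              n_segments = as.integer(n_segments),
              cn_contamination = rec(cn_contamination),
              n_somatic_snvs = as.integer(n_somatic_snvs),
              adjacent_vaf_scale = rec(adjacent_vaf_scale),
              depth_mean = depth_mean, rna_depth_mean = rna_depth_mean,
              n_mrna_features = as.integer(n_mrna_features),
              n_mir_features = as.integer(n_mir_features),
              subtype_effect_log2 = subtype_effect_log2,
              affected_fraction = affected_fraction,
              p_active = p_active, mir_concordance = mir_concordance,
              survival_log_hr = survival_log_hr,
              baseline_hazard = baseline_hazard, censor_time = censor_time,
              seg_len_min = seg_len_min, seg_len_max = seg_len_max,
              germline_cnv = isTRUE(germline_cnv), seed = as.integer(seed))
  if (any(cfg$occult_fractions < 0 | cfg$occult_fractions > 1) ||
      any(cfg$cn_contamination < 0 | cfg$cn_contamination > 1) ||
      any(cfg$adjacent_vaf_scale < 0 | cfg$adjacent_vaf_scale > 1))
    fs_stopf("per-patient fractions must lie in [0, 1]")
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config: %d patients, %d probes, %d SNVs/patient, ",
                     "%d/%d expression features, seed %d>\n"),
              x$n_patients, x$n_probes, x$n_somatic_snvs,
              x$n_mrna_features, x$n_mir_features, x$seed))
  invisible(x)
}

patient_ids <- function(config)
  sprintf("P%03d", seq_len(config$n_patients))

probe_ids <- function(config)
  sprintf("cg%05d", seq_len(config$n_probes))

# probe architecture shared by all patients: first block hyper-methylated
# in tumor, second block hypo-methylated, remainder neutral
probe_blocks <- function(config) {
  n <- config$n_probes
  n_diff <- min(floor(n / 2), max(520L, floor(n / 3)))
  list(hyper = seq_len(n_diff),
       hypo = seq_len(n_diff) + n_diff,
       neutral = setdiff(seq_len(n), seq_len(2L * n_diff)))
}

#' Simulate one patient's methylation triplet
#'
#' Tumor betas are drawn so that the hyper block exceeds normal by at
#' least 0.2; the adjacent profile is the mixture
#' `f * tumor + (1 - f) * normal` plus Gaussian noise (clipped to \[0,1\]),
#' where `f` is the patient's occult fraction. A field-effect patient
#' instead has a random 10% probe subset shifted toward tumor by a fixed
#' offset (0.3, capped at the tumor-normal gap) — a sparse signature
#' distinct from global mixing.
#'
#' @param config a [sim_config()].
#' @param patient patient index (1-based).
#' @return list of beta vectors `tumor`, `normal`, `adjacent`, named by
#'   probe id.
#' @export
simulate_methylation_triplet <- function(config, patient) {
  set.seed(patient_seed(config$seed, patient * 7L + 1L))
  n <- config$n_probes
  blocks <- probe_blocks(config)
  normal <- numeric(n)
  tumor <- numeric(n)
  normal[blocks$hyper] <- stats::runif(length(blocks$hyper), 0.05, 0.25)
  tumor[blocks$hyper] <- pmin(1, normal[blocks$hyper] +
                                stats::runif(length(blocks$hyper), 0.2, 0.75))
  normal[blocks$hypo] <- stats::runif(length(blocks$hypo), 0.75, 0.95)
  tumor[blocks$hypo] <- pmax(0, normal[blocks$hypo] -
                               stats::runif(length(blocks$hypo), 0.2, 0.75))
  if (length(blocks$neutral)) {
    normal[blocks$neutral] <- stats::runif(length(blocks$neutral), 0.2, 0.8)
    tumor[blocks$neutral] <- pmin(1, pmax(0, normal[blocks$neutral] +
      stats::rnorm(length(blocks$neutral), 0, 0.02)))
  }
  f <- config$occult_fractions[patient]
  if (isTRUE(config$field_effect_flags[patient]) && f == 0) {
    adjacent <- normal
    idx <- sample.int(n, size = max(1L, round(0.10 * n)))
    gap <- tumor[idx] - normal[idx]
    adjacent[idx] <- normal[idx] + sign(gap) * pmin(0.3, abs(gap))
  } else {
    adjacent <- f * tumor + (1 - f) * normal
  }
  if (config$probe_noise_sd > 0)
    adjacent <- adjacent + stats::rnorm(n, 0, config$probe_noise_sd)
  adjacent <- pmin(1, pmax(0, adjacent))
  ids <- probe_ids(config)
  names(tumor) <- names(normal) <- names(adjacent) <- ids
  list(tumor = tumor, normal = normal, adjacent = adjacent)
}

empty_seg <- function() {
  data.frame(sample = character(), chrom = character(), start = numeric(),
             end = numeric(), seg_mean = numeric(), stringsAsFactors = FALSE)
}

#' Simulate one patient's copy-number segment triplet
#'
#' The tumor receives `n_segments` somatic alterations with |log2 ratio|
#' uniform in \[0.2, 1\]; each is copied into the adjacent profile with
#' probability `cn_contamination`, its log2 ratio attenuated by the
#' patient's `adjacent_vaf_scale` (a dilute occult clone shifts the
#' aggregate copy ratio proportionally). Blood carries no somatic events;
#' with `germline_cnv = TRUE` one germline CNV is injected into all three
#' profiles as a negative control for the blood-exclusion rule.
#'
#' @param config a [sim_config()].
#' @param patient patient index.
#' @return list of 0-based half-open segment data.frames `tumor`, `blood`,
#'   `adjacent`.
#' @export
simulate_segments <- function(config, patient) {
  set.seed(patient_seed(config$seed, patient * 7L + 2L))
  pid <- patient_ids(config)[patient]
  ns <- config$n_segments
  chrom <- as.character(sample.int(22L, ns, replace = TRUE))
  start <- floor(stats::runif(ns, 0, 1e8))
  len <- floor(stats::runif(ns, config$seg_len_min, config$seg_len_max))
  sgn <- sample(c(-1, 1), ns, replace = TRUE)
  mag <- stats::runif(ns, 0.2, 1.0)
  tumor <- data.frame(sample = rep(pid, ns), chrom = chrom, start = start,
                      end = start + len, seg_mean = sgn * mag,
                      stringsAsFactors = FALSE)
  copied <- stats::runif(ns) < config$cn_contamination[patient]
  adjacent <- tumor[copied, , drop = FALSE]
  adjacent$seg_mean <- adjacent$seg_mean * config$adjacent_vaf_scale[patient]
  blood <- empty_seg()
  if (config$germline_cnv) {
    germ <- data.frame(sample = pid, chrom = "7", start = 5e7,
                       end = 5e7 + 2e5, seg_mean = 0.5,
                       stringsAsFactors = FALSE)
    tumor <- rbind(tumor, germ)
    adjacent <- rbind(adjacent, germ)
    blood <- rbind(blood, germ)
  }
  ord <- function(d) {
    d <- d[order(d$chrom, d$start), , drop = FALSE]
    rownames(d) <- NULL
    d
  }
  list(tumor = ord(tumor), blood = ord(blood), adjacent = ord(adjacent))
}

gene_pool <- c("PIK3CA", "TP53", "GATA3", "MAP3K1", "CDH1",
               "MLL3", "PTEN", "AKT1", "RUNX1", "CBFB")

#' Simulate one patient's somatic SNV pileups
#'
#' Tumor VAFs are uniform in \[0.13, 0.60\] (the observed tumor range for
#' recurrent driver mutations); the adjacent-normal VAF is the tumor VAF
#' scaled by `adjacent_vaf_scale`. Read depths are Poisson, alt counts
#' binomial; blood alt reads arise only from a 0.001 sequencing error
#' rate. RNA evidence at each locus uses the adjacent VAF at
#' `rna_depth_mean` coverage.
#'
#' @param config a [sim_config()].
#' @param patient patient index.
#' @return a `variant_table` data.frame (one row per SNV).
#' @export
simulate_variants <- function(config, patient) {
  set.seed(patient_seed(config$seed, patient * 7L + 3L))
  nv <- config$n_somatic_snvs
  if (nv == 0) return(as_variant_table(empty_variants()))
  pid <- patient_ids(config)[patient]
  vaf <- stats::runif(nv, 0.13, 0.60)
  scale <- config$adjacent_vaf_scale[patient]
  depth <- function(mu) stats::rpois(nv, mu)
  td <- depth(config$depth_mean); bd <- depth(config$depth_mean)
  nd <- depth(config$depth_mean); rd <- depth(config$rna_depth_mean)
  t_alt <- stats::rbinom(nv, td, vaf)
  b_alt <- stats::rbinom(nv, bd, 0.001)
  n_alt <- stats::rbinom(nv, nd, vaf * scale)
  rna_alt <- stats::rbinom(nv, rd, vaf * scale)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, nv, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  df <- data.frame(patient = rep(pid, nv),
                   chrom = as.character(sample.int(22L, nv, replace = TRUE)),
                   pos = sample.int(1e8L, nv),
                   ref = ref, alt = alt,
                   t_ref = td - t_alt, t_alt = t_alt,
                   b_ref = bd - b_alt, b_alt = b_alt,
                   n_ref = nd - n_alt, n_alt = n_alt,
                   rna_ref = rd - rna_alt, rna_alt = rna_alt,
                   gene = sample(gene_pool, nv, replace = TRUE),
                   stringsAsFactors = FALSE)
  as_variant_table(df)
}

empty_variants <- function() {
  df <- data.frame(patient = character(), chrom = character(), pos = integer(),
                   ref = character(), alt = character(),
                   t_ref = integer(), t_alt = integer(),
                   b_ref = integer(), b_alt = integer(),
                   n_ref = integer(), n_alt = integer(),
                   rna_ref = integer(), rna_alt = integer(),
                   gene = character(), stringsAsFactors = FALSE)
  df
}

#' Simulate expression matrices, subtype labels, and survival
#'
#' Each patient is assigned the active subtype with probability
#' `p_active`; the first `affected_fraction` of features are shifted by
#' `subtype_effect_log2` (log2 scale) in active samples, for both mRNA and
#' miR matrices. The miR subtype label equals the mRNA label with
#' probability `mir_concordance`. Survival is exponential with hazard
#' `baseline_hazard * exp(survival_log_hr * active)`, administratively
#' censored at `censor_time` years.
#'
#' @param config a [sim_config()].
#' @return list with `mrna` and `mir` count [matrix_table()]s, character
#'   vectors `subtype` (mRNA truth) and `mir_subtype`, and a
#'   `clinical_table` data.frame.
#' @export
simulate_expression_and_survival <- function(config) {
  set.seed(patient_seed(config$seed, 0L) + 1L)
  n <- config$n_patients
  pids <- patient_ids(config)
  active <- stats::rbinom(n, 1, config$p_active) == 1
  mir_active <- ifelse(stats::runif(n) < config$mir_concordance,
                       active, !active)

  gen_matrix <- function(n_feat, lab_active, prefix) {
    n_aff <- max(1L, round(config$affected_fraction * n_feat))
    mu <- stats::runif(n_feat, 1, 9)          # baseline log2 abundance
    eff <- c(rep(config$subtype_effect_log2, n_aff),
             rep(0, n_feat - n_aff))
    logm <- matrix(mu, n_feat, n) +
      outer(eff, as.numeric(lab_active)) +
      matrix(stats::rnorm(n_feat * n, 0, 0.5), n_feat, n)
    counts <- matrix(stats::rpois(n_feat * n, 2^logm), n_feat, n)
    dimnames(counts) <- list(sprintf("%s%04d", prefix, seq_len(n_feat)), pids)
    matrix_table(counts, "count")
  }
  mrna <- gen_matrix(config$n_mrna_features, active, "gene")
  mir <- gen_matrix(config$n_mir_features, mir_active, "mir")

  rate <- config$baseline_hazard * exp(config$survival_log_hr * active)
  t_event <- stats::rexp(n, rate)
  event <- t_event <= config$censor_time
  time <- pmin(t_event, config$censor_time)
  stage <- sample(c("I", "II", "III/IV"), n, replace = TRUE,
                  prob = c(0.4, 0.45, 0.15))
  clinical <- data.frame(
    patient_id = pids,
    er_status = sample(c("positive", "negative"), n, replace = TRUE,
                       prob = c(0.75, 0.25)),
    age_decade = sample(clinical_levels$age_decade, n, replace = TRUE,
                        prob = c(0.05, 0.2, 0.3, 0.25, 0.2)),
    stage = stage,
    stage_raw = ifelse(stage == "III/IV",
                       sample(c("III", "IV"), n, replace = TRUE,
                              prob = c(0.75, 0.25)), stage),
    t_size = sample(clinical_levels$t_size, n, replace = TRUE,
                    prob = c(0.4, 0.4, 0.15, 0.05)),
    node_status = sample(c("negative", "positive"), n, replace = TRUE,
                         prob = c(0.55, 0.45)),
    tumor_subtype = sample(c("LumA", "LumB", "HER2", "Basal"), n,
                           replace = TRUE, prob = c(0.5, 0.2, 0.15, 0.15)),
    time_years = time, event = event, stringsAsFactors = FALSE)
  for (v in names(clinical_levels))
    clinical[[v]] <- factor(clinical[[v]], levels = clinical_levels[[v]])
  class(clinical) <- c("clinical_table", "data.frame")
  list(mrna = mrna, mir = mir,
       subtype = ifelse(active, "active", "inactive"),
       mir_subtype = ifelse(mir_active, "active", "inactive"),
       clinical = clinical)
}

#' Simulate a full cohort, optionally writing it to disk
#'
#' Runs all four per-assay simulators over the cohort and assembles the
#' cross-platform objects. With `out_dir` set, every input format of the
#' analysis stages is written (beta matrices, per-compartment SEG files,
#' variant TSV, count matrices, clinical TSV) together with `truth.tsv`
#' holding the generating parameters per patient, so recovery tests never
#' re-derive truth from the simulation code path.
#'
#' @param config a [sim_config()].
#' @param out_dir optional output directory.
#' @return list with elements `methylation` (tumor/normal/adjacent beta
#'   [matrix_table()]s), `segments` (per-patient triplets), `variants`
#'   (one `variant_table`), `expression` (see
#'   [simulate_expression_and_survival()]), and `truth` (data.frame).
#' @export
simulate_cohort <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  pids <- patient_ids(config)
  meth <- lapply(seq_len(config$n_patients),
                 function(i) simulate_methylation_triplet(config, i))
  as_mt <- function(part) {
    m <- vapply(meth, `[[`, numeric(config$n_probes), part)
    dimnames(m) <- list(probe_ids(config), pids)
    matrix_table(m, "beta")
  }
  methylation <- list(tumor = as_mt("tumor"), normal = as_mt("normal"),
                      adjacent = as_mt("adjacent"))
  segments <- lapply(seq_len(config$n_patients),
                     function(i) simulate_segments(config, i))
  names(segments) <- pids
  variants <- do.call(rbind, lapply(seq_len(config$n_patients),
                                    function(i) simulate_variants(config, i)))
  variants <- as_variant_table(variants)
  expression <- simulate_expression_and_survival(config)
  truth <- data.frame(patient_id = pids,
                      occult_fraction = config$occult_fractions,
                      field_effect = config$field_effect_flags,
                      cn_contamination = config$cn_contamination,
                      adjacent_vaf_scale = config$adjacent_vaf_scale,
                      subtype = expression$subtype,
                      mir_subtype = expression$mir_subtype,
                      stringsAsFactors = FALSE)
  cohort <- list(methylation = methylation, segments = segments,
                 variants = variants, expression = expression, truth = truth)
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  write_matrix(cohort$methylation$tumor, p("methylation_tumor.tsv"), "probe_id")
  write_matrix(cohort$methylation$normal, p("methylation_normal.tsv"), "probe_id")
  write_matrix(cohort$methylation$adjacent, p("methylation_adjacent.tsv"), "probe_id")
  for (part in c("tumor", "blood", "adjacent")) {
    seg <- do.call(rbind, lapply(cohort$segments, `[[`, part))
    write_seg(seg, p(sprintf("segments_%s.seg", part)))
  }
  write_variants(cohort$variants, p("variants.tsv"))
  write_matrix(cohort$expression$mrna, p("mrna_counts.tsv"), "gene_id")
  write_matrix(cohort$expression$mir, p("mir_counts.tsv"), "mir_id")
  write_clinical(cohort$expression$clinical, p("clinical.tsv"))
  utils::write.table(cohort$truth, p("truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}
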