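# shared fixture builders and independent oracles

make_seg <- function(sample = "S1", chrom = "1", start = 0, end = 100,
                     seg_mean = 0.5) {
  data.frame(sample = sample, chrom = as.character(chrom),
             start = start, end = end, seg_mean = seg_mean,
             stringsAsFactors = FALSE)
}

random_profile <- function(n_seg, max_coord = 1000, sample = "S1") {
  if (n_seg == 0) return(make_seg()[0, ])
  start <- sample.int(max_coord - 2, n_seg, replace = TRUE)
  len <- sample.int(50, n_seg, replace = TRUE)
  make_seg(sample = sample,
           chrom = as.character(sample.int(3, n_seg, replace = TRUE)),
           start = start, end = pmin(start + len, max_coord),
           seg_mean = round(stats::runif(n_seg, -1, 1), 3))
}

# per-base brute-force segment matcher applying the same predicates as
# match_adjacent_to_tumor, computed by enumerating integer basepairs
oracle_match <- function(adjacent, tumor, blood = NULL, min_ro = 0.5,
                         min_abs_log2 = 0.1) {
  bases <- function(s) paste(s$chrom,
                             seq(s$start + 1, s$end), sep = ":")
  shared_bases <- function(a, b) length(intersect(bases(a), bases(b)))
  rows <- list()
  for (i in seq_len(nrow(adjacent))) {
    a <- adjacent[i, ]
    if (abs(a$seg_mean) <= min_abs_log2) next
    vetoed <- FALSE
    if (!is.null(blood) && nrow(blood)) for (j in seq_len(nrow(blood))) {
      b <- blood[j, ]
      if (abs(b$seg_mean) > min_abs_log2 && shared_bases(a, b) >= 1)
        vetoed <- TRUE
    }
    if (vetoed) next
    best <- NULL
    for (j in seq_len(nrow(tumor))) {
      t <- tumor[j, ]
      if (abs(t$seg_mean) <= min_abs_log2) next
      if (sign(t$seg_mean) != sign(a$seg_mean)) next
      ov <- shared_bases(a, t)
      if (ov / (a$end - a$start) < min_ro) next
      if (ov / (t$end - t$start) < min_ro) next
      cand <- list(j = j, ov = ov, len = t$end - t$start, start = t$start)
      if (is.null(best) || cand$ov > best$ov ||
          (cand$ov == best$ov && cand$len > best$len) ||
          (cand$ov == best$ov && cand$len == best$len &&
           cand$start < best$start))
        best <- cand
    }
    if (!is.null(best))
      rows[[length(rows) + 1]] <- data.frame(adj_idx = i,
                                             tumor_idx = best$j,
                                             overlap_bp = best$ov)
  }
  if (!length(rows))
    return(data.frame(adj_idx = integer(), tumor_idx = integer(),
                      overlap_bp = numeric()))
  do.call(rbind, rows)
}

# closed-form simple linear regression
oracle_ols <- function(x, y) {
  xb <- mean(x); yb <- mean(y)
  slope <- sum((x - xb) * (y - yb)) / sum((x - xb)^2)
  intercept <- yb - slope * xb
  rss <- sum((y - intercept - slope * x)^2)
  list(slope = slope, intercept = intercept,
       residual_se = sqrt(rss / (length(x) - 2)))
}

# two-sided Fisher exact p by direct hypergeometric enumeration
oracle_fisher <- function(a, b, c, d) {
  m1 <- a + c; m2 <- b + d; k <- a + b
  support <- max(0, k - m2):min(k, m1)
  dens <- dhyper(support, m1, m2, k)
  obs <- dhyper(a, m1, m2, k)
  sum(dens[dens <= obs * (1 + 1e-7)])
}

# textbook silhouette widths from a dissimilarity matrix
oracle_silhouette <- function(d, lab) {
  vapply(seq_len(nrow(d)), function(i) {
    own <- setdiff(which(lab == lab[i]), i)
    if (!length(own)) return(0)
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(unique(lab), lab[i]),
                    function(cl) mean(d[i, lab == cl]), numeric(1)))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
}

# hand-written burden truth from detected count and VAF>1% fraction
oracle_burden <- function(n_detected, frac) {
  if (n_detected < 2) "none"
  else if (frac >= 0.5) "high"
  else if (frac <= 0.1) "low"
  else "moderate"
}

# build a variant table with prescribed adjacent detection pattern:
# n_det variants with >= 2 adjacent alt reads of which k_high have
# VAF > 1%, plus n_undetected with no adjacent alt reads
variants_with_burden <- function(n_det, k_high, n_undetected = 1) {
  n <- n_det + n_undetected
  depth <- 1000L
  n_alt <- c(rep(0L, n_undetected),
             c(rep(25L, k_high), rep(5L, n_det - k_high)))   # VAF 2.5% / 0.5%
  df <- data.frame(patient = "P1", chrom = "1", pos = seq_len(n),
                   ref = "A", alt = "C",
                   t_ref = 600L, t_alt = 400L,
                   b_ref = depth, b_alt = 0L,
                   n_ref = depth - n_alt, n_alt = n_alt,
                   rna_ref = 50L, rna_alt = 0L,
                   stringsAsFactors = FALSE)
  fieldscape:::as_variant_table(df)
}

small_clinical <- function(n, time, event, er = "positive",
                           stage = "I", stage_raw = NULL) {
  d <- data.frame(patient_id = sprintf("P%03d", seq_len(n)),
                  er_status = factor(rep_len(er, n),
                                     levels = c("positive", "negative", "unknown")),
                  age_decade = factor(rep_len(c("40-49", "50-59"), n),
                                      levels = c("<40", "40-49", "50-59",
                                                 "60-69", "70+")),
                  stage = factor(rep_len(stage, n),
                                 levels = c("I", "II", "III/IV")),
                  t_size = factor(rep_len(c("T1", "T2"), n),
                                  levels = paste0("T", 1:4)),
                  node_status = factor(rep_len(c("negative", "positive"), n),
                                       levels = c("negative", "positive")),
                  tumor_subtype = factor(rep_len(c("LumA", "LumB"), n),
                                         levels = c("LumA", "LumB", "HER2",
                                                    "Basal", "unknown")),
                  time_years = rep_len(time, n),
                  event = rep_len(event, n), stringsAsFactors = FALSE)
  if (!is.null(stage_raw)) d$stage_raw <- rep_len(stage_raw, n)
  d
}
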