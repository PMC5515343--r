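#' Reciprocal overlap between two segments
#'
#' For half-open segments on the same chromosome, the overlap in
#' basepairs and the fraction of each segment's own length it covers.
#' Segments on different chromosomes overlap by 0.
#'
#' @param a,b single-row segment data.frames (or lists) with `chrom`,
#'   `start`, `end`.
#' @return list `overlap_bp`, `frac_a`, `frac_b`.
#' @export
reciprocal_overlap <- function(a, b) {
  if (normalize_chrom(a$chrom) != normalize_chrom(b$chrom))
    return(list(overlap_bp = 0, frac_a = 0, frac_b = 0))
  ov <- max(0, min(a$end, b$end) - max(a$start, b$start))
  list(overlap_bp = ov,
       frac_a = ov / (a$end - a$start),
       frac_b = ov / (b$end - b$start))
}

#' Match adjacent-normal segments to tumor segments
#'
#' A candidate adjacent segment must exceed the amplitude filter
#' (|log2 ratio| > `min_abs_log2`). It matches a tumor segment (also past
#' the filter) on the same chromosome when the reciprocal overlap is at
#' least `min_ro` of both segment lengths and, with
#' `require_sign_concordance`, the two log2 ratios share a sign. A
#' candidate is vetoed when any blood segment past the amplitude filter
#' overlaps it by at least one basepair (germline CNVs); blood segments at
#' near-neutral log2 — the genome-tiling remainder in typical SEG exports —
#' never veto. Each adjacent segment takes at most one tumor partner:
#' largest overlap, ties to the longer, then leftmost, tumor segment.
#'
#' @param adjacent,tumor,blood segment data.frames (0-based half-open);
#'   `blood = NULL` for tumor/adjacent pairs.
#' @param min_ro reciprocal-overlap fraction (default 0.5).
#' @param min_abs_log2 amplitude filter (default 0.1, strict).
#' @param require_sign_concordance gains match gains, losses match losses.
#' @return data.frame of matches: adjacent index/coords, tumor index,
#'   `overlap_bp`.
#' @export
match_adjacent_to_tumor <- function(adjacent, tumor, blood = NULL,
                                    min_ro = 0.5, min_abs_log2 = 0.1,
                                    require_sign_concordance = TRUE) {
  empty <- data.frame(adj_idx = integer(), tumor_idx = integer(),
                      chrom = character(), start = numeric(), end = numeric(),
                      overlap_bp = numeric(), stringsAsFactors = FALSE)
  if (is.null(adjacent) || !nrow(adjacent)) return(empty)
  adjacent$chrom <- normalize_chrom(adjacent$chrom)
  cand <- which(abs(adjacent$seg_mean) > min_abs_log2)
  if (!length(cand) || is.null(tumor) || !nrow(tumor)) return(empty)
  tumor$chrom <- normalize_chrom(tumor$chrom)
  tum_map <- which(abs(tumor$seg_mean) > min_abs_log2)
  tum <- tumor[tum_map, , drop = FALSE]
  if (!nrow(tum)) return(empty)
  bld <- if (!is.null(blood) && nrow(blood)) {
    blood$chrom <- normalize_chrom(blood$chrom)
    blood[abs(blood$seg_mean) > min_abs_log2, , drop = FALSE]
  } else NULL
  rows <- lapply(cand, function(i) {
    a <- adjacent[i, ]
    if (!is.null(bld) && nrow(bld)) {
      ovb <- pmax(0, pmin(a$end, bld$end) - pmax(a$start, bld$start))
      if (any(bld$chrom == a$chrom & ovb >= 1)) return(NULL)
    }
    same <- tum$chrom == a$chrom
    if (require_sign_concordance) same <- same & sign(tum$seg_mean) == sign(a$seg_mean)
    if (!any(same)) return(NULL)
    tt <- tum[same, , drop = FALSE]
    ov <- pmax(0, pmin(a$end, tt$end) - pmax(a$start, tt$start))
    ok <- ov / (a$end - a$start) >= min_ro & ov / (tt$end - tt$start) >= min_ro
    if (!any(ok)) return(NULL)
    tt <- tt[ok, , drop = FALSE]; ov <- ov[ok]
    # one-to-one: largest overlap, then longer tumor segment, then leftmost
    best <- order(-ov, -(tt$end - tt$start), tt$start)[1]
    data.frame(adj_idx = i,
               tumor_idx = which(same)[ok][best] + 0L,
               chrom = a$chrom, start = a$start, end = a$end,
               overlap_bp = ov[best], stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  # map tumor_idx back to row numbers of the original tumor frame
  out$tumor_idx <- tum_map[out$tumor_idx]
  rownames(out) <- NULL
  out
}

#' Tier a sample's copy-number evidence of tumor
#'
#' Sums the matched overlap basepairs and applies the shared-alteration
#' tiers. Triplets (blood available): > 100,000 bp shared is evidence of
#' tumor, 1,000-99,999 bp is small evidence, less is normal. Pairs (no
#' blood to exclude germline events): > 100,000 bp is only likely
#' evidence, anything else normal. Exactly 100,000 bp falls in neither
#' printed range and is assigned to the evidence tier.
#'
#' @param matches data.frame from [match_adjacent_to_tumor()].
#' @param mode `"triplet"` or `"pair"`.
#' @param sample_id carried into the call.
#' @param evidence_bp,small_bp tier thresholds in bp.
#' @return a `cn_call`: list with `sample_id`, `shared_bp`,
#'   `n_matched_segments`, `mode`, `category`.
#' @export
classify_cn <- function(matches, mode = c("triplet", "pair"),
                        sample_id = NA_character_,
                        evidence_bp = 1e5, small_bp = 1e3) {
  mode <- match.arg(mode)
  shared <- if (nrow(matches)) sum(matches$overlap_bp) else 0
  category <- if (mode == "triplet") {
    if (shared >= evidence_bp) "evidence_of_tumor"
    else if (shared >= small_bp) "small_evidence"
    else "normal"
  } else {
    if (shared >= evidence_bp) "likely_evidence" else "normal"
  }
  out <- list(sample_id = sample_id, shared_bp = shared,
              n_matched_segments = nrow(matches), mode = mode,
              category = category)
  class(out) <- "cn_call"
  out
}

#' @export
print.cn_call <- function(x, ...) {
  cat(sprintf("<cn_call%s: %s bp shared over %d segment(s), %s mode -> %s>\n",
              if (is.na(x$sample_id)) "" else paste0(" ", x$sample_id),
              format(x$shared_bp, big.mark = ","), x$n_matched_segments,
              x$mode, x$category))
  invisible(x)
}

#' Copy-number screen over a cohort of segment triplets
#'
#' @param segments named list (per patient) of lists with `tumor`,
#'   `adjacent`, and optionally `blood` segment data.frames; patients with
#'   an empty/absent blood profile but `mode = "triplet"` still use
#'   triplet tiers (an empty blood profile is an observed blood with no
#'   events). Use `mode = "pair"` when blood was never assayed.
#' @param mode `"triplet"` or `"pair"`; with `"pair"` any supplied blood
#'   profile is an error.
#' @param ... passed to [match_adjacent_to_tumor()].
#' @return data.frame, one row per patient (shared_bp, n_matches, mode,
#'   category).
#' @export
cnv_screen <- function(segments, mode = c("triplet", "pair"), ...) {
  mode <- match.arg(mode)
  rows <- lapply(names(segments), function(pid) {
    trip <- segments[[pid]]
    if (mode == "pair" && !is.null(trip$blood) && nrow(trip$blood))
      fs_stopf("pair mode but blood profile provided for %s", pid)
    m <- match_adjacent_to_tumor(trip$adjacent, trip$tumor,
                                 if (mode == "triplet") trip$blood else NULL,
                                 ...)
    call <- classify_cn(m, mode, sample_id = pid)
    data.frame(sample_id = pid, shared_bp = call$shared_bp,
               n_matches = call$n_matched_segments, mode = mode,
               category = call$category, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
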