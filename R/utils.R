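`%||%` <- function(x, y) if (is.null(x)) y else x

#' @keywords internal
#' @noRd
fs_stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

fs_warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Deterministic per-patient substream seed derived from a master seed.
# Knuth multiplicative hash keeps seeds < 2^31 and decorrelates neighbours,
# so extending a cohort never perturbs existing patients.
patient_seed <- function(master_seed, patient_index) {
  stopifnot(is.numeric(master_seed), is.numeric(patient_index))
  as.integer((master_seed * 2654435761 + patient_index * 40503) %% 2147483647L)
}

# strip leading "chr"; sex chromosomes stay strings
normalize_chrom <- function(chrom) sub("^chr", "", as.character(chrom))

assert_finite <- function(x, what) {
  if (any(!is.finite(x))) fs_stopf("non-finite values in %s", what)
  invisible(x)
}
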