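# Internal helpers shared across modules.

# Dosages are ALT-allele counts in {0, 1, 2, NA}.
check_dosage <- function(x, arg = "dosage") {
  bad <- !is.na(x) & !(x %in% c(0, 1, 2))
  if (any(bad)) {
    abort(sprintf(
      "%s must be 0, 1, 2 or NA; offending values: %s",
      arg, paste(unique(x[bad]), collapse = ", ")
    ))
  }
  as.integer(x)
}

check_status <- function(x) {
  if (!all(x %in% c(0L, 1L))) {
    abort("status must be coded 0 (control) / 1 (case) with no missing values")
  }
  as.integer(x)
}

# Derive a stream-specific 32-bit seed from a master seed, so pipeline stages
# can be rerun independently yet reproducibly.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.double(seed) * 48271 + h) %% 2147483647)
}

# Genotype dosage columns of a cohort are those named in attr or matching the
# supplied variant ids.
variant_cols <- function(cohort, variants) {
  ids <- if (is.character(variants)) variants else variants$variant_id
  missing <- setdiff(ids, names(cohort))
  if (length(missing) > 0) {
    abort(paste0("variants absent from cohort: ", paste(missing, collapse = ", ")))
  }
  ids
}
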