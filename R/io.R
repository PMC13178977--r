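# Reading genotypes and phenotypes and joining them into the analysis frame.
# Genotype coding is ALT-allele dosage at ingest; risk-allele orientation is
# applied downstream (see orient_to_risk()), never at I/O.

phenotype_vocab <- list(
  status            = c("control", "case", "0", "1"),
  sex               = c("boy", "girl"),
  age_group         = c("7-8", "11-14", "15-18"),
  maternal_edu      = c("high_school_or_below", "junior_college_or_above"),
  paternal_edu      = c("high_school_or_below", "junior_college_or_above"),
  income            = c("low", "medium", "high"),
  physical_activity = c("adequate", "inadequate"),
  sleep             = c("adequate", "inadequate")
)

#' Read biallelic genotypes as ALT-allele dosages
#'
#' Reads either a VCF (4.x, `GT` field) or a wide dosage TSV (first column
#' `sample_id`, one column per variant, values 0/1/2/NA) into a dosage table
#' plus per-variant summaries. Dosage is the count of ALT alleles; missing and
#' half-missing genotype calls (`./.`, `0/.`) become `NA`. Phased (`|`) and
#' unphased (`/`) separators are treated identically.
#'
#' @param path Path to the genotype file.
#' @param format `"vcf"` or `"dosage-tsv"`.
#' @return A list with `dosages` (tibble: `sample_id` plus one integer column
#'   per variant) and `variants` (tibble: `variant_id`, `ref_allele`,
#'   `alt_allele`, `maf`, `call_rate`). Minor-allele frequency and call rate
#'   are computed from the data.
#' @export
read_genotypes <- function(path, format = c("vcf", "dosage-tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_tsv(path)
}

read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT %||% "")
  if (any(multi)) {
    abort(paste0(
      "multi-allelic records are not supported: ",
      paste(fix$ID[multi], collapse = ", ")
    ))
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  # rows = variants, cols = samples; normalise separators and count ALT alleles
  dose_row <- function(g) {
    g <- gsub("|", "/", g, fixed = TRUE)
    alleles <- strsplit(g, "/", fixed = TRUE)
    vapply(alleles, function(a) {
      if (length(a) != 2 || anyNA(a) || any(a == ".")) return(NA_integer_)
      sum(a == "1")
    }, integer(1))
  }
  dos <- t(apply(gt, 1, dose_row))
  if (nrow(gt) == 1) dos <- matrix(dos, nrow = 1, dimnames = dimnames(gt))
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0("var", which(is.na(ids) | ids == "."))
  dosages <- tibble(sample_id = colnames(gt)) %>%
    dplyr::bind_cols(as_tibble(setNames(
      lapply(seq_along(ids), function(i) as.integer(dos[i, ])), ids
    )))
  variants <- tibble(
    variant_id = ids,
    ref_allele = fix$REF,
    alt_allele = fix$ALT
  ) %>% add_variant_summaries(dosages)
  list(dosages = dosages, variants = variants)
}

read_genotypes_tsv <- function(path) {
  dosages <- readr::read_tsv(path, show_col_types = FALSE, na = c("NA", ""))
  if (names(dosages)[1] != "sample_id") {
    abort("dosage TSV must have 'sample_id' as its first column")
  }
  for (v in names(dosages)[-1]) {
    dosages[[v]] <- check_dosage(dosages[[v]], arg = v)
  }
  dosages$sample_id <- as.character(dosages$sample_id)
  variants <- tibble(
    variant_id = names(dosages)[-1],
    ref_allele = NA_character_,
    alt_allele = NA_character_
  ) %>% add_variant_summaries(dosages)
  list(dosages = dosages, variants = variants)
}

add_variant_summaries <- function(variants, dosages) {
  variants$call_rate <- vapply(
    variants$variant_id,
    function(v) mean(!is.na(dosages[[v]])),
    numeric(1), USE.NAMES = FALSE
  )
  variants$maf <- vapply(variants$variant_id, function(v) {
    d <- dosages[[v]]
    d <- d[!is.na(d)]
    if (length(d) == 0) return(NA_real_)
    f <- sum(d) / (2 * length(d))
    min(f, 1 - f)
  }, numeric(1), USE.NAMES = FALSE)
  variants
}

#' Read the per-sample phenotype and covariate table
#'
#' Expects a TSV with header columns `sample_id`, `status` and any of `sex`,
#' `age_group`, `school`, `maternal_edu`, `paternal_edu`, `income`,
#' `physical_activity`, `sleep`. `status` may be coded `case`/`control` or
#' `1`/`0`. Categorical values are validated against the declared vocabulary;
#' empty lifestyle fields become `NA` and the row is retained.
#'
#' @param path Path to the phenotype TSV.
#' @return A tibble with `status` recoded to integer 0/1.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  ph <- readr::read_tsv(
    path,
    show_col_types = FALSE, na = c("NA", ""),
    col_types = readr::cols(.default = readr::col_character())
  )
  if (!all(c("sample_id", "status") %in% names(ph))) {
    abort("phenotype file must contain 'sample_id' and 'status' columns")
  }
  if (anyNA(ph$status)) abort("missing status values are not allowed")
  dup <- ph$sample_id[duplicated(ph$sample_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate sample_id: ", paste(unique(dup), collapse = ", ")))
  }
  for (col in intersect(names(ph), names(phenotype_vocab))) {
    vals <- ph[[col]][!is.na(ph[[col]])]
    bad <- setdiff(unique(vals), phenotype_vocab[[col]])
    if (length(bad) > 0) {
      abort(sprintf(
        "unknown %s level(s): %s (expected one of %s)",
        col, paste(bad, collapse = ", "),
        paste(phenotype_vocab[[col]], collapse = ", ")
      ))
    }
  }
  ph$status <- as.integer(ph$status %in% c("case", "1"))
  ph
}

#' Join phenotypes and genotype dosages into one analysis frame
#'
#' Inner join on `sample_id`. Counts of samples dropped from either side are
#' reported as a message and attached as the `"dropped"` attribute.
#'
#' @param phenotypes Tibble from [read_phenotypes()].
#' @param dosages Dosage tibble from [read_genotypes()].
#' @param variants Optional variant tibble; if supplied it is attached as the
#'   `"variants"` attribute of the result.
#' @return The joined cohort tibble (phenotype columns then dosage columns).
#' @export
join_cohort <- function(phenotypes, dosages, variants = NULL) {
  common <- intersect(phenotypes$sample_id, dosages$sample_id)
  if (length(common) == 0) abort("no overlapping sample_id between phenotypes and genotypes")
  dropped <- c(
    phenotypes = nrow(phenotypes) - length(common),
    genotypes  = nrow(dosages) - length(common)
  )
  if (sum(dropped) > 0) {
    message(sprintf(
      "join_cohort: dropped %d phenotype-only and %d genotype-only sample(s)",
      dropped[["phenotypes"]], dropped[["genotypes"]]
    ))
  }
  cohort <- dplyr::inner_join(phenotypes, dosages, by = "sample_id")
  cohort$status <- check_status(cohort$status)
  attr(cohort, "dropped") <- dropped
  if (!is.null(variants)) attr(cohort, "variants") <- variants
  cohort
}

#' Write and re-read a cohort as TSV
#'
#' Round-trip helpers: all fields survive a write/read cycle bit-identically.
#'
#' @param cohort Cohort tibble.
#' @param path Output path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` the tibble.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_tsv(cohort, path, na = "NA")
  invisible(path)
}

#' @rdname write_cohort
#' @param variant_ids Character vector of columns to read as integer dosages.
#' @export
read_cohort <- function(path, variant_ids = character()) {
  ct <- readr::cols(.default = readr::col_character())
  cohort <- readr::read_tsv(path, show_col_types = FALSE, na = "NA", col_types = ct)
  cohort$status <- as.integer(cohort$status)
  for (v in intersect(variant_ids, names(cohort))) {
    cohort[[v]] <- as.integer(cohort[[v]])
  }
  cohort
}
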