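# Orchestration: run the full analysis from a config (list or YAML file),
# writing one TSV per stage plus a run log. Stage order: QC -> single-locus
# association -> CART -> GRS -> interaction.

#' Assemble a pipeline configuration
#'
#' @param genotypes Path to the genotype file.
#' @param phenotypes Path to the phenotype TSV.
#' @param format Genotype format (`"vcf"` or `"dosage-tsv"`).
#' @param variant_meta Tibble with `variant_id`, `risk_allele` (and
#'   optionally `gene_label`) declaring the designated risk alleles.
#' @param out_dir Output directory for the stage TSVs and run log.
#' @param stages Character subset of
#'   `c("qc", "association", "cart", "grs", "interaction")`.
#' @param covariates Adjustment covariates.
#' @param B_permutation,B_bootstrap Resampling sizes.
#' @param seed Master seed; per-stage seeds are derived from it.
#' @return A `grsxe_config` list.
#' @export
pipeline_config <- function(genotypes, phenotypes, format = "vcf",
                            variant_meta = NULL,
                            out_dir = ".",
                            stages = c("qc", "association", "cart", "grs",
                                       "interaction"),
                            covariates = c("age_group", "sex", "maternal_edu",
                                           "paternal_edu", "income"),
                            B_permutation = 1000L, B_bootstrap = 1000L,
                            seed = 1L) {
  structure(
    list(genotypes = genotypes, phenotypes = phenotypes, format = format,
         variant_meta = variant_meta, out_dir = out_dir, stages = stages,
         covariates = covariates, B_permutation = as.integer(B_permutation),
         B_bootstrap = as.integer(B_bootstrap), seed = as.integer(seed)),
    class = "grsxe_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with the fields of [pipeline_config()];
#'   `variant_meta` as a list of `{variant_id, risk_allele, gene_label}`
#'   records.
#' @return A `grsxe_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  vm <- NULL
  if (!is.null(raw$variant_meta)) {
    vm <- dplyr::bind_rows(lapply(raw$variant_meta, as_tibble))
  }
  pipeline_config(
    genotypes = raw$genotypes, phenotypes = raw$phenotypes,
    format = raw$format %||% "vcf", variant_meta = vm,
    out_dir = raw$out_dir %||% ".",
    stages = raw$stages %||% c("qc", "association", "cart", "grs", "interaction"),
    covariates = raw$covariates %||% c("age_group", "sex", "maternal_edu",
                                       "paternal_edu", "income"),
    B_permutation = raw$B_permutation %||% 1000L,
    B_bootstrap = raw$B_bootstrap %||% 1000L,
    seed = raw$seed %||% 1L
  )
}

#' Run the full pipeline
#'
#' Reads and joins the inputs, then runs the enabled stages in order,
#' writing `qc.tsv`, `association.tsv`, `cart.tsv`, `grs.tsv`,
#' `interaction.tsv` and `run_log.tsv` under `out_dir`. "Important variants"
#' feeding the GRS stage are the union of variants significant after
#' permutation correction (dominant or additive model, p < 0.05) and the
#' variants on the root path of the highest-risk CART terminal node; GRS
#' weights are the additive-model log-ORs re-estimated from this cohort.
#'
#' @param config A `grsxe_config` (or path to a YAML config).
#' @return Invisible list of the per-stage result objects.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "grsxe_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- list()
  note <- function(stage, what, value) {
    log[[length(log) + 1]] <<- tibble(stage = stage, key = what,
                                      value = as.character(value))
  }

  geno <- read_genotypes(config$genotypes, format = config$format)
  pheno <- read_phenotypes(config$phenotypes)
  variants <- geno$variants
  if (!is.null(config$variant_meta)) {
    variants <- dplyr::left_join(
      variants,
      dplyr::select(config$variant_meta, dplyr::any_of(c(
        "variant_id", "risk_allele", "gene_label"))),
      by = "variant_id"
    )
  }
  cohort <- suppressMessages(join_cohort(pheno, geno$dosages, variants))
  note("input", "n_joined", nrow(cohort))
  note("input", "n_cases", sum(cohort$status == 1))
  note("input", "n_controls", sum(cohort$status == 0))
  note("input", "seed", config$seed)
  dropped <- attr(cohort, "dropped")
  note("input", "dropped_phenotypes", dropped[["phenotypes"]])
  note("input", "dropped_genotypes", dropped[["genotypes"]])

  results <- list()
  ids <- variants$variant_id

  if ("qc" %in% config$stages) {
    qc <- qc_report(cohort, ids, B = config$B_permutation,
                    seed = derive_seed(config$seed, "qc"))
    readr::write_tsv(qc, file.path(config$out_dir, "qc.tsv"))
    results$qc <- qc
    note("qc", "n_variants", nrow(qc))
  }

  assoc <- NULL
  if (any(c("association", "grs", "interaction") %in% config$stages)) {
    assoc <- association_scan(
      cohort, variants, B = config$B_permutation,
      covariates = config$covariates,
      seed = derive_seed(config$seed, "assoc")
    )
    if ("association" %in% config$stages) {
      readr::write_tsv(assoc, file.path(config$out_dir, "association.tsv"))
      results$association <- assoc
    }
  }

  tree <- NULL
  if (any(c("cart", "grs", "interaction") %in% config$stages)) {
    tree <- grow_tree(cohort, ids)
    cv <- cross_validate(cohort, ids, seed = derive_seed(config$seed, "cv"))
    node_or <- terminal_node_or(tree, cohort, covariates = config$covariates)
    if ("cart" %in% config$stages) {
      readr::write_tsv(node_or, file.path(config$out_dir, "cart.tsv"))
      results$cart <- list(tree = tree, cv_misclassification = cv,
                           terminal = node_or)
      note("cart", "n_terminal", sum(tree$nodes$is_terminal))
      note("cart", "cv_misclassification", sprintf("%.4f", cv))
    }
  }

  important <- character()
  if (!is.null(assoc) && !is.null(tree)) {
    sig <- assoc %>%
      dplyr::filter(.data$model %in% c("dominant", "additive"),
                    !is.na(.data$p_permutation), .data$p_permutation < 0.05)
    term <- dplyr::filter(tree$nodes, .data$is_terminal)
    prop <- term$n_cases / (term$n_cases + term$n_controls)
    top <- term$node_id[order(-prop, term$node_id)][1]
    important <- union(unique(sig$variant_id), root_path_variants(tree, top))
    note("grs", "important_variants", paste(important, collapse = ","))
  }

  if (any(c("grs", "interaction") %in% config$stages)) {
    if (length(important) == 0) {
      abort("grs stage: no important variants identified")
    }
    weights <- grs_weights_from_fit(cohort, variants, important,
                                    covariates = config$covariates)
    profiles <- compute_grs(cohort, weights)
    note("grs", "n_incomplete", sum(!profiles$complete))
    if ("grs" %in% config$stages) {
      grs_tab <- dplyr::bind_rows(
        grs_association(cohort, profiles, "unweighted", "three_level",
                        covariates = config$covariates),
        grs_association(cohort, profiles, "unweighted", "high_vs_rest",
                        covariates = config$covariates),
        grs_association(cohort, profiles, "unweighted", "per_unit",
                        covariates = config$covariates),
        grs_association(cohort, profiles, "weighted", "three_level",
                        covariates = config$covariates),
        grs_association(cohort, profiles, "weighted", "high_vs_rest",
                        covariates = config$covariates)
      )
      readr::write_tsv(grs_tab, file.path(config$out_dir, "grs.tsv"))
      results$grs <- list(weights = weights, profiles = profiles,
                          association = grs_tab)
    }
    if ("interaction" %in% config$stages) {
      inter <- purrr::map(c("sleep", "physical_activity"), function(exp) {
        purrr::map(c("unweighted", "weighted"), function(sc) {
          high <- categorize_grs(profiles[[sc]]) == "high"
          bootstrap_interaction(
            cohort, high, exp, covariates = config$covariates,
            B = config$B_bootstrap,
            seed = derive_seed(config$seed, paste0("boot", sc, exp))
          )
        }) %>% setNames(c("unweighted", "weighted"))
      }) %>% setNames(c("sleep", "physical_activity"))
      inter_tab <- purrr::map_dfr(names(inter), function(exp) {
        purrr::map_dfr(names(inter[[exp]]), function(sc) {
          dplyr::mutate(tidy(inter[[exp]][[sc]]), exposure = exp, score = sc,
                        .before = 1)
        })
      })
      readr::write_tsv(inter_tab, file.path(config$out_dir, "interaction.tsv"))
      results$interaction <- inter
      note("interaction", "B_bootstrap", config$B_bootstrap)
    }
  }

  readr::write_tsv(dplyr::bind_rows(log), file.path(config$out_dir, "run_log.tsv"))
  invisible(results)
}

# Variants on the split path from the root to `node_id`.
root_path_variants <- function(tree, node_id) {
  path <- character()
  id <- node_id
  while (id > 1) {
    parent <- id %/% 2L
    row <- tree$nodes[tree$nodes$node_id == parent, ]
    path <- c(path, row$split_variant)
    id <- parent
  }
  unique(rev(path))
}

# Re-estimate per-allele (additive, adjusted) log-ORs as GRS weights;
# negative estimates flip the risk allele so betas stay non-negative.
grs_weights_from_fit <- function(cohort, variants, important,
                                 covariates = c("age_group", "sex",
                                                "maternal_edu", "paternal_edu",
                                                "income")) {
  covm <- covariate_matrix(cohort, covariates)
  purrr::map_dfr(important, function(v) {
    vi <- variants[variants$variant_id == v, ]
    risk <- if (!is.null(vi$risk_allele) && !is.na(vi$risk_allele)) {
      vi$risk_allele
    } else vi$alt_allele
    d <- orient_to_risk(cohort[[v]], dplyr::mutate(vi, risk_allele = risk))
    X <- cbind(additive = as.numeric(d), covm)
    keep <- stats::complete.cases(X)
    fit <- fit_logistic(X[keep, , drop = FALSE], cohort$status[keep])
    beta <- fit$coefficients[["additive"]]
    if (beta < 0) {  # flip orientation so the designated allele confers risk
      risk <- if (risk == vi$alt_allele) vi$ref_allele else vi$alt_allele
      beta <- -beta
    }
    tibble(variant_id = v, ref_allele = vi$ref_allele,
           alt_allele = vi$alt_allele, risk_allele = risk, beta = beta)
  })
}

#' Write a synthetic VCF + phenotype fixture to disk
#'
#' Simulates a cohort with [simulate_cohort()] and writes a minimal VCF 4.2
#' (GT-only) plus a phenotype TSV and a matching YAML pipeline config.
#' Identical seeds produce byte-identical files.
#'
#' @param dir Output directory.
#' @param config A [sim_config()]; the default is the study-like cohort.
#' @param seed Overrides the config seed if non-NULL.
#' @return Invisible named list of the written paths.
#' @export
make_fixture <- function(dir, config = sim_config(), seed = NULL) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- simulate_cohort(config)
  vt <- config$variants
  vcf_path <- file.path(dir, "genotypes.vcf")
  pheno_path <- file.path(dir, "phenotypes.tsv")
  cfg_path <- file.path(dir, "config.yaml")

  gt_string <- function(d) {
    ifelse(is.na(d), "./.", c("0/0", "0/1", "1/1")[d + 1])
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=grsxe_synthetic_cohort",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", cohort$sample_id), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(vt)), function(i) {
    paste(c("1", as.character(1000L * i), vt$variant_id[i], vt$ref_allele[i],
            vt$alt_allele[i], ".", "PASS", ".", "GT",
            gt_string(cohort[[vt$variant_id[i]]])), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), vcf_path)

  pheno_cols <- c("sample_id", "status", "sex", "age_group", "school",
                  "maternal_edu", "paternal_edu", "income",
                  "physical_activity", "sleep")
  pheno <- cohort[, intersect(pheno_cols, names(cohort))]
  pheno$status <- ifelse(pheno$status == 1, "case", "control")
  readr::write_tsv(pheno, pheno_path, na = "")

  yaml::write_yaml(list(
    genotypes = vcf_path, phenotypes = pheno_path, format = "vcf",
    variant_meta = purrr::pmap(
      list(vt$variant_id, vt$risk_allele, vt$gene_label),
      function(v, r, g) list(variant_id = v, risk_allele = r, gene_label = g)
    ),
    out_dir = file.path(dir, "results"),
    B_permutation = 1000L, B_bootstrap = 1000L, seed = config$seed
  ), cfg_path)
  invisible(list(vcf = vcf_path, phenotypes = pheno_path, config = cfg_path))
}

#' Published crossover odds ratios shipped for worked examples
#'
#' Adjusted odds ratios of the four GRS-by-lifestyle crossover blocks as
#' printed by the childhood-obesity case-control study this package's
#' defaults emulate, for recomputing the interaction measures by their closed
#' forms.
#'
#' @return Tibble with `score`, `exposure`, cell counts and `or11`, `or10`,
#'   `or01`.
#' @export
published_crossover_ors <- function() {
  path <- system.file("extdata", "published_crossover_ors.tsv",
                      package = "grsxe", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE)
}
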