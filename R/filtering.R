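# The custom variant-filter cascade: per-call quality, population MAF,
# disease-gene annotation, and cohort-recurrence rules.  All predicates are
# vectorised over the variant table; the exported scalar-style helpers
# (passes_*) are thin wrappers used directly in tests and interactive work.

quality_flags <- function(variants, config) {
  is_snv <- variants$vclass == "SNV"
  # The published depth/mapping-quality thresholds are stated for SNVs only;
  # INDELs are held to the alternate-read-depth rule alone.  Missing quality
  # fields fail closed.
  fail_mq <- is_snv & (is.na(variants$map_quality) |
                         variants$map_quality < config$min_map_quality)
  fail_dp <- is_snv & (is.na(variants$depth) | variants$depth < config$min_depth)
  fail_ad <- is.na(variants$alt_depth) | variants$alt_depth < config$min_alt_depth
  tibble(quality_mq = fail_mq, quality_dp = fail_dp, quality_altdp = fail_ad)
}

#' Per-call quality rule
#'
#' A SNV passes iff mapping quality, depth and alternate-allele depth all
#' meet their inclusive minima; an INDEL is held only to the
#' alternate-allele-depth rule.  Missing values fail.
#'
#' @param variants Variant tibble.
#' @param config A [filter_config()].
#' @return Logical vector, one element per row.
#' @export
passes_quality <- function(variants, config = filter_config()) {
  q <- quality_flags(variants, config)
  !(q$quality_mq | q$quality_dp | q$quality_altdp)
}

#' Population minor-allele-frequency rule
#'
#' Panel frequencies are folded to the minor allele (`min(af, 1 - af)`); a
#' variant fails when the folded MAF reaches `max_maf` in any consulted
#' panel.  Panels without a reported frequency contribute nothing, so a
#' variant absent from every panel passes.
#'
#' @inheritParams passes_quality
#' @return Logical vector, one element per row.
#' @export
passes_population_maf <- function(variants, config = filter_config()) {
  validate_af(variants)
  fail <- rep(FALSE, nrow(variants))
  for (panel in config$reference_panels) {
    col <- paste0("af_", panel)
    if (!col %in% names(variants)) next
    af <- variants[[col]]
    maf <- pmin(af, 1 - af)
    fail <- fail | (!is.na(maf) & maf >= config$max_maf)
  }
  !fail
}

#' Disease-gene annotation rule
#'
#' A variant passes iff its gene is present in the gene-annotation table,
#' carries a listed HGMD/OMIM disease phenotype, and is not flagged as a
#' non-disease-trait-only gene.  The lookup is gene-level: the exact variant
#' is not required to have been reported.
#'
#' @inheritParams passes_quality
#' @param annotations Gene-annotation tibble ([read_gene_annotation()]).
#' @return Logical vector, one element per row.
#' @export
passes_gene_phenotype <- function(variants, annotations) {
  idx <- match(variants$gene, annotations$gene)
  has_pheno <- !is.na(idx) & annotations$has_hgmd_omim_phenotype[idx]
  trait_only <- !is.na(idx) & annotations$is_non_disease_trait_only[idx]
  has_pheno & !trait_only
}

gene_phenotype_rule <- function(variants, annotations) {
  idx <- match(variants$gene, annotations$gene)
  known <- !is.na(idx)
  has_pheno <- known & annotations$has_hgmd_omim_phenotype[idx]
  trait_only <- known & annotations$is_non_disease_trait_only[idx]
  tibble(no_phenotype_gene = !has_pheno,
         non_disease_trait = has_pheno & trait_only)
}

#' Cohort-recurrence filter
#'
#' An allele key `(chrom, pos, ref, alt)` carried by at least
#' `max_cohort_fraction` of the cohort's samples (distinct carriers) is
#' removed from every carrier; this targets locally recurrent calling
#' artifacts.
#'
#' @param variants Variant tibble spanning the cohort.
#' @param n_samples Number of samples in the cohort (denominator).
#' @param config A [filter_config()].
#' @return A list with elements `retained` and `removed`, a partition of the
#'   input rows.
#' @export
cohort_frequency_filter <- function(variants, n_samples, config = filter_config()) {
  assert_that(n_samples >= 1, "n_samples must be >= 1")
  frequent <- cohort_frequent_keys(variants, n_samples, config)
  removed <- variant_key(variants$chrom, variants$pos, variants$ref, variants$alt) %in% frequent
  list(retained = variants[!removed, , drop = FALSE],
       removed = variants[removed, , drop = FALSE])
}

cohort_frequent_keys <- function(variants, n_samples, config) {
  if (nrow(variants) == 0L) return(character())
  carriers <- variants |>
    mutate(key = variant_key(.data$chrom, .data$pos, .data$ref, .data$alt)) |>
    group_by(.data$key) |>
    summarise(n_carriers = n_distinct(.data$sample_id), .groups = "drop")
  carriers$key[carriers$n_carriers / n_samples >= config$max_cohort_fraction]
}

#' Apply the full filter cascade
#'
#' Applies quality, population-MAF, gene-phenotype and cohort-recurrence
#' rules and records a per-variant outcome.  The rules are independent
#' predicates, so the retained set does not depend on evaluation order; the
#' cohort-recurrence carrier counts are computed on the quality-passing set,
#' since the rule targets recurrent calling artifacts rather than real
#' common alleles.
#'
#' @param variants Annotated variant tibble for the whole cohort.
#' @param annotations Gene-annotation tibble.
#' @param config A [filter_config()].
#' @param n_samples Cohort size; defaults to the number of distinct
#'   `sample_id`s in `variants`.
#' @return A list with `retained` (variant tibble) and `outcomes` (one row
#'   per input variant: `key`, `sample_id`, `passed`, `failed_rules` as a
#'   comma-joined string in canonical rule order).
#' @export
apply_filters <- function(variants, annotations, config = filter_config(),
                          n_samples = NULL) {
  validate_variants(variants)
  n_samples <- n_samples %||% n_distinct(variants$sample_id)
  q <- quality_flags(variants, config)
  maf_ok <- passes_population_maf(variants, config)
  gp <- gene_phenotype_rule(variants, annotations)
  quality_ok <- !(q$quality_mq | q$quality_dp | q$quality_altdp)
  frequent <- cohort_frequent_keys(variants[quality_ok, , drop = FALSE],
                                   n_samples, config)
  keys <- variant_key(variants$chrom, variants$pos, variants$ref, variants$alt)
  cohort_fail <- keys %in% frequent

  fails <- cbind(
    quality_mq = q$quality_mq, quality_dp = q$quality_dp,
    quality_altdp = q$quality_altdp, population_maf = !maf_ok,
    cohort_frequency = cohort_fail, no_phenotype_gene = gp$no_phenotype_gene,
    non_disease_trait = gp$non_disease_trait
  )
  passed <- rowSums(fails) == 0L
  failed_rules <- apply(fails, 1L, function(row) {
    paste(WES_FILTER_RULES[WES_FILTER_RULES %in% colnames(fails)[row]], collapse = ",")
  })
  outcomes <- tibble(key = keys, sample_id = variants$sample_id,
                     passed = passed, failed_rules = failed_rules)
  list(retained = variants[passed, , drop = FALSE], outcomes = outcomes)
}
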