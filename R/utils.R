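# Shared vocabularies and small helpers.

# Reference-population panels consulted by the MAF filter; allele-frequency
# columns in variant tables are named paste0("af_", panel).
WES_PANELS <- c("g1000", "hapmap", "esp", "danish")

WES_CONSEQUENCES <- c(
  "stop_gained", "stop_lost", "start_lost", "splice_site", "missense",
  "frameshift", "inframe_codon_change", "codon_insertion_deletion",
  "synonymous", "other"
)

WES_INHERITANCE_CODES <- c("AD", "AD_AR", "AR", "XLR", "XLD", "YL", "SNP", "DIGENIC")
WES_MENDELIAN_CODES <- c("AD", "AD_AR", "AR", "XLR", "XLD", "DIGENIC")

# Inheritance classes used in the cross-tabulation (SNP genes subdivided,
# YL/protective/unobservable-non-Mendelian folded into OTHERS).
WES_INH_CLASSES <- c(
  "AD", "AD_AR", "DIGENIC", "AR", "XLR", "XLD",
  "SNP_novel", "SNP_exact", "OTHERS"
)

WES_SCORES <- c("YES", "NO", "X")

WES_FILTER_RULES <- c(
  "quality_mq", "quality_dp", "quality_altdp", "population_maf",
  "cohort_frequency", "no_phenotype_gene", "non_disease_trait"
)

WES_ZYGOSITIES <- c("heterozygous", "homozygous_alt", "hemizygous")

#' Canonical variant key
#'
#' Builds the `chrom:pos:ref:alt` key used throughout the package to identify
#' an allele irrespective of carrier sample.
#'
#' @param chrom Chromosome name(s).
#' @param pos 1-based position(s).
#' @param ref,alt Reference and alternate allele strings.
#' @return Character vector of keys.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  sprintf("%s:%d:%s:%s", chrom, as.integer(pos), ref, alt)
}

af_cols <- function() paste0("af_", WES_PANELS)

variant_cols <- function() {
  c("sample_id", "chrom", "pos", "ref", "alt", "vclass", "zygosity",
    "map_quality", "depth", "alt_depth", "consequence", "sift", "polyphen",
    "gene", af_cols())
}

is_sex_chrom <- function(chrom) {
  sub("^chr", "", chrom) %in% c("X", "Y")
}

infer_vclass <- function(ref, alt) {
  ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNV", "INDEL")
}

assert_that <- function(ok, msg, ...) {
  if (!isTRUE(ok)) abort(sprintf(msg, ...))
  invisible(TRUE)
}

#' Validate a variant-call table
#'
#' Checks column presence and the structural invariants of a variant table:
#' `alt_depth <= depth` (where both are known), SNV/INDEL consistency with
#' allele lengths, positive positions, and hemizygous calls restricted to the
#' sex chromosomes.
#'
#' @param variants A variant tibble (one row per called ALT allele per sample).
#' @return The input, invisibly, after validation.
#' @export
validate_variants <- function(variants) {
  missing <- setdiff(variant_cols(), names(variants))
  assert_that(length(missing) == 0L,
              "variant table is missing columns: %s", paste(missing, collapse = ", "))
  assert_that(all(variants$pos >= 1L), "variant positions must be >= 1")
  bad_ad <- !is.na(variants$alt_depth) & !is.na(variants$depth) &
    variants$alt_depth > variants$depth
  assert_that(!any(bad_ad), "alt_depth exceeds depth for %d variant(s)", sum(bad_ad))
  assert_that(all(variants$vclass %in% c("SNV", "INDEL")), "vclass must be SNV or INDEL")
  mismatch <- variants$vclass != infer_vclass(variants$ref, variants$alt)
  assert_that(!any(mismatch),
              "vclass inconsistent with allele lengths for %d variant(s)", sum(mismatch))
  assert_that(all(variants$zygosity %in% WES_ZYGOSITIES), "unknown zygosity value")
  hemi_auto <- variants$zygosity == "hemizygous" & !is_sex_chrom(variants$chrom)
  assert_that(!any(hemi_auto), "hemizygous call on an autosome (%d row(s))", sum(hemi_auto))
  invisible(variants)
}

validate_af <- function(variants) {
  for (col in intersect(af_cols(), names(variants))) {
    af <- variants[[col]]
    bad <- !is.na(af) & (af < 0 | af > 1)
    assert_that(!any(bad), "allele frequency outside [0,1] in column %s", col)
  }
  invisible(variants)
}
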