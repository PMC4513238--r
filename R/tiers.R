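# Tier-1/Tier-2 consequence classification.
#
# Tier-1 SNV: stop gain/loss, start loss, splice site.
# Tier-2 SNV: missense with in-silico support (SIFT or PolyPhen damaging).
# Tier-1 INDEL: frameshift or splice site.
# Tier-2 INDEL: in-frame codon change or codon insertion/deletion.
# Everything else (synonymous, other, unsupported missense) is not
# reportable and is dropped by classify_all().

TIER1_SNV <- c("stop_gained", "stop_lost", "start_lost", "splice_site")
TIER1_INDEL <- c("frameshift", "splice_site")
TIER2_INDEL <- c("inframe_codon_change", "codon_insertion_deletion")
SNV_ONLY_CONSEQ <- c("stop_gained", "stop_lost", "start_lost", "missense", "synonymous")
INDEL_ONLY_CONSEQ <- c("frameshift", "inframe_codon_change", "codon_insertion_deletion")

#' In-silico support for a missense variant
#'
#' TRUE iff SIFT or PolyPhen calls the variant damaging; two missing
#' predictions count as no support.
#'
#' @param variants Variant tibble; every row must be a missense call.
#' @return Logical vector.
#' @export
is_damaging <- function(variants) {
  assert_that(all(variants$consequence == "missense"),
              "is_damaging() is defined for missense variants only")
  sift <- replace_na(variants$sift, "missing")
  polyphen <- replace_na(variants$polyphen, "missing")
  sift == "damaging" | polyphen == "damaging"
}

check_vclass_consequence <- function(variants) {
  bad <- (variants$vclass == "SNV" & variants$consequence %in% INDEL_ONLY_CONSEQ) |
    (variants$vclass == "INDEL" & variants$consequence %in% SNV_ONLY_CONSEQ)
  assert_that(!any(bad),
              "inconsistent vclass/consequence pair(s), e.g. %s + %s",
              variants$vclass[bad][1] %||% "", variants$consequence[bad][1] %||% "")
  invisible(variants)
}

tier_of <- function(variants) {
  sift <- replace_na(variants$sift, "missing")
  polyphen <- replace_na(variants$polyphen, "missing")
  damaging <- sift == "damaging" | polyphen == "damaging"
  dplyr::case_when(
    variants$vclass == "SNV" & variants$consequence %in% TIER1_SNV ~ 1L,
    variants$vclass == "SNV" & variants$consequence == "missense" & damaging ~ 2L,
    variants$vclass == "INDEL" & variants$consequence %in% TIER1_INDEL ~ 1L,
    variants$vclass == "INDEL" & variants$consequence %in% TIER2_INDEL ~ 2L,
    TRUE ~ NA_integer_
  )
}

#' Classify variants into tiers
#'
#' `classify_variants()` appends `tier` (1, 2 or NA for non-reportable) and
#' `tier_basis` (the triggering consequence) to the variant table;
#' `classify_all()` additionally drops the non-reportable rows, preserving
#' input order.  Classification is a pure function of
#' `(vclass, consequence, sift, polyphen)`.
#'
#' @param variants Filter-passing variant tibble.
#' @return The variant tibble with `tier` and `tier_basis` columns.
#' @export
classify_variants <- function(variants) {
  check_vclass_consequence(variants)
  tier <- tier_of(variants)
  mutate(variants, tier = tier,
         tier_basis = ifelse(is.na(tier), NA_character_, .data$consequence))
}

#' @rdname classify_variants
#' @export
classify_all <- function(variants) {
  out <- classify_variants(variants)
  filter(out, !is.na(.data$tier))
}
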