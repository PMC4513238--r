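# Minimal single-sample VCF 4.2 reading/writing.  Reading goes through
# VariantAnnotation; only GT/DP/AD per-sample fields and the MQ INFO field
# are consumed.  Functional annotations (gene, consequence, in-silico calls,
# population frequencies) live in a sidecar TSV keyed by
# (chrom, pos, ref, alt, gene) -- see read_variant_annotation().

#' Read variant calls for one sample from a VCF file
#'
#' Parses a VCF 4.x file and returns one row per carried ALT allele.
#' Multi-allelic records are split into per-ALT calls sharing the record's
#' DP, with the alternate-allele depth taken from the allele's own AD entry.
#' Zygosity is derived from GT: `0/1 -> heterozygous`, `1/1 ->
#' homozygous_alt`, a single-allele genotype (e.g. `1` on X in a male) `->
#' hemizygous`.  ALT alleles not present in the genotype are dropped.
#'
#' @param path Path to a VCF file.
#' @param sample_id Name of the sample column to read.
#' @param format_keys Named character vector mapping the required roles
#'   `gt`, `dp`, `ad` to per-sample FORMAT keys.
#' @return A tibble of variant calls (no annotation columns; join these with
#'   [annotate_variants()]).
#' @seealso [write_vcf()], [annotate_variants()]
#' @export
read_vcf <- function(path, sample_id,
                     format_keys = c(gt = "GT", dp = "DP", ad = "AD")) {
  vcf <- tryCatch(
    suppressWarnings(VariantAnnotation::readVcf(path)),
    error = function(e) abort(sprintf("malformed VCF '%s': %s", path, conditionMessage(e)))
  )
  samples <- colnames(vcf)
  assert_that(sample_id %in% samples,
              "sample '%s' not found in VCF '%s' (samples: %s)",
              sample_id, path, paste(samples, collapse = ", "))
  geno <- VariantAnnotation::geno(vcf)
  for (role in c("gt", "dp", "ad")) {
    key <- format_keys[[role]]
    assert_that(key %in% names(geno),
                "VCF '%s' lacks the required per-sample field '%s'", path, key)
  }
  n_rec <- nrow(vcf)
  if (n_rec == 0L) {
    return(tibble(sample_id = character(), chrom = character(), pos = integer(),
                  ref = character(), alt = character(), vclass = character(),
                  zygosity = character(), map_quality = double(),
                  depth = integer(), alt_depth = integer()))
  }

  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomeInfoDb::seqnames(rr))
  pos <- BiocGenerics::start(rr)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt_list <- VariantAnnotation::alt(vcf)
  alt_chr <- lapply(seq_len(n_rec), function(i) as.character(alt_list[[i]]))

  gt <- as.character(geno[[format_keys[["gt"]]]][, sample_id])
  dp_raw <- geno[[format_keys[["dp"]]]][, sample_id]
  ad_raw <- geno[[format_keys[["ad"]]]][, sample_id]
  info <- VariantAnnotation::info(vcf)
  mq <- if ("MQ" %in% names(info)) as.numeric(info$MQ) else rep(NA_real_, n_rec)

  out <- vector("list", n_rec)
  for (i in seq_len(n_rec)) {
    alleles <- strsplit(gt[[i]], "[/|]")[[1]]
    if (length(alleles) == 0L || all(alleles == ".")) {
      abort(sprintf("missing genotype for sample '%s' at record %d (%s:%d)",
                    sample_id, i, chrom[[i]], pos[[i]]))
    }
    suppressWarnings(idx <- as.integer(alleles))
    if (anyNA(idx)) {
      abort(sprintf("unknown GT symbol '%s' at record %d (%s:%d)",
                    gt[[i]], i, chrom[[i]], pos[[i]]))
    }
    ad_i <- ad_raw[[i]]
    rows <- list()
    for (a in seq_along(alt_chr[[i]])) {
      n_a <- sum(idx == a)
      if (n_a == 0L) next
      zyg <- if (length(idx) == 1L) "hemizygous"
             else if (n_a == 2L) "homozygous_alt"
             else "heterozygous"
      alt_depth <- if (length(ad_i) >= a + 1L) as.integer(ad_i[[a + 1L]]) else NA_integer_
      ref_i <- ref[[i]]
      alt_a <- alt_chr[[i]][[a]]
      rows[[length(rows) + 1L]] <- tibble(
        sample_id = sample_id, chrom = chrom[[i]], pos = as.integer(pos[[i]]),
        ref = ref_i, alt = alt_a,
        vclass = infer_vclass(ref_i, alt_a),
        zygosity = zyg, map_quality = mq[[i]],
        depth = as.integer(dp_raw[[i]]), alt_depth = alt_depth
      )
    }
    out[[i]] <- bind_rows(rows)
  }
  bind_rows(out)
}

#' Write one sample's variant calls as a minimal VCF 4.2 file
#'
#' Emits GT:DP:AD per-sample fields and the mapping quality as the `MQ` INFO
#' field.  Records are sorted by chromosome and position.  The output
#' round-trips through [read_vcf()] on `(chrom, pos, ref, alt, zygosity,
#' depth, alt_depth)`.
#'
#' @param variants Variant tibble for a single sample.
#' @param path Output path.
#' @param sample_id Sample column name; defaults to the table's unique
#'   `sample_id`.
#' @return The path, invisibly.
#' @export
write_vcf <- function(variants, path, sample_id = NULL) {
  if (is.null(sample_id)) {
    ids <- unique(variants$sample_id)
    assert_that(length(ids) <= 1L, "write_vcf() expects calls from a single sample")
    sample_id <- if (length(ids) == 1L) ids else "SAMPLE"
  }
  v <- arrange(variants, .data$chrom, .data$pos, .data$alt)
  gt <- c(heterozygous = "0/1", homozygous_alt = "1/1", hemizygous = "1")[v$zygosity]
  ref_depth <- pmax(v$depth - v$alt_depth, 0L)
  fmt <- sprintf("%s:%d:%d,%d", gt, v$depth, ref_depth, v$alt_depth)
  contigs <- unique(v$chrom)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=wescorr",
    '##INFO=<ID=MQ,Number=1,Type=Float,Description="PHRED-scaled mapping quality">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    sprintf("##contig=<ID=%s>", contigs),
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample_id)
  )
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tMQ=%s\tGT:DP:AD\t%s",
                  v$chrom, v$pos, v$ref, v$alt,
                  ifelse(is.na(v$map_quality), ".", format(v$map_quality)), fmt)
  write_lines(c(header, body), path)
  invisible(path)
}
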