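# Builders for miniature in-code fixtures, plus a cached copy of the
# reference cohort and its pipeline run (built once per test session).

make_variant <- function(sample_id = "S1", chrom = "1", pos = 1000L,
                         ref = "A", alt = "G", zygosity = "heterozygous",
                         map_quality = 60, depth = 50L, alt_depth = 24L,
                         consequence = "missense", sift = "damaging",
                         polyphen = "benign", gene = "GENE1",
                         af_g1000 = NA_real_, af_hapmap = NA_real_,
                         af_esp = NA_real_, af_danish = NA_real_) {
  tibble::tibble(
    sample_id = sample_id, chrom = chrom, pos = as.integer(pos),
    ref = ref, alt = alt,
    vclass = ifelse(nchar(ref) == 1 & nchar(alt) == 1, "SNV", "INDEL"),
    zygosity = zygosity, map_quality = map_quality,
    depth = as.integer(depth), alt_depth = as.integer(alt_depth),
    consequence = consequence, sift = sift, polyphen = polyphen, gene = gene,
    af_g1000 = af_g1000, af_hapmap = af_hapmap, af_esp = af_esp,
    af_danish = af_danish
  )
}

make_gene <- function(gene = "GENE1", phenotypes = "Eczema",
                      has_pheno = TRUE, trait_only = FALSE,
                      inheritance = "AD", protective = FALSE,
                      sex_limited = "none", observable = TRUE,
                      gwas = character()) {
  tibble::tibble(
    gene = gene, phenotypes = list(as.character(phenotypes)),
    has_hgmd_omim_phenotype = has_pheno,
    is_non_disease_trait_only = trait_only,
    inheritance = inheritance, protective_only = protective,
    sex_limited = sex_limited, observable_in_emr = observable,
    gwas_exact_positions = list(as.character(gwas))
  )
}

make_participant <- function(sample_id = "S1", sex = "M",
                             diagnoses = character(), cancer = FALSE,
                             group = 1L) {
  tibble::tibble(sample_id = sample_id, sex = sex,
                 diagnoses = list(as.character(diagnoses)),
                 has_invasive_cancer = cancer, group = as.integer(group))
}

# Independent Fisher oracle: exhaustive enumeration with the closed-form
# multivariate-hypergeometric table probability (log-factorial form), kept
# deliberately distinct from the dhyper-based implementation.
fisher_enumerate <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); c2 <- sum(tab[, 2]); n <- r1 + r2
  lp <- function(a) {
    b <- r1 - a; c <- c1 - a; d <- r2 - c
    if (b < 0 || c < 0 || d < 0) return(-Inf)
    lgamma(r1 + 1) + lgamma(r2 + 1) + lgamma(c1 + 1) + lgamma(c2 + 1) -
      lgamma(n + 1) - lgamma(a + 1) - lgamma(b + 1) - lgamma(c + 1) - lgamma(d + 1)
  }
  support <- 0:min(r1, c1)
  logs <- vapply(support, lp, numeric(1))
  probs <- exp(logs)
  p_obs <- exp(lp(tab[1, 1]))
  if (n == 0) return(1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Session-level cache of the reference fixture and its pipeline run.
.wescorr_cache <- new.env(parent = emptyenv())

cached_fixture <- function() {
  if (is.null(.wescorr_cache$fx)) .wescorr_cache$fx <- table2_fixture(seed = 1)
  .wescorr_cache$fx
}

cached_run <- function() {
  if (is.null(.wescorr_cache$run)) {
    .wescorr_cache$run <- run_pipeline(cached_fixture())
  }
  .wescorr_cache$run
}
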