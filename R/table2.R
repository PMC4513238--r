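# The deterministic reference fixture: an 89-participant cohort whose
# pipeline output reproduces, cell by cell, the published cross-tabulation
# of 7046 filtered variants (374/270 Tier-1 SNV/INDEL, 5703/699 Tier-2),
# including the secondary-findings (ACMG-56) and cancer-predisposition
# (57-gene) panel structure and the phenotype-centric match distribution
# (146 matched of 636 diagnoses over 73 participants; 16 with none).

#' Reference cross-tabulation cell counts
#'
#' The per-(tier, variant class, inheritance class) Yes/No/X counts the
#' fixture is built to reproduce.  Where the published SNP sub-rows are
#' arithmetically inconsistent with their block margins, the cells are
#' resolved in favour of the block totals (which the cohort-level summary
#' counts also satisfy); the methods vignette documents the resolution.
#'
#' @return A tibble with columns `tier`, `vclass`, `inh_class`, `yes`, `no`,
#'   `x` and `n`.
#' @export
table2_cells <- function() {
  rows <- list(
    # tier, vclass, class, yes, no, x
    list(1L, "SNV", "AD", 3, 55, 2),
    list(1L, "SNV", "AD_AR", 1, 11, 1),
    list(1L, "SNV", "DIGENIC", 0, 2, 0),
    list(1L, "SNV", "AR", 2, 0, 90),
    list(1L, "SNV", "XLR", 1, 2, 8),
    list(1L, "SNV", "XLD", 0, 2, 0),
    list(1L, "SNV", "SNP_novel", 11, 135, 1),
    list(1L, "SNV", "SNP_exact", 0, 17, 17),
    list(1L, "SNV", "OTHERS", 0, 0, 13),
    list(1L, "INDEL", "AD", 4, 34, 1),
    list(1L, "INDEL", "AD_AR", 1, 16, 0),
    list(1L, "INDEL", "DIGENIC", 1, 6, 0),
    list(1L, "INDEL", "AR", 0, 0, 84),
    list(1L, "INDEL", "XLR", 0, 0, 0),
    list(1L, "INDEL", "XLD", 0, 0, 0),
    list(1L, "INDEL", "SNP_novel", 4, 97, 13),
    list(1L, "INDEL", "SNP_exact", 0, 6, 0),
    list(1L, "INDEL", "OTHERS", 0, 0, 3),
    list(2L, "SNV", "AD", 27, 861, 26),
    list(2L, "SNV", "AD_AR", 15, 145, 17),
    list(2L, "SNV", "DIGENIC", 4, 50, 4),
    list(2L, "SNV", "AR", 2, 0, 2127),
    list(2L, "SNV", "XLR", 0, 12, 39),
    list(2L, "SNV", "XLD", 0, 8, 3),
    list(2L, "SNV", "SNP_novel", 100, 1779, 291),
    list(2L, "SNV", "SNP_exact", 7, 118, 31),
    list(2L, "SNV", "OTHERS", 0, 0, 37),
    list(2L, "INDEL", "AD", 2, 179, 31),
    list(2L, "INDEL", "AD_AR", 4, 2, 0),
    list(2L, "INDEL", "DIGENIC", 0, 0, 0),
    list(2L, "INDEL", "AR", 2, 0, 111),
    list(2L, "INDEL", "XLR", 0, 11, 24),
    list(2L, "INDEL", "XLD", 0, 1, 0),
    list(2L, "INDEL", "SNP_novel", 11, 161, 26),
    list(2L, "INDEL", "SNP_exact", 0, 0, 0),
    list(2L, "INDEL", "OTHERS", 0, 0, 134)
  )
  out <- bind_rows(lapply(rows, function(r) {
    tibble(tier = r[[1]], vclass = r[[2]], inh_class = r[[3]],
           yes = as.integer(r[[4]]), no = as.integer(r[[5]]), x = as.integer(r[[6]]))
  }))
  mutate(out, n = .data$yes + .data$no + .data$x)
}

table2_cell_counts <- function() {
  cells <- table2_cells()
  bind_rows(
    select(mutate(cells, score = "YES", n = .data$yes),
           all_of(c("tier", "vclass", "inh_class", "score", "n"))),
    select(mutate(cells, score = "NO", n = .data$no),
           all_of(c("tier", "vclass", "inh_class", "score", "n"))),
    select(mutate(cells, score = "X", n = .data$x),
           all_of(c("tier", "vclass", "inh_class", "score", "n")))
  )
}

# ---- fixture demography ----------------------------------------------------
# 89 participants: 51 male (1..51), 38 female; 39 with invasive-cancer
# history (23 of the 39 group-1 participants, 16 of the 50 group-2
# participants); participants 1..73 have at least one matched diagnosis,
# 74..89 have none.

fixture_cancer_idx <- function() c(1:23, 40:55)

fixture_match_slots <- function() {
  tibble(
    sample_idx = c(1L, 2:6, 7:73),
    n_slots = c(7L, rep(1L, 5), rep(2L, 67))
  )
}

fixture_filler_diagnoses <- function() {
  # 636 total diagnoses over participants 1..73 (146 matched + 490 filler);
  # non-matching participants 74..89 carry 6 unmatched diagnoses each.
  c(1L, rep(7L, 57), rep(6L, 15), rep(6L, 16))
}

# ---- secondary-findings / cancer panel plan --------------------------------

# Per-person panel variant counts.  A: ACMG-56 counts (161 variants in 74
# carriers, median 2, range 0-6, 15 participants with none).  C: 57-gene
# cancer-panel counts (115 variants; 51 over the 39 cancer participants,
# mean 1.3, range 0-3; 64 over the 50 without cancer, range 0-4).  Variants
# in the 23 shared genes count in both panels.
fixture_panel_profile <- function() {
  A <- integer(89)
  A[1:6] <- 6L; A[7:9] <- 5L; A[10:54] <- 2L; A[55:74] <- 1L
  C <- integer(89)
  canc <- fixture_cancer_idx()
  C[canc[1:4]] <- 3L; C[canc[5:14]] <- 2L; C[canc[15:33]] <- 1L
  nonc <- setdiff(1:89, canc)
  C[nonc[1]] <- 4L; C[nonc[2:5]] <- 3L; C[nonc[6:18]] <- 2L; C[nonc[19:40]] <- 1L
  s <- pmin(A, C)
  # Participants 15 and 16 host the cancer-only likely-pathogenic variants
  # (ATR frameshift, BRIP1 missense): free their single overlap slot.
  s[c(15L, 16L)] <- 0L
  list(A = A, C = C, shared = s, acmg_only = A - s, cancer_only = C - s)
}

acmg_cancer23 <- function() {
  c("BRCA1", "BRCA2", "TP53", "STK11", "MLH1", "MSH2", "MSH6", "PMS2", "APC",
    "MUTYH", "VHL", "MEN1", "RET", "PTEN", "RB1", "SDHD", "SDHAF2", "SDHC",
    "SDHB", "TSC1", "TSC2", "WT1", "NF2")
}

fixture_panel_plan <- function() {
  prof <- fixture_panel_profile()
  shared23 <- acmg_cancer23()
  acmg_noncancer <- setdiff(acmg56_genes(), shared23)
  cancer_only34 <- setdiff(cancer57_genes(), shared23)

  plan <- list()
  add <- function(sample_idx, gene, tier, vclass) {
    plan[[length(plan) + 1L]] <<- tibble(sample_idx = sample_idx, gene = gene,
                                         tier = tier, vclass = vclass)
  }

  shared <- prof$shared
  acmg_only <- prof$acmg_only
  cancer_only <- prof$cancer_only

  # Tier-1 placements (13 ACMG: 8 SNV + 5 INDEL; 3 cancer-panel: the two
  # shared BRCA2 calls plus the ATR frameshift).
  add(1L, "BRCA2", 1L, "SNV"); shared[1] <- shared[1] - 1L
  add(2L, "BRCA2", 1L, "INDEL"); shared[2] <- shared[2] - 1L
  t1_snv <- c("APOB", "APOB", "LDLR", "LDLR", "MYBPC3", "MYBPC3", "SMAD3")
  for (i in seq_along(t1_snv)) {
    p <- (3:9)[i]
    add(p, t1_snv[i], 1L, "SNV"); acmg_only[p] <- acmg_only[p] - 1L
  }
  t1_indel <- c("DSC2", "PCSK9", "DSP", "DSP")
  for (i in seq_along(t1_indel)) {
    p <- (17:20)[i]
    add(p, t1_indel[i], 1L, "INDEL"); acmg_only[p] <- acmg_only[p] - 1L
  }
  add(15L, "ATR", 1L, "INDEL"); cancer_only[15] <- cancer_only[15] - 1L
  add(16L, "BRIP1", 2L, "SNV"); cancer_only[16] <- cancer_only[16] - 1L

  assert_that(all(shared >= 0) && all(acmg_only >= 0) && all(cancer_only >= 0),
              "fixture panel plan over-consumed a per-person slot")

  # Remaining slots are Tier-2 SNVs cycling through the respective gene lists.
  fill <- function(counts, genes) {
    idx <- rep(seq_along(counts), counts)
    if (length(idx) > 0L) {
      add(idx, rep_len(genes, length(idx)), 2L, "SNV")
    }
  }
  fill(shared, shared23)
  fill(acmg_only, acmg_noncancer)
  # ATR and BRIP1 are reserved for the two likely-pathogenic placements above.
  fill(cancer_only, setdiff(cancer_only34, c("ATR", "BRIP1")))
  bind_rows(plan)
}

# Reassigns pre-generated (AD, NO) variants to panel genes and planned
# carriers; cell counts are untouched, only gene symbols and carriers move.
plant_panel_variants <- function(cohort, plan) {
  truth <- cohort$truth
  keys_all <- variant_key(cohort$variants$chrom, cohort$variants$pos,
                          cohort$variants$ref, cohort$variants$alt)
  used <- logical(nrow(cohort$variants))
  replaced_genes <- character()

  for (i in seq_len(nrow(plan))) {
    p <- plan[i, ]
    cand <- which(!used &
                    truth$tier == p$tier & truth$vclass == p$vclass &
                    truth$inh_class == "AD" & truth$score == "NO" &
                    !truth$is_decoy)
    assert_that(length(cand) > 0L,
                "fixture panel plan exhausted the (Tier-%d, %s, AD, NO) cell",
                p$tier, p$vclass)
    j <- cand[1]
    used[j] <- TRUE
    replaced_genes <- c(replaced_genes, cohort$variants$gene[j])
    sid <- cohort$participants$sample_id[p$sample_idx]
    cohort$variants$gene[j] <- p$gene
    cohort$variants$sample_id[j] <- sid
    truth$sample_id[j] <- sid
  }
  cohort$truth <- truth

  panel_genes <- unique(plan$gene)
  cohort$annotations <- cohort$annotations |>
    filter(!.data$gene %in% replaced_genes)
  cohort$annotations <- bind_rows(
    cohort$annotations,
    tibble(gene = panel_genes,
           phenotypes = lapply(panel_genes, function(g) paste0("gpacmg", tolower(g))),
           has_hgmd_omim_phenotype = TRUE,
           is_non_disease_trait_only = FALSE,
           inheritance = "AD", protective_only = FALSE, sex_limited = "none",
           observable_in_emr = TRUE,
           gwas_exact_positions = replicate(length(panel_genes), character(),
                                            simplify = FALSE))
  )
  cohort
}

#' The reference cohort fixture
#'
#' Builds the deterministic 89-participant synthetic cohort whose full
#' pipeline output reproduces the reference cross-tabulation
#' ([table2_cells()]): 7046 classified variants (644 Tier-1, 6402 Tier-2;
#' 202 YES / 3710 NO / 3134 X), 161 variants in the ACMG-56 panel (13
#' Tier-1, 148 Tier-2; 74 carriers, median 2 per person, 15 participants
#' with none), 115 variants in the 57-gene cancer panel (3 Tier-1; 51 over
#' the 39 cancer participants), and 146 matched diagnoses out of 636 over
#' the 73 participants with any match.  Decoy variants violating each
#' filter rule are spiked in; the two likely-pathogenic (score 4)
#' cancer-panel variants (an ATR frameshift and a BRIP1 missense) are
#' carried by cancer participants, all other cancer-panel variants score 3
#' (uncertain significance) in the bundled pathogenicity table.
#'
#' @param seed Integer seed; cell counts and all summary counts are
#'   seed-invariant (only sampled positions vary).
#' @return A `wes_cohort` with an additional `pathogenicity` element.
#' @export
table2_fixture <- function(seed = 1L) {
  spec <- cohort_spec(
    n_participants = 89L,
    seed = seed,
    cell_counts = table2_cell_counts(),
    n_quality_fail_decoys = 9L,
    n_common_af_decoys = 6L,
    n_cohort_recurrent_decoys = 1L,
    n_no_phenotype_gene_decoys = 6L,
    n_non_disease_trait_decoys = 6L,
    n_male = 51L,
    cancer_idx = fixture_cancer_idx(),
    group2_start = 40L
  )
  cohort <- generate_cohort(spec,
                            match_slots = fixture_match_slots(),
                            filler_diagnoses = fixture_filler_diagnoses())
  cohort <- plant_panel_variants(cohort, fixture_panel_plan())
  cohort <- spike_decoys(cohort)

  decoy_keys <- cohort$truth$key[cohort$truth$is_decoy]
  all_keys <- variant_key(cohort$variants$chrom, cohort$variants$pos,
                          cohort$variants$ref, cohort$variants$alt)
  cancer_vars <- subset_to_panel(cohort$variants[!all_keys %in% decoy_keys, ],
                                 cancer57_genes())
  keys <- variant_key(cancer_vars$chrom, cancer_vars$pos,
                      cancer_vars$ref, cancer_vars$alt)
  lp_keys <- keys[cancer_vars$gene %in% c("ATR", "BRIP1")]
  cohort$pathogenicity <- tibble(
    key = keys,
    score = ifelse(keys %in% lp_keys, 4L, 3L)
  )
  cohort
}
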