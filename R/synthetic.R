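# Deterministic synthetic-cohort generation.  A CohortSpec states how many
# variants the full pipeline should assign to each
# (tier x variant-class x inheritance-class x score) cell; the generator
# constructs calls, gene annotations and participant diagnoses so that the
# real pipeline reproduces those counts exactly, and can spike decoy
# variants that each violate exactly one filter rule.

#' Specify a synthetic cohort
#'
#' @param n_participants Cohort size (>= 1).
#' @param seed Integer seed; cohorts are byte-identical for identical seeds,
#'   and differ only in sampled positions for different seeds (never in cell
#'   counts).
#' @param cell_counts Tibble with columns `tier` (1/2), `vclass`
#'   (SNV/INDEL), `inh_class` (one of the cross-tabulation classes), `score`
#'   (YES/NO/X) and `n`.  Omitted cells are zero.
#' @param n_quality_fail_decoys,n_common_af_decoys,n_cohort_recurrent_decoys,n_no_phenotype_gene_decoys,n_non_disease_trait_decoys
#'   Decoy counts used by [spike_decoys()]; `n_cohort_recurrent_decoys`
#'   counts recurrent allele keys, each planted in just enough samples to
#'   trip the cohort filter.
#' @param fraction_cancer Fraction of participants with invasive-cancer
#'   history (used when `cancer_idx` is not given).
#' @param n_male Number of male participants (participants `1..n_male` are
#'   male); defaults to half the cohort.
#' @param cancer_idx Optional explicit indices of cancer participants.
#' @param group2_start Index of the first group-2 participant (earlier
#'   participants form group 1); defaults to none (all group 1).
#' @return A `wes_cohort_spec`.
#' @export
cohort_spec <- function(n_participants,
                        seed = 1L,
                        cell_counts = NULL,
                        n_quality_fail_decoys = 0L,
                        n_common_af_decoys = 0L,
                        n_cohort_recurrent_decoys = 0L,
                        n_no_phenotype_gene_decoys = 0L,
                        n_non_disease_trait_decoys = 0L,
                        fraction_cancer = 0.44,
                        n_male = NULL,
                        cancer_idx = NULL,
                        group2_start = NULL) {
  assert_that(n_participants >= 1, "n_participants must be >= 1")
  cell_counts <- cell_counts %||%
    tibble(tier = integer(), vclass = character(),
           inh_class = character(), score = character(), n = integer())
  assert_that(all(cell_counts$tier %in% c(1L, 2L)), "tier must be 1 or 2")
  assert_that(all(cell_counts$vclass %in% c("SNV", "INDEL")), "vclass must be SNV or INDEL")
  assert_that(all(cell_counts$inh_class %in% WES_INH_CLASSES),
              "inh_class must be one of: %s", paste(WES_INH_CLASSES, collapse = ", "))
  assert_that(all(cell_counts$score %in% WES_SCORES), "score must be YES, NO or X")
  assert_that(all(cell_counts$n >= 0), "cell counts must be non-negative")
  bad <- cell_counts$inh_class == "OTHERS" & cell_counts$score != "X" & cell_counts$n > 0
  assert_that(!any(bad),
              "infeasible cell: OTHERS-class variants always score X (cannot assess)")
  assert_that(fraction_cancer >= 0 && fraction_cancer <= 1,
              "fraction_cancer must lie in [0,1]")
  structure(list(
    n_participants = as.integer(n_participants),
    seed = as.integer(seed),
    cell_counts = as_tibble(cell_counts),
    n_quality_fail_decoys = as.integer(n_quality_fail_decoys),
    n_common_af_decoys = as.integer(n_common_af_decoys),
    n_cohort_recurrent_decoys = as.integer(n_cohort_recurrent_decoys),
    n_no_phenotype_gene_decoys = as.integer(n_no_phenotype_gene_decoys),
    n_non_disease_trait_decoys = as.integer(n_non_disease_trait_decoys),
    fraction_cancer = fraction_cancer,
    n_male = if (is.null(n_male)) NULL else as.integer(n_male),
    cancer_idx = cancer_idx,
    group2_start = group2_start
  ), class = "wes_cohort_spec")
}

new_rotation <- function(idx) {
  env <- new.env(parent = emptyenv())
  env$idx <- idx
  env$ptr <- 0L
  env
}

rotate <- function(rot, k) {
  if (k == 0L) return(integer())
  assert_that(length(rot$idx) > 0L, "no eligible participants for this cell")
  out <- rot$idx[(rot$ptr + seq_len(k) - 1L) %% length(rot$idx) + 1L]
  rot$ptr <- (rot$ptr + k) %% length(rot$idx)
  out
}

cell_sex_requirement <- function(inh_class, score) {
  case_when(
    inh_class == "XLR" & score == "YES" ~ "M",   # hemizygous male carrier
    inh_class == "XLR" & score == "NO" ~ "M",    # hemizygous male, assessable
    inh_class == "XLR" & score == "X" ~ "F",     # heterozygous female carrier
    inh_class == "XLD" ~ "F",                    # heterozygous female carrier
    inh_class == "OTHERS" ~ "M",                 # Y-linked genes
    grepl("^SNP", inh_class) & score == "X" ~ "F",  # male-limited gene in a woman
    TRUE ~ "any"
  )
}

#' Generate a synthetic annotated cohort
#'
#' Constructs, deterministically for a given seed, a cohort whose variants
#' the full pipeline (filtering, tier classification, inheritance
#' assignment, Yes/No/X scoring) labels exactly as requested by
#' `spec$cell_counts`.  YES cells plant a shared controlled-vocabulary
#' keyword between the gene's phenotype list and the carrier's diagnoses; X
#' cells are realised by the mechanism proper to their class (monoallelic
#' recessive carrier, female XLR heterozygote, unobservable-phenotype gene,
#' sex-limited gene in the incompatible sex, or Y-linked gene); every
#' variant receives its own synthetic gene so that cells stay independent.
#'
#' @param spec A [cohort_spec()].
#' @param match_slots Optional tibble (`sample_idx`, `n_slots`) pre-defining
#'   the (participant, keyword) slots that YES variants are assigned to; used
#'   to reproduce a phenotype-centric match distribution.  By default every
#'   YES variant receives its own slot on a rotating carrier.
#' @param filler_diagnoses Optional integer vector (length `n_participants`)
#'   of additional non-matching diagnoses per participant; defaults to 3
#'   each.
#' @return A `wes_cohort`: list with `participants`, `variants`,
#'   `annotations`, `truth` (intended labels per variant) and `spec`.
#' @export
generate_cohort <- function(spec, match_slots = NULL, filler_diagnoses = NULL) {
  set.seed(spec$seed)
  n <- spec$n_participants
  n_male <- spec$n_male %||% ceiling(n / 2)
  assert_that(n_male >= 0 && n_male <= n, "n_male must lie in [0, n_participants]")
  sex <- c(rep("M", n_male), rep("F", n - n_male))
  cancer_idx <- spec$cancer_idx %||% head(seq_len(n), round(spec$fraction_cancer * n))
  group2_start <- spec$group2_start %||% (n + 1L)
  participants <- tibble(
    sample_id = sprintf("BB%03d", seq_len(n)),
    sex = sex,
    diagnoses = replicate(n, character(), simplify = FALSE),
    has_invasive_cancer = seq_len(n) %in% cancer_idx,
    group = ifelse(seq_len(n) >= group2_start, 2L, 1L)
  )

  cells <- spec$cell_counts |>
    filter(.data$n > 0) |>
    arrange(.data$tier, .data$vclass,
            match(.data$inh_class, WES_INH_CLASSES),
            match(.data$score, WES_SCORES))

  # --- YES-slot allocation -------------------------------------------------
  yes_cells <- filter(cells, .data$score == "YES")
  demands <- tibble(
    cell = rep(seq_len(nrow(yes_cells)), yes_cells$n),
    sex_req = rep(cell_sex_requirement(yes_cells$inh_class, yes_cells$score),
                  yes_cells$n)
  )
  if (is.null(match_slots)) {
    rot_any <- new_rotation(seq_len(n))
    rot_m <- new_rotation(which(sex == "M"))
    rot_f <- new_rotation(which(sex == "F"))
    slot_sample <- integer(nrow(demands))
    for (i in seq_len(nrow(demands))) {
      rot <- switch(demands$sex_req[i], M = rot_m, F = rot_f, rot_any)
      if (length(rot$idx) == 0L) {
        cc <- yes_cells[demands$cell[i], ]
        abort(sprintf("infeasible cell (Tier-%d, %s, %s, %s): no %s participants",
                      cc$tier, cc$vclass, cc$inh_class, cc$score,
                      if (demands$sex_req[i] == "M") "male" else "female"))
      }
      slot_sample[i] <- rotate(rot, 1L)
    }
    slots <- tibble(slot_id = seq_len(nrow(demands)), sample_idx = slot_sample,
                    keyword = sprintf("kw%05d", seq_len(nrow(demands))))
    demands$slot <- slots$slot_id
  } else {
    slots <- tibble(
      slot_id = seq_len(sum(match_slots$n_slots)),
      sample_idx = rep(match_slots$sample_idx, match_slots$n_slots)
    )
    slots$keyword <- sprintf("kw%05d", slots$slot_id)
    slot_sex <- sex[slots$sample_idx]
    used <- rep(FALSE, nrow(slots))
    demands$slot <- NA_integer_
    # Sex-constrained demands claim matching unused slots first.
    for (i in which(demands$sex_req != "any")) {
      ok <- which(!used & slot_sex == demands$sex_req[i])
      if (length(ok) == 0L) ok <- which(slot_sex == demands$sex_req[i])
      if (length(ok) == 0L) {
        cc <- yes_cells[demands$cell[i], ]
        abort(sprintf("infeasible cell (Tier-%d, %s, %s, %s): no %s slot available",
                      cc$tier, cc$vclass, cc$inh_class, cc$score,
                      if (demands$sex_req[i] == "M") "male" else "female"))
      }
      demands$slot[i] <- ok[1]
      used[ok[1]] <- TRUE
    }
    free <- which(!used)
    open <- which(is.na(demands$slot))
    take <- head(free, length(open))
    demands$slot[open[seq_along(take)]] <- take
    used[take] <- TRUE
    # Extra YES variants beyond the slot count reuse slots cyclically.
    left <- which(is.na(demands$slot))
    if (length(left) > 0L) {
      demands$slot[left] <- slots$slot_id[(seq_along(left) - 1L) %% nrow(slots) + 1L]
    }
  }

  # --- variant construction ------------------------------------------------
  rot_any <- new_rotation(seq_len(n))
  rot_m <- new_rotation(which(sex == "M"))
  rot_f <- new_rotation(which(sex == "F"))
  autosomes <- as.character(1:22)
  n_total <- sum(cells$n)
  jitter <- if (n_total > 0) sample.int(999L, n_total, replace = TRUE) else integer()

  gene_no <- 0L
  var_no <- 0L
  variant_rows <- vector("list", nrow(cells))
  gene_rows <- vector("list", nrow(cells))
  truth_rows <- vector("list", nrow(cells))
  yes_taken <- 0L

  for (ci in seq_len(nrow(cells))) {
    cc <- cells[ci, ]
    k <- cc$n
    tier <- cc$tier; vclass <- cc$vclass; class <- cc$inh_class; scr <- cc$score

    conseq <- if (vclass == "SNV") {
      if (tier == 1L) "stop_gained" else "missense"
    } else {
      if (tier == 1L) "frameshift" else "inframe_codon_change"
    }
    ref <- if (vclass == "SNV") "A" else if (tier == 1L) "AC" else "ACCC"
    alt <- if (vclass == "SNV") "G" else "A"
    sift <- if (conseq == "missense") "damaging" else "missing"
    polyphen <- if (conseq == "missense") "benign" else "missing"

    inheritance <- switch(class, SNP_novel = "SNP", SNP_exact = "SNP",
                          OTHERS = "YL", class)
    chrom_pool <- switch(class, XLR = "X", XLD = "X", OTHERS = "Y", autosomes)
    observable <- !(scr == "X" && class %in% c("AD", "AD_AR", "DIGENIC", "XLD"))
    sex_limited <- if (scr == "X" && class %in% c("SNP_novel", "SNP_exact")) {
      "male_only"
    } else "none"
    zygosity <- case_when(
      class == "OTHERS" ~ "hemizygous",
      class == "XLR" & scr %in% c("YES", "NO") ~ "hemizygous",
      class == "AR" & scr == "NO" ~ "homozygous_alt",
      TRUE ~ "heterozygous"
    )

    sex_req <- cell_sex_requirement(class, scr)
    if (scr == "YES") {
      # demands$cell indexes yes_cells rows; recover this cell's demand rows
      yes_cell_idx <- sum(cells$score[seq_len(ci)] == "YES")
      d <- demands[demands$cell == yes_cell_idx, , drop = FALSE]
      carrier <- slots$sample_idx[d$slot]
      keywords <- slots$keyword[d$slot]
    } else {
      rot <- switch(sex_req, M = rot_m, F = rot_f, rot_any)
      if (k > 0L && length(rot$idx) == 0L) {
        abort(sprintf("infeasible cell (Tier-%d, %s, %s, %s): no %s participants",
                      tier, vclass, class, scr,
                      if (sex_req == "M") "male" else "female"))
      }
      carrier <- rotate(rot, k)
      keywords <- NULL
    }

    gene_idx <- gene_no + seq_len(k)
    gene_no <- gene_no + k
    genes <- sprintf("G%05d", gene_idx)
    pos <- 1000000L + (var_no + seq_len(k)) * 1000L + jitter[var_no + seq_len(k)]
    var_no <- var_no + k
    chrom <- rep_len(chrom_pool, k)
    depth <- 50L
    zyg1 <- zygosity[1]  # scalar per cell by construction
    alt_depth <- switch(zyg1,
                        heterozygous = 24L, homozygous_alt = 50L, hemizygous = 47L)

    variant_rows[[ci]] <- tibble(
      sample_id = participants$sample_id[carrier],
      chrom = chrom, pos = pos, ref = ref, alt = alt,
      vclass = vclass, zygosity = rep(zyg1, k),
      map_quality = 60, depth = depth, alt_depth = alt_depth,
      consequence = conseq, sift = sift, polyphen = polyphen,
      gene = genes,
      af_g1000 = 0.01, af_hapmap = NA_real_, af_esp = NA_real_,
      af_danish = NA_real_
    )

    phen <- if (scr == "YES") as.list(keywords) else as.list(sprintf("gp%05d", gene_idx))
    key <- variant_key(chrom, pos, ref, alt)
    gwas <- replicate(k, character(), simplify = FALSE)
    if (class == "SNP_exact") gwas <- as.list(key)
    if (class == "SNP_novel") {
      gwas <- as.list(variant_key(chrom, pos + 1L, ref, alt))
    }
    gene_rows[[ci]] <- tibble(
      gene = genes,
      phenotypes = lapply(phen, as.character),
      has_hgmd_omim_phenotype = TRUE,
      is_non_disease_trait_only = FALSE,
      inheritance = inheritance,
      protective_only = FALSE,
      sex_limited = sex_limited,
      observable_in_emr = TRUE,
      gwas_exact_positions = gwas
    )
    gene_rows[[ci]]$observable_in_emr <- observable

    truth_rows[[ci]] <- tibble(
      key = key, sample_id = participants$sample_id[carrier],
      tier = tier, vclass = vclass, inh_class = class, score = scr,
      is_decoy = FALSE, decoy_rule = NA_character_
    )
  }

  variants <- bind_rows(variant_rows)
  annotations <- bind_rows(gene_rows)
  truth <- bind_rows(truth_rows)

  # Plant each slot keyword once in its participant's diagnosis list, then
  # pad with unique non-matching filler diagnoses.
  for (sl in seq_len(nrow(slots))) {
    i <- slots$sample_idx[sl]
    participants$diagnoses[[i]] <- c(participants$diagnoses[[i]], slots$keyword[sl])
  }
  filler <- filler_diagnoses %||% rep(3L, n)
  assert_that(length(filler) == n,
              "filler_diagnoses must have one entry per participant")
  dx_no <- 0L
  for (i in seq_len(n)) {
    k <- filler[i]
    if (k > 0L) {
      participants$diagnoses[[i]] <-
        c(participants$diagnoses[[i]], sprintf("dx%05d", dx_no + seq_len(k)))
      dx_no <- dx_no + k
    }
  }

  structure(list(participants = participants, variants = variants,
                 annotations = annotations, truth = truth, spec = spec),
            class = "wes_cohort")
}

#' @export
print.wes_cohort <- function(x, ...) {
  cat(sprintf("<wes_cohort> %d participants, %d variant calls, %d annotated genes\n",
              nrow(x$participants), nrow(x$variants), nrow(x$annotations)))
  if (!is.null(x$truth)) {
    cat(sprintf("  truth labels: %d non-decoy, %d decoy rows\n",
                sum(!x$truth$is_decoy), sum(x$truth$is_decoy)))
  }
  invisible(x)
}

#' Spike filter-decoy variants into a cohort
#'
#' Appends variants that each violate exactly one filter rule: mapping
#' quality, depth or alternate-depth below threshold; a common reference
#' allele frequency; cohort-recurrent allele keys placed in just enough
#' samples to reach the recurrence threshold; genes without an HGMD/OMIM
#' phenotype; and non-disease-trait genes.  Truth rows record the violated
#' rule, so tests can verify that the filter removes all decoys and nothing
#' else.
#'
#' @param cohort A `wes_cohort`.
#' @param config The [filter_config()] the decoys should be calibrated
#'   against (thresholds are violated marginally).
#' @param n_quality_fail,n_common_af,n_cohort_recurrent,n_no_phenotype_gene,n_non_disease_trait
#'   Decoy counts; default to the cohort spec's values.
#' @return The cohort with decoys appended.
#' @export
spike_decoys <- function(cohort, config = filter_config(),
                         n_quality_fail = NULL, n_common_af = NULL,
                         n_cohort_recurrent = NULL,
                         n_no_phenotype_gene = NULL,
                         n_non_disease_trait = NULL) {
  spec <- cohort$spec
  n_quality_fail <- n_quality_fail %||% spec$n_quality_fail_decoys %||% 0L
  n_common_af <- n_common_af %||% spec$n_common_af_decoys %||% 0L
  n_cohort_recurrent <- n_cohort_recurrent %||% spec$n_cohort_recurrent_decoys %||% 0L
  n_no_phenotype_gene <- n_no_phenotype_gene %||% spec$n_no_phenotype_gene_decoys %||% 0L
  n_non_disease_trait <- n_non_disease_trait %||% spec$n_non_disease_trait_decoys %||% 0L

  n <- nrow(cohort$participants)
  rot <- new_rotation(seq_len(n))
  gene_no <- nrow(cohort$annotations)
  pos_no <- 0L
  next_gene <- function() {
    gene_no <<- gene_no + 1L
    sprintf("D%05d", gene_no)
  }
  next_pos <- function(k = 1L) {
    out <- 200000000L + (pos_no + seq_len(k)) * 1000L
    pos_no <<- pos_no + k
    out
  }

  base_row <- function(sample_idx, chrom, pos, gene, rule,
                       mq = 60, dp = 50L, ad = 24L, af = 0.01) {
    list(
      variant = tibble(
        sample_id = cohort$participants$sample_id[sample_idx],
        chrom = chrom, pos = pos, ref = "A", alt = "G", vclass = "SNV",
        zygosity = "heterozygous", map_quality = mq, depth = dp, alt_depth = ad,
        consequence = "stop_gained", sift = "missing", polyphen = "missing",
        gene = gene, af_g1000 = af, af_hapmap = NA_real_, af_esp = NA_real_,
        af_danish = NA_real_
      ),
      truth = tibble(
        key = variant_key(chrom, pos, "A", "G"),
        sample_id = cohort$participants$sample_id[sample_idx],
        tier = NA_integer_, vclass = "SNV", inh_class = NA_character_,
        score = NA_character_, is_decoy = TRUE, decoy_rule = rule
      )
    )
  }
  disease_gene <- function(gene, has_pheno = TRUE, trait = FALSE) {
    tibble(gene = gene,
           phenotypes = list(if (has_pheno) paste0("gp", tolower(gene)) else character()),
           has_hgmd_omim_phenotype = has_pheno,
           is_non_disease_trait_only = trait,
           inheritance = "AD", protective_only = FALSE, sex_limited = "none",
           observable_in_emr = TRUE,
           gwas_exact_positions = list(character()))
  }

  pieces <- list()
  add <- function(p) pieces[[length(pieces) + 1L]] <<- p

  if (n_quality_fail > 0L) {
    modes <- rep_len(c("quality_mq", "quality_dp", "quality_altdp"), n_quality_fail)
    for (m in modes) {
      g <- next_gene()
      p <- next_pos()
      row <- switch(m,
        quality_mq = base_row(rotate(rot, 1L), "1", p, g, m,
                              mq = config$min_map_quality - 1),
        quality_dp = base_row(rotate(rot, 1L), "1", p, g, m,
                              dp = as.integer(config$min_depth - 1),
                              ad = min(24L, as.integer(config$min_depth - 1))),
        quality_altdp = base_row(rotate(rot, 1L), "1", p, g, m,
                                 ad = as.integer(config$min_alt_depth - 1))
      )
      add(c(row, list(gene_row = disease_gene(g))))
    }
  }
  for (i in seq_len(n_common_af)) {
    g <- next_gene()
    row <- base_row(rotate(rot, 1L), "2", next_pos(), g, "population_maf",
                    af = min(1, config$max_maf + 0.15))
    add(c(row, list(gene_row = disease_gene(g))))
  }
  if (n_cohort_recurrent > 0L) {
    carriers_needed <- ceiling(config$max_cohort_fraction * n)
    for (i in seq_len(n_cohort_recurrent)) {
      g <- next_gene()
      p <- next_pos()
      carriers <- rotate(rot, carriers_needed)
      rows <- lapply(unique(carriers), function(s)
        base_row(s, "3", p, g, "cohort_frequency"))
      merged <- list(
        variant = bind_rows(lapply(rows, `[[`, "variant")),
        truth = bind_rows(lapply(rows, `[[`, "truth")),
        gene_row = disease_gene(g)
      )
      add(merged)
    }
  }
  for (i in seq_len(n_no_phenotype_gene)) {
    g <- next_gene()
    row <- base_row(rotate(rot, 1L), "4", next_pos(), g, "no_phenotype_gene")
    add(c(row, list(gene_row = disease_gene(g, has_pheno = FALSE))))
  }
  for (i in seq_len(n_non_disease_trait)) {
    g <- next_gene()
    row <- base_row(rotate(rot, 1L), "5", next_pos(), g, "non_disease_trait")
    add(c(row, list(gene_row = disease_gene(g, trait = TRUE))))
  }

  if (length(pieces) > 0L) {
    cohort$variants <- bind_rows(cohort$variants,
                                 bind_rows(lapply(pieces, `[[`, "variant")))
    cohort$truth <- bind_rows(cohort$truth,
                              bind_rows(lapply(pieces, `[[`, "truth")))
    cohort$annotations <- bind_rows(cohort$annotations,
                                    bind_rows(lapply(pieces, `[[`, "gene_row")))
  }
  cohort
}
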