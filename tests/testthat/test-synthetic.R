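# The synthetic-cohort generator and its mutual-oracle relationship with
# the pipeline.

small_cells <- tibble::tibble(
  tier      = c(1L, 1L, 2L, 2L, 1L, 2L, 1L, 2L, 2L),
  vclass    = c("SNV", "SNV", "SNV", "SNV", "INDEL", "INDEL", "SNV", "SNV", "INDEL"),
  inh_class = c("AD", "AR", "AD", "AR", "AD", "SNP_novel", "XLR", "SNP_exact", "OTHERS"),
  score     = c("YES", "X", "NO", "YES", "NO", "NO", "YES", "X", "X"),
  n         = c(3L, 4L, 5L, 2L, 3L, 4L, 1L, 2L, 3L)
)

test_that("an all-zero spec yields participants and no variants", {
  spec <- cohort_spec(n_participants = 5, seed = 1)
  cohort <- generate_cohort(spec)
  expect_equal(nrow(cohort$participants), 5L)
  expect_equal(nrow(cohort$variants), 0L)
  expect_equal(nrow(cohort$truth), 0L)
})

test_that("identical seeds give identical cohorts; seeds never move counts", {
  spec1 <- cohort_spec(n_participants = 12, seed = 5, cell_counts = small_cells)
  spec2 <- cohort_spec(n_participants = 12, seed = 5, cell_counts = small_cells)
  expect_identical(generate_cohort(spec1), generate_cohort(spec2))

  other <- generate_cohort(cohort_spec(n_participants = 12, seed = 99,
                                       cell_counts = small_cells))
  counts1 <- dplyr::count(generate_cohort(spec1)$truth, tier, vclass, inh_class, score)
  counts2 <- dplyr::count(other$truth, tier, vclass, inh_class, score)
  expect_equal(counts1, counts2)
})

test_that("label recovery: the pipeline reproduces any feasible cell spec", {
  spec <- cohort_spec(n_participants = 12, seed = 21, cell_counts = small_cells)
  cohort <- generate_cohort(spec)
  res <- run_pipeline(cohort)
  got <- res$scored |>
    dplyr::count(tier, vclass, inh_class, score, name = "n_got")
  merged <- dplyr::full_join(small_cells, got,
                             by = c("tier", "vclass", "inh_class", "score"))
  expect_true(all(!is.na(merged$n_got)))
  expect_equal(merged$n_got, merged$n)
  expect_equal(nrow(res$scored), sum(small_cells$n))
})

test_that("generated variants pass structural validation", {
  cohort <- generate_cohort(cohort_spec(n_participants = 12, seed = 2,
                                        cell_counts = small_cells))
  expect_silent(validate_variants(cohort$variants))
  expect_silent(validate_gene_annotation(cohort$annotations))
  # every variant's gene is annotated; truth covers exactly the non-decoys
  expect_true(all(cohort$variants$gene %in% cohort$annotations$gene))
  expect_equal(nrow(cohort$truth), nrow(cohort$variants))
})

test_that("infeasible cells are rejected by name", {
  xlr_yes <- tibble::tibble(tier = 1L, vclass = "SNV", inh_class = "XLR",
                            score = "YES", n = 1L)
  spec <- cohort_spec(n_participants = 3, seed = 1, cell_counts = xlr_yes,
                      n_male = 0L)
  expect_error(generate_cohort(spec), "XLR")
  others_no <- tibble::tibble(tier = 1L, vclass = "SNV", inh_class = "OTHERS",
                              score = "NO", n = 1L)
  expect_error(cohort_spec(n_participants = 3, cell_counts = others_no),
               "OTHERS")
})

test_that("every decoy fails exactly its own filter and is eliminated", {
  spec <- cohort_spec(n_participants = 20, seed = 8, cell_counts = small_cells,
                      n_quality_fail_decoys = 6L, n_common_af_decoys = 3L,
                      n_cohort_recurrent_decoys = 2L,
                      n_no_phenotype_gene_decoys = 3L,
                      n_non_disease_trait_decoys = 3L)
  cohort <- spike_decoys(generate_cohort(spec))
  truth <- cohort$truth
  expect_gt(sum(truth$is_decoy), 0L)

  res <- apply_filters(cohort$variants, cohort$annotations, filter_config(),
                       n_samples = 20)
  out <- dplyr::left_join(
    truth,
    dplyr::distinct(res$outcomes, key, sample_id, .keep_all = TRUE),
    by = c("key", "sample_id")
  )
  decoys <- out[out$is_decoy, ]
  expect_true(all(!decoys$passed))
  expect_equal(decoys$failed_rules, decoys$decoy_rule)
  expect_true(all(out$passed[!out$is_decoy]))
  # retained count equals the non-decoy count
  expect_equal(nrow(res$retained), sum(!truth$is_decoy))
})

test_that("removing the violated threshold re-admits the decoy", {
  spec <- cohort_spec(n_participants = 20, seed = 8, cell_counts = small_cells,
                      n_quality_fail_decoys = 3L, n_common_af_decoys = 1L,
                      n_cohort_recurrent_decoys = 1L)
  cohort <- spike_decoys(generate_cohort(spec))
  truth <- cohort$truth
  relaxations <- list(
    quality_mq = filter_config(min_map_quality = 0),
    quality_dp = filter_config(min_depth = 0),
    quality_altdp = filter_config(min_alt_depth = 0),
    population_maf = filter_config(max_maf = 1),
    cohort_frequency = filter_config(max_cohort_fraction = 1)
  )
  for (rule in names(relaxations)) {
    res <- apply_filters(cohort$variants, cohort$annotations,
                         relaxations[[rule]], n_samples = 20)
    readmitted <- variant_key(res$retained$chrom, res$retained$pos,
                              res$retained$ref, res$retained$alt)
    target <- truth$key[!is.na(truth$decoy_rule) & truth$decoy_rule == rule]
    expect_true(all(target %in% readmitted), info = rule)
  }
})

test_that("a decoy-only cohort filters to nothing but reports cleanly", {
  spec <- cohort_spec(n_participants = 10, seed = 4,
                      n_quality_fail_decoys = 3L, n_common_af_decoys = 2L,
                      n_no_phenotype_gene_decoys = 2L)
  cohort <- spike_decoys(generate_cohort(spec))
  res <- run_pipeline(cohort)
  expect_equal(nrow(res$scored), 0L)
  expect_equal(res$crosstab$grand$n_total, 0L)
  expect_equal(res$summary$per_person$mean, 0)
})

test_that("cohort-recurrent decoys sit exactly at the removal threshold", {
  spec <- cohort_spec(n_participants = 89, seed = 6, cell_counts = small_cells,
                      n_cohort_recurrent_decoys = 1L)
  cohort <- spike_decoys(generate_cohort(spec))
  truth <- cohort$truth
  key <- unique(truth$key[!is.na(truth$decoy_rule) &
                            truth$decoy_rule == "cohort_frequency"])
  carriers <- sum(truth$key == key)
  expect_equal(carriers, ceiling(0.1 * 89))  # 9 of 89 trips the 10% rule
  res <- apply_filters(cohort$variants, cohort$annotations, filter_config(),
                       n_samples = 89)
  expect_false(key %in% variant_key(res$retained$chrom, res$retained$pos,
                                    res$retained$ref, res$retained$alt))
})
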