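# The custom filter cascade.

test_that("quality rule uses inclusive thresholds and fails closed", {
  cfg <- filter_config()
  at_threshold <- make_variant(map_quality = 20, depth = 20, alt_depth = 5)
  expect_true(passes_quality(at_threshold, cfg))
  expect_false(passes_quality(make_variant(map_quality = 19, depth = 200,
                                           alt_depth = 80), cfg))
  expect_false(passes_quality(make_variant(map_quality = 60, depth = 20,
                                           alt_depth = 4), cfg))
  expect_false(passes_quality(make_variant(map_quality = NA_real_), cfg))
  expect_false(passes_quality(make_variant(depth = NA_integer_,
                                           alt_depth = NA_integer_), cfg))
})

test_that("INDELs are held only to the alternate-depth rule", {
  cfg <- filter_config()
  indel <- make_variant(ref = "AC", alt = "A", consequence = "frameshift",
                        map_quality = 5, depth = 8, alt_depth = 5)
  expect_true(passes_quality(indel, cfg))
  expect_false(passes_quality(dplyr::mutate(indel, alt_depth = 4L), cfg))
})

test_that("population MAF folds to the minor allele and handles absence", {
  cfg <- filter_config()
  expect_false(passes_population_maf(make_variant(af_g1000 = 0.10), cfg))
  expect_true(passes_population_maf(make_variant(af_g1000 = 0.099), cfg))
  expect_true(passes_population_maf(make_variant(), cfg))          # all absent
  expect_true(passes_population_maf(make_variant(af_g1000 = 0.95), cfg))  # folded 0.05
  expect_false(passes_population_maf(make_variant(af_g1000 = 0.85), cfg)) # folded 0.15
  expect_false(passes_population_maf(make_variant(af_danish = 0.5), cfg)) # any panel
  expect_error(passes_population_maf(make_variant(af_g1000 = 1.2), cfg), "outside")
})

test_that("consulted panels are configurable", {
  cfg <- filter_config(reference_panels = c("g1000", "hapmap"))
  v <- make_variant(af_danish = 0.5)
  expect_true(passes_population_maf(v, cfg))
})

test_that("gene-phenotype rule needs a listed disease phenotype", {
  ann <- dplyr::bind_rows(
    make_gene("DISEASE", "Eczema"),
    make_gene("NOPHENO", character(), has_pheno = FALSE),
    make_gene("TRAIT", "Hair colour", trait_only = TRUE)
  )
  expect_true(passes_gene_phenotype(make_variant(gene = "DISEASE"), ann))
  expect_false(passes_gene_phenotype(make_variant(gene = "ABSENT"), ann))
  expect_false(passes_gene_phenotype(make_variant(gene = "NOPHENO"), ann))
  expect_false(passes_gene_phenotype(make_variant(gene = "TRAIT"), ann))
})

test_that("cohort filter threshold matches the 10%-of-89 example", {
  cfg <- filter_config()
  key9 <- dplyr::bind_rows(lapply(1:9, function(i)
    make_variant(sample_id = sprintf("S%02d", i), pos = 5000)))
  key8 <- dplyr::bind_rows(lapply(1:8, function(i)
    make_variant(sample_id = sprintf("S%02d", i), pos = 6000)))
  res <- cohort_frequency_filter(dplyr::bind_rows(key9, key8), 89, cfg)
  expect_true(all(res$removed$pos == 5000))
  expect_true(all(res$retained$pos == 6000))
  expect_equal(nrow(res$removed), 9L)
  expect_equal(nrow(res$retained), 8L)
  empty <- cohort_frequency_filter(make_variant()[0, ], 89, cfg)
  expect_equal(nrow(empty$retained), 0L)
  expect_equal(nrow(empty$removed), 0L)
})

test_that("carrier counting agrees with a brute-force per-key scan", {
  set.seed(42)
  n_samples <- 25
  v <- dplyr::bind_rows(lapply(1:400, function(i) {
    make_variant(sample_id = sprintf("S%02d", sample.int(n_samples, 1)),
                 pos = 1000L + 100L * sample.int(30, 1))
  }))
  cfg <- filter_config(max_cohort_fraction = 0.2)
  res <- cohort_frequency_filter(v, n_samples, cfg)
  keys <- variant_key(v$chrom, v$pos, v$ref, v$alt)
  brute_removed <- vapply(seq_len(nrow(v)), function(i) {
    carriers <- unique(v$sample_id[keys == keys[i]])
    length(carriers) / n_samples >= cfg$max_cohort_fraction
  }, logical(1))
  got_removed <- keys %in% variant_key(res$removed$chrom, res$removed$pos,
                                       res$removed$ref, res$removed$alt)
  expect_equal(got_removed, brute_removed)
  expect_equal(nrow(res$retained) + nrow(res$removed), nrow(v))
})

test_that("apply_filters partitions input and records ordered rules", {
  ann <- dplyr::bind_rows(make_gene("OKGENE", "Eczema"),
                          make_gene("TRAIT", "Hair colour", trait_only = TRUE))
  v <- dplyr::bind_rows(
    make_variant(sample_id = "S1", pos = 1000, gene = "OKGENE"),
    make_variant(sample_id = "S1", pos = 2000, gene = "TRAIT",
                 map_quality = 10, af_g1000 = 0.5),
    make_variant(sample_id = "S1", pos = 3000, gene = "MISSING")
  )
  res <- apply_filters(v, ann, filter_config(), n_samples = 50)
  expect_equal(res$outcomes$passed, c(TRUE, FALSE, FALSE))
  expect_equal(res$outcomes$failed_rules[1], "")
  expect_equal(res$outcomes$failed_rules[2],
               "quality_mq,population_maf,non_disease_trait")
  expect_equal(res$outcomes$failed_rules[3], "no_phenotype_gene")
  expect_equal(nrow(res$retained) + sum(!res$outcomes$passed), nrow(v))
})

test_that("raising thresholds never grows the retained set (monotonicity)", {
  fx <- cached_fixture()
  base_cfg <- filter_config()
  base <- apply_filters(fx$variants, fx$annotations, base_cfg, 89)
  base_keys <- with(base$retained, paste(sample_id, chrom, pos, alt))
  tighter <- list(
    filter_config(min_map_quality = 70),
    filter_config(min_depth = 60),
    filter_config(min_alt_depth = 30),
    filter_config(max_maf = 0.005),
    filter_config(max_cohort_fraction = 0.01)
  )
  for (cfg in tighter) {
    res <- apply_filters(fx$variants, fx$annotations, cfg, 89)
    keys <- with(res$retained, paste(sample_id, chrom, pos, alt))
    expect_true(all(keys %in% base_keys))
    expect_lte(nrow(res$retained), nrow(base$retained))
  }
})

test_that("relaxing every threshold leaves only the gene-phenotype rules", {
  fx <- cached_fixture()
  cfg <- filter_config(min_map_quality = 0, min_depth = 0, min_alt_depth = 0,
                       max_maf = 1, max_cohort_fraction = 1)
  res <- apply_filters(fx$variants, fx$annotations, cfg, 89)
  failed <- res$outcomes$failed_rules[!res$outcomes$passed]
  expect_true(all(failed %in% c("no_phenotype_gene", "non_disease_trait")))
})
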