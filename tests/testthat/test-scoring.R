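# Inheritance assignment and Yes/No/X scoring.

tiered <- function(...) classify_all(make_variant(...))

test_that("phenotype overlap matches on keywords and lexicon synonyms", {
  expect_true(phenotype_overlap("Eczema", "Eczema"))
  expect_true(phenotype_overlap(
    c("Progressive symmetric erythrokeratodermia of Gottron", "Deafness"),
    "Hearing loss"))
  expect_true(phenotype_overlap(
    "Arrhythmogenic right ventricular cardiomyopathy",
    "Ventricular tachycardia"))
  expect_true(phenotype_overlap("Osteoarthritis", "Degenerative joint disease"))
  expect_true(phenotype_overlap("Nephropathy", "Chronic renal failure"))
  expect_false(phenotype_overlap("Eczema", "Gout"))
  expect_false(phenotype_overlap("Eczema", character()))
  # generic filler words must not create matches
  expect_false(phenotype_overlap("Fabry disease", "Coronary artery disease"))
})

test_that("lexicon overlap is symmetric", {
  pairs <- list(c("Deafness", "Hearing loss"),
                c("Glaucoma suspect", "Glaucoma"),
                c("Abdominal aortic aneurysm", "Aneurysms"),
                c("Eczema", "Psoriasis"))
  for (p in pairs) {
    expect_equal(phenotype_overlap(p[1], p[2]), phenotype_overlap(p[2], p[1]),
                 info = paste(p, collapse = " / "))
  }
})

test_that("inheritance classes pass through with SNP subdivision", {
  v <- tiered(gene = "G1", consequence = "stop_gained", sift = "missing",
              chrom = "1", pos = 1000)
  key <- variant_key("1", 1000L, "A", "G")
  for (code in c("AD", "AD_AR", "AR", "DIGENIC")) {
    ann <- make_gene("G1", "Eczema", inheritance = code)
    expect_equal(assign_inheritance(v, ann)$inh_class, code)
  }
  snp_exact <- make_gene("G1", "Eczema", inheritance = "SNP", gwas = key)
  expect_equal(assign_inheritance(v, snp_exact)$inh_class, "SNP_exact")
  snp_novel <- make_gene("G1", "Eczema", inheritance = "SNP",
                         gwas = variant_key("1", 999L, "A", "G"))
  expect_equal(assign_inheritance(v, snp_novel)$inh_class, "SNP_novel")
  yl <- make_gene("G1", "Eczema", inheritance = "YL")
  expect_equal(assign_inheritance(v, yl)$inh_class, "OTHERS")
  prot <- make_gene("G1", "Eczema", protective = TRUE)
  expect_equal(assign_inheritance(v, prot)$inh_class, "OTHERS")
  unobs_snp <- make_gene("G1", "Eczema", inheritance = "SNP",
                         observable = FALSE, gwas = key)
  expect_equal(assign_inheritance(v, unobs_snp)$inh_class, "OTHERS")
  unobs_ad <- make_gene("G1", "Eczema", observable = FALSE)
  expect_equal(assign_inheritance(v, unobs_ad)$inh_class, "AD")
  expect_error(assign_inheritance(v, make_gene("OTHERGENE")), "unannotated")
})

score_one <- function(variant, gene, participant) {
  score_cohort(classify_all(variant), gene, participant)
}

test_that("the decision cascade reproduces the published X examples", {
  # monoallelic change in a recessive gene
  ar <- score_one(make_variant(gene = "G1", consequence = "stop_gained",
                               sift = "missing"),
                  make_gene("G1", "Cystinosis", inheritance = "AR"),
                  make_participant("S1", diagnoses = "Gout"))
  expect_equal(ar$score, "X")
  expect_equal(ar$reason, "monoallelic_recessive")

  # prostate-cancer gene variant found in a woman
  sexed <- score_one(make_variant(gene = "G1", consequence = "stop_gained",
                                  sift = "missing"),
                     make_gene("G1", "Prostate cancer", sex_limited = "male_only"),
                     make_participant("S1", sex = "F", diagnoses = "Prostate cancer"))
  expect_equal(sexed$score, "X")
  expect_equal(sexed$reason, "sex_incompatible")

  # abnormal sperm shape: not observable on typical medical visits
  unobs <- score_one(make_variant(gene = "G1", consequence = "stop_gained",
                                  sift = "missing"),
                     make_gene("G1", "Abnormal sperm morphology",
                               observable = FALSE),
                     make_participant("S1", diagnoses = "Gout"))
  expect_equal(unobs$score, "X")
  expect_equal(unobs$reason, "unobservable_phenotype")

  # variants that reduce risk
  prot <- score_one(make_variant(gene = "G1", consequence = "stop_gained",
                                 sift = "missing"),
                    make_gene("G1", "Reduced risk of asthma", protective = TRUE),
                    make_participant("S1", diagnoses = "Asthma"))
  expect_equal(prot$score, "X")
  expect_equal(prot$reason, "others_category")
})

test_that("overlap precedes the monoallelic rule (AR carriers can score YES)", {
  yes <- score_one(make_variant(gene = "G1", consequence = "stop_gained",
                                sift = "missing"),
                   make_gene("G1", "Eczema", inheritance = "AR"),
                   make_participant("S1", diagnoses = "Eczema"))
  expect_equal(yes$score, "YES")
  expect_equal(yes$reason, "phenotype_overlap")
  expect_equal(yes$matched_phenotype, "Eczema")
})

test_that("AR heterozygotes never score NO", {
  set.seed(7)
  diagnoses <- c("Eczema", "Gout", "Asthma", "Cataract")
  for (i in 1:20) {
    dx <- sample(diagnoses, sample.int(3, 1))
    ph <- sample(diagnoses, 1)
    out <- score_one(make_variant(gene = "G1", consequence = "stop_gained",
                                  sift = "missing"),
                     make_gene("G1", ph, inheritance = "AR"),
                     make_participant("S1", diagnoses = dx))
    expect_true(out$score %in% c("YES", "X"))
  }
})

test_that("biallelic evidence makes recessive-gene variants assessable", {
  gene <- make_gene("G1", "Cystinosis", inheritance = "AR")
  p <- make_participant("S1", diagnoses = "Gout")
  hom <- score_one(make_variant(gene = "G1", consequence = "stop_gained",
                                sift = "missing", zygosity = "homozygous_alt",
                                alt_depth = 50), gene, p)
  expect_equal(hom$score, "NO")
  two <- score_cohort(classify_all(dplyr::bind_rows(
    make_variant(gene = "G1", pos = 1000, consequence = "stop_gained", sift = "missing"),
    make_variant(gene = "G1", pos = 2000, consequence = "stop_gained", sift = "missing")
  )), gene, p)
  expect_equal(two$score, c("NO", "NO"))
})

test_that("X-linked recessive scoring depends on sex and zygosity", {
  gene <- make_gene("G1", "Haemophilia", inheritance = "XLR")
  hemi_m <- score_one(make_variant(gene = "G1", chrom = "X",
                                   consequence = "stop_gained", sift = "missing",
                                   zygosity = "hemizygous", alt_depth = 47),
                      gene, make_participant("S1", sex = "M", diagnoses = "Gout"))
  expect_equal(hemi_m$score, "NO")
  het_f <- score_one(make_variant(gene = "G1", chrom = "X",
                                  consequence = "stop_gained", sift = "missing"),
                     gene, make_participant("S1", sex = "F", diagnoses = "Gout"))
  expect_equal(het_f$score, "X")
  expect_equal(het_f$reason, "monoallelic_recessive")
  match_f <- score_one(make_variant(gene = "G1", chrom = "X",
                                    consequence = "stop_gained", sift = "missing"),
                       gene, make_participant("S1", sex = "F",
                                              diagnoses = "Haemophilia"))
  expect_equal(match_f$score, "YES")
})

test_that("digenic variants use the dominant-style rules", {
  out <- score_one(make_variant(gene = "G1", consequence = "stop_gained",
                                sift = "missing"),
                   make_gene("G1", "Deafness", inheritance = "DIGENIC"),
                   make_participant("S1", diagnoses = "Gout"))
  expect_equal(out$score, "NO")
})

test_that("scoring totals satisfy YES+NO+X = n for every cell", {
  run <- cached_run()
  tab <- run$crosstab$cells
  expect_true(all(tab$n == tab$n_yes + tab$n_no + tab$n_x))
  pt <- run$crosstab$panel_totals
  expect_true(all(pt$n == pt$n_yes + pt$n_no + pt$n_x))
})

test_that("scoring is invariant to cohort row order", {
  fx <- cached_fixture()
  run <- cached_run()
  set.seed(99)
  idx <- sample.int(nrow(fx$variants))
  filt <- apply_filters(fx$variants[idx, ], fx$annotations, filter_config(),
                        n_samples = 89)
  scored <- score_cohort(classify_all(filt$retained), fx$annotations,
                         fx$participants)
  a <- dplyr::arrange(run$scored, sample_id, chrom, pos, alt)
  b <- dplyr::arrange(scored, sample_id, chrom, pos, alt)
  expect_equal(as.data.frame(b), as.data.frame(a))
})

test_that("a cohort without diagnoses scores zero YES", {
  spec <- cohort_spec(
    n_participants = 4, seed = 3,
    cell_counts = tibble::tibble(tier = 2L, vclass = "SNV", inh_class = "AD",
                                 score = "NO", n = 6L)
  )
  cohort <- generate_cohort(spec, filler_diagnoses = rep(0L, 4))
  res <- run_pipeline(cohort)
  expect_equal(res$crosstab$grand$n_yes, 0L)
})

test_that("phenotype-centric view uses set semantics per diagnosis", {
  ann <- dplyr::bind_rows(
    make_gene("G1", "Eczema", inheritance = "AD"),
    make_gene("G2", "Eczema", inheritance = "AD")
  )
  p <- make_participant("S1", diagnoses = c("Eczema", "Gout"))
  scored <- score_cohort(classify_all(dplyr::bind_rows(
    make_variant(gene = "G1", pos = 1000),
    make_variant(gene = "G2", pos = 2000)
  )), ann, p)
  view <- phenotype_centric_view(scored, p, ann)
  expect_equal(view$n_matched, 1L)   # one diagnosis, two matching variants
  expect_equal(view$per_participant$n_phenotypes, 2L)
  expect_equal(view$per_participant$matched[[1]], "Eczema")

  none <- phenotype_centric_view(scored[0, ], p, ann)
  expect_equal(none$n_matched, 0L)
  expect_equal(none$n_participants_no_match, 1L)
})
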