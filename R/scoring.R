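# Inheritance-class assignment and Yes/No/X genotype-phenotype correlation
# scoring.  The manual side-by-side chart comparison is codified as
# normalized-keyword overlap between a gene's reported phenotype strings and
# a participant's diagnosis list, optionally bridged by a synonym lexicon.

# Generic tokens that would cause spurious matches between unrelated
# conditions ("... disease" vs "... disease") are treated as stopwords.
WES_STOPWORDS <- c(
  "a", "an", "and", "at", "by", "due", "for", "in", "of", "on", "or", "the",
  "to", "with", "without", "type", "disease", "disorder", "syndrome",
  "association", "associated", "susceptibility", "increased", "reduced",
  "risk", "familial", "hereditary", "onset", "early", "late", "primary",
  "chronic", "acute"
)

#' Default phenotype-synonym lexicon
#'
#' Synonym sets bridging clinically equivalent wordings that plain keyword
#' overlap would miss (e.g. "deafness" vs "hearing loss").  Each element is a
#' character vector of mutually synonymous phrases; matching is symmetric.
#'
#' @return A named list of character vectors (class `wes_lexicon`).
#' @export
default_lexicon <- function() {
  structure(list(
    hearing_loss = c("deafness", "hearing loss", "hearing impairment"),
    arvc = c("ventricular tachycardia", "arrhythmogenic right ventricular cardiomyopathy"),
    glaucoma = c("glaucoma", "glaucoma suspect", "open angle glaucoma"),
    nephropathy = c("nephropathy", "chronic renal failure", "renal failure",
                    "chronic kidney disease"),
    aneurysm = c("aneurysm", "aneurysms", "abdominal aortic aneurysm",
                 "aortic aneurysm"),
    osteoarthritis = c("osteoarthritis", "degenerative joint disease")
  ), class = "wes_lexicon")
}

#' Write / read a synonym lexicon as JSON
#'
#' @param lexicon A lexicon (named list of synonym character vectors).
#' @param path File path.
#' @return `read_lexicon()` returns a `wes_lexicon`.
#' @export
write_lexicon <- function(lexicon, path) {
  jsonlite::write_json(unclass(lexicon), path)
  invisible(path)
}

#' @rdname write_lexicon
#' @export
read_lexicon <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE), class = "wes_lexicon")
}

normalize_tokens <- function(x) {
  x <- str_to_lower(x)
  x <- gsub("[^a-z0-9 ]", " ", x)
  toks <- unlist(strsplit(str_squish(x), " ", fixed = TRUE))
  setdiff(toks, WES_STOPWORDS)
}

# Token set of a bag of free-text strings, augmented with one marker token
# per lexicon synonym set whose member phrase occurs (all of its non-stopword
# tokens present) in any of the strings.
text_tokens <- function(strings, lexicon) {
  toks <- unique(unlist(lapply(strings, normalize_tokens)))
  if (length(toks) == 0L) return(character())
  markers <- character()
  for (i in seq_along(lexicon)) {
    phrases <- lexicon[[i]]
    for (p in phrases) {
      ptoks <- normalize_tokens(p)
      if (length(ptoks) > 0L && all(ptoks %in% toks)) {
        markers <- c(markers, paste0(".lex_", names(lexicon)[i] %||% i))
        break
      }
    }
  }
  c(toks, markers)
}

#' Keyword overlap between gene phenotypes and participant diagnoses
#'
#' Strings are lowercased, stripped of punctuation and stopwords, and split
#' into tokens; the gene's phenotype descriptions overlap the diagnosis list
#' iff they share any token, either directly or through a common lexicon
#' synonym set.  Matching is gene-level and symmetric.
#'
#' @param phenotypes Character vector of gene phenotype descriptions.
#' @param diagnoses Character vector of participant diagnoses.
#' @param lexicon A synonym lexicon ([default_lexicon()]).
#' @return TRUE iff any keyword is shared.
#' @examples
#' phenotype_overlap("Eczema", "Eczema")
#' phenotype_overlap("Deafness", "Hearing loss")
#' @export
phenotype_overlap <- function(phenotypes, diagnoses, lexicon = default_lexicon()) {
  length(intersect(text_tokens(phenotypes, lexicon),
                   text_tokens(diagnoses, lexicon))) > 0L
}

#' Assign inheritance classes to tiered variants
#'
#' Mendelian inheritance modes (AD, AD/AR, AR, XLR, XLD, digenic) pass
#' through unchanged.  GWAS-association-only (SNP) genes are subdivided by
#' whether the variant coincides with a listed associated position
#' (`SNP_exact`) or is a different variant of the same gene (`SNP_novel`).
#' Y-linked genes, protective-only genes, and non-Mendelian genes whose
#' phenotype is not observable in a typical medical record fold into
#' `OTHERS`.
#'
#' @param tiered Tiered variant tibble ([classify_all()]).
#' @param annotations Gene-annotation tibble; every gene must be annotated.
#' @return The input with an `inh_class` column.
#' @export
assign_inheritance <- function(tiered, annotations) {
  idx <- match(tiered$gene, annotations$gene)
  assert_that(!anyNA(idx), "unannotated gene(s): %s",
              paste(unique(tiered$gene[is.na(idx)]), collapse = ", "))
  inheritance <- annotations$inheritance[idx]
  protective <- annotations$protective_only[idx]
  observable <- annotations$observable_in_emr[idx]
  key <- variant_key(tiered$chrom, tiered$pos, tiered$ref, tiered$alt)
  gwas_hit <- map2_lgl(annotations$gwas_exact_positions[idx], key,
                       function(gw, k) k %in% gw)
  inh_class <- case_when(
    inheritance == "YL" ~ "OTHERS",
    protective ~ "OTHERS",
    !observable & !inheritance %in% WES_MENDELIAN_CODES ~ "OTHERS",
    inheritance == "SNP" & gwas_hit ~ "SNP_exact",
    inheritance == "SNP" ~ "SNP_novel",
    TRUE ~ inheritance
  )
  mutate(tiered, inh_class = inh_class)
}

#' Score genotype-phenotype correlation for a cohort
#'
#' Applies the Yes/No/X decision cascade to every tiered variant:
#' \enumerate{
#'   \item `OTHERS` class (Y-linked, protective-only, unobservable
#'     non-Mendelian genes) cannot be assessed;
#'   \item protective-only genes cannot be assessed (risk-reducing variants);
#'   \item a sex-limited gene carried by the incompatible sex (e.g. a
#'     prostate-cancer gene in a woman) cannot be assessed;
#'   \item a gene whose phenotype is not observable in a typical medical
#'     record cannot be assessed;
#'   \item keyword overlap between the gene's reported phenotypes and the
#'     carrier's diagnoses scores YES;
#'   \item a monoallelic variant in a recessive gene (heterozygous in AR, or
#'     heterozygous in XLR in a female) cannot be assessed -- unless the
#'     same participant carries a homozygous or second distinct variant in
#'     that gene, which makes the gene's variants assessable;
#'   \item otherwise NO.
#' }
#' Overlap (rule 5) deliberately precedes the monoallelic rule (6) so that
#' matching carriers of recessive-gene variants score YES; consequently AR
#' heterozygotes never score NO.
#'
#' @param tiered Tiered variant tibble (with or without `inh_class`; it is
#'   assigned if absent).
#' @param annotations Gene-annotation tibble.
#' @param participants Participant tibble; every `sample_id` in `tiered`
#'   must appear.
#' @param lexicon Synonym lexicon for phenotype matching.
#' @return The tiered tibble with columns `inh_class`, `score`
#'   (YES/NO/X), `reason`, and `matched_phenotype` (first overlapping gene
#'   phenotype for YES rows).
#' @export
score_cohort <- function(tiered, annotations, participants,
                         lexicon = default_lexicon()) {
  if (!"inh_class" %in% names(tiered)) {
    tiered <- assign_inheritance(tiered, annotations)
  }
  pidx <- match(tiered$sample_id, participants$sample_id)
  assert_that(!anyNA(pidx), "variant sample id(s) with no participant record: %s",
              paste(unique(tiered$sample_id[is.na(pidx)]), collapse = ", "))
  gidx <- match(tiered$gene, annotations$gene)
  assert_that(!anyNA(gidx), "unannotated gene(s): %s",
              paste(unique(tiered$gene[is.na(gidx)]), collapse = ", "))

  gene_tok <- lapply(annotations$phenotypes, text_tokens, lexicon = lexicon)
  diag_tok <- lapply(participants$diagnoses, text_tokens, lexicon = lexicon)
  overlap <- map2_lgl(gene_tok[gidx], diag_tok[pidx],
                      function(g, d) length(intersect(g, d)) > 0L)

  sex <- participants$sex[pidx]
  sex_limited <- annotations$sex_limited[gidx]
  sex_incompatible <- (sex_limited == "male_only" & sex == "F") |
    (sex_limited == "female_only" & sex == "M")
  protective <- annotations$protective_only[gidx]
  observable <- annotations$observable_in_emr[gidx]

  # Biallelic evidence: homozygous genotype, or >= 2 distinct variant keys of
  # the same gene in the same participant (potential compound heterozygote).
  biallelic <- tiered |>
    mutate(key = variant_key(.data$chrom, .data$pos, .data$ref, .data$alt)) |>
    group_by(.data$sample_id, .data$gene) |>
    mutate(.biallelic = n_distinct(.data$key) >= 2L |
             any(.data$zygosity == "homozygous_alt")) |>
    ungroup() |>
    pull(".biallelic")

  monoallelic <- !biallelic & tiered$zygosity == "heterozygous" &
    (tiered$inh_class == "AR" | (tiered$inh_class == "XLR" & sex == "F"))

  score <- case_when(
    tiered$inh_class == "OTHERS" ~ "X",
    protective ~ "X",
    sex_incompatible ~ "X",
    !observable ~ "X",
    overlap ~ "YES",
    monoallelic ~ "X",
    TRUE ~ "NO"
  )
  reason <- case_when(
    tiered$inh_class == "OTHERS" ~ "others_category",
    protective ~ "protective_variant",
    sex_incompatible ~ "sex_incompatible",
    !observable ~ "unobservable_phenotype",
    overlap ~ "phenotype_overlap",
    monoallelic ~ "monoallelic_recessive",
    TRUE ~ "no_overlap"
  )
  matched <- rep(NA_character_, nrow(tiered))
  yes_rows <- which(score == "YES")
  for (i in yes_rows) {
    phen <- annotations$phenotypes[[gidx[i]]]
    hit <- vapply(phen, function(p) {
      length(intersect(text_tokens(p, lexicon), diag_tok[[pidx[i]]])) > 0L
    }, logical(1))
    matched[i] <- if (any(hit)) phen[hit][1] else NA_character_
  }
  mutate(tiered, score = score, reason = reason, matched_phenotype = matched)
}

#' Phenotype-centric view of the scored cohort
#'
#' Reverses the correlation question: starting from each participant's
#' diagnosis list, a diagnosis counts as matched if at least one of the
#' participant's YES-scored variants overlaps it (set semantics: a diagnosis
#' matched by several variants counts once).
#'
#' @param scored Scored variant tibble ([score_cohort()]).
#' @param participants Participant tibble.
#' @param annotations Gene-annotation tibble.
#' @param lexicon Synonym lexicon.
#' @return A list with `per_participant` (tibble: `sample_id`,
#'   `n_phenotypes`, `n_matched`, `matched` list-column), and cohort totals
#'   `n_phenotypes`, `n_matched`, `n_participants_no_match`.
#' @export
phenotype_centric_view <- function(scored, participants, annotations,
                                   lexicon = default_lexicon()) {
  yes <- filter(scored, .data$score == "YES")
  gidx <- match(yes$gene, annotations$gene)
  per <- lapply(seq_len(nrow(participants)), function(i) {
    sid <- participants$sample_id[[i]]
    dx <- participants$diagnoses[[i]]
    genes <- unique(gidx[yes$sample_id == sid])
    tok_sets <- lapply(annotations$phenotypes[genes], text_tokens, lexicon = lexicon)
    matched <- vapply(dx, function(d) {
      dt <- text_tokens(d, lexicon)
      any(vapply(tok_sets, function(g) length(intersect(g, dt)) > 0L, logical(1)))
    }, logical(1))
    tibble(sample_id = sid, n_phenotypes = length(dx),
           n_matched = sum(matched), matched = list(dx[matched]))
  })
  per <- bind_rows(per)
  list(
    per_participant = per,
    n_phenotypes = sum(per$n_phenotypes),
    n_matched = sum(per$n_matched),
    n_participants_no_match = sum(per$n_matched == 0L)
  )
}
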