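# Tabular I/O: variant-annotation sidecar, gene annotation, participants,
# panel files, scored-result tables, and whole-cohort read/write.

split_pipe <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) character() else str_trim(strsplit(s, "|", fixed = TRUE)[[1]])
  })
}

join_pipe <- function(x) vapply(x, paste, character(1), collapse = "|")

split_csv <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) character() else str_trim(strsplit(s, ",", fixed = TRUE)[[1]])
  })
}

#' Read / write the per-variant annotation sidecar
#'
#' A TSV keyed by `(chrom, pos, ref, alt, gene)` carrying the functional
#' annotations that an external annotation engine would provide: consequence
#' class, SIFT/PolyPhen calls and per-panel population allele frequencies.
#'
#' @param path File path.
#' @return A tibble with columns `chrom, pos, ref, alt, gene, consequence,
#'   sift, polyphen` and one `af_<panel>` column per reference panel.
#' @export
read_variant_annotation <- function(path) {
  ann <- read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("chrom", "pos", "ref", "alt", "gene", "consequence", "sift", "polyphen")
  missing <- setdiff(required, names(ann))
  assert_that(length(missing) == 0L,
              "variant annotation is missing columns: %s", paste(missing, collapse = ", "))
  bad <- setdiff(unique(ann$consequence), WES_CONSEQUENCES)
  assert_that(length(bad) == 0L,
              "unknown consequence value(s): %s (allowed: %s)",
              paste(bad, collapse = ", "), paste(WES_CONSEQUENCES, collapse = ", "))
  ann$chrom <- as.character(ann$chrom)
  ann$pos <- as.integer(ann$pos)
  as_tibble(ann)
}

#' @rdname read_variant_annotation
#' @param annotation The annotation tibble to write.
#' @export
write_variant_annotation <- function(annotation, path) {
  write_tsv(annotation, path, progress = FALSE)
  invisible(path)
}

#' Attach sidecar annotations to raw VCF calls
#'
#' Left-joins calls with the variant-annotation table by
#' `(chrom, pos, ref, alt)`; a variant annotated against several genes yields
#' one row per gene, matching the per-(variant, gene) granularity of the
#' downstream filters.
#'
#' @param calls Output of [read_vcf()] (possibly several samples).
#' @param annotation Output of [read_variant_annotation()].
#' @return An annotated variant tibble.
#' @export
annotate_variants <- function(calls, annotation) {
  out <- left_join(calls, annotation, by = c("chrom", "pos", "ref", "alt"))
  for (col in af_cols()) {
    if (!col %in% names(out)) out[[col]] <- NA_real_
  }
  if (!"consequence" %in% names(out)) out$consequence <- NA_character_
  out
}

#' Read a gene-annotation table
#'
#' One row per gene, emulating curated HGMD/OMIM gene records: pipe-delimited
#' phenotype descriptions, a disease-phenotype flag, a non-disease-trait
#' flag, the inheritance mode assigned to disorders of the gene (one of
#' AD, AD_AR, AR, XLR, XLD, YL, SNP, DIGENIC), protective-only and
#' sex-limited flags, whether the phenotype is observable in a typical
#' medical record, and (for GWAS-SNP-only genes) the comma-delimited
#' `chrom:pos:ref:alt` keys of the exact associated variants.
#'
#' @param path File path.
#' @return A tibble with list-columns `phenotypes` and `gwas_exact_positions`.
#' @export
read_gene_annotation <- function(path) {
  g <- read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("gene", "phenotypes", "has_hgmd_omim_phenotype",
                "is_non_disease_trait_only", "inheritance", "protective_only",
                "sex_limited", "observable_in_emr", "gwas_exact_positions")
  missing <- setdiff(required, names(g))
  assert_that(length(missing) == 0L,
              "gene annotation is missing columns: %s", paste(missing, collapse = ", "))
  dup <- g$gene[duplicated(g$gene)]
  assert_that(length(dup) == 0L,
              "duplicated gene symbol(s) in gene annotation: %s",
              paste(unique(dup), collapse = ", "))
  bad <- setdiff(unique(g$inheritance), WES_INHERITANCE_CODES)
  assert_that(length(bad) == 0L,
              "unknown inheritance code(s): %s (allowed: %s)",
              paste(bad, collapse = ", "), paste(WES_INHERITANCE_CODES, collapse = ", "))
  g$phenotypes <- split_pipe(as.character(g$phenotypes))
  g$gwas_exact_positions <- split_csv(as.character(g$gwas_exact_positions))
  g$sex_limited <- replace_na(as.character(g$sex_limited), "none")
  assert_that(all(g$sex_limited %in% c("none", "male_only", "female_only")),
              "sex_limited must be none, male_only or female_only")
  validate_gene_annotation(as_tibble(g))
}

validate_gene_annotation <- function(g) {
  no_pheno <- !g$has_hgmd_omim_phenotype & lengths(g$phenotypes) > 0L
  assert_that(!any(no_pheno),
              "gene(s) without an HGMD/OMIM phenotype flag carry phenotype strings: %s",
              paste(g$gene[no_pheno], collapse = ", "))
  bad_gwas <- lengths(g$gwas_exact_positions) > 0L & g$inheritance != "SNP"
  assert_that(!any(bad_gwas),
              "gwas_exact_positions set for non-SNP gene(s): %s",
              paste(g$gene[bad_gwas], collapse = ", "))
  g
}

#' @rdname read_gene_annotation
#' @param genes The gene-annotation tibble to write.
#' @export
write_gene_annotation <- function(genes, path) {
  out <- genes
  out$phenotypes <- join_pipe(out$phenotypes)
  out$gwas_exact_positions <- vapply(out$gwas_exact_positions, paste,
                                     character(1), collapse = ",")
  write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a participant table
#'
#' @param path File path to a TSV with columns `sample_id, sex, diagnoses,
#'   has_invasive_cancer, group`.
#' @param diagnosis_sep Separator of the free-text diagnosis list
#'   (default `";"`).
#' @return A tibble with a `diagnoses` list-column, in file order.
#' @export
read_participants <- function(path, diagnosis_sep = ";") {
  p <- read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("sample_id", "sex", "diagnoses", "has_invasive_cancer", "group")
  missing <- setdiff(required, names(p))
  assert_that(length(missing) == 0L,
              "participant table is missing columns: %s", paste(missing, collapse = ", "))
  dup <- p$sample_id[duplicated(p$sample_id)]
  assert_that(length(dup) == 0L,
              "duplicated sample id(s): %s", paste(unique(dup), collapse = ", "))
  sex <- toupper(substr(str_trim(as.character(p$sex)), 1, 1))
  assert_that(all(sex %in% c("M", "F")),
              "unparseable sex value(s): %s",
              paste(unique(p$sex[!sex %in% c("M", "F")]), collapse = ", "))
  p$sex <- sex
  p$diagnoses <- lapply(as.character(p$diagnoses), function(s) {
    if (is.na(s) || !nzchar(s)) character()
    else str_trim(strsplit(s, diagnosis_sep, fixed = TRUE)[[1]])
  })
  as_tibble(p)
}

#' @rdname read_participants
#' @param participants The participant tibble to write.
#' @export
write_participants <- function(participants, path, diagnosis_sep = ";") {
  out <- participants
  out$diagnoses <- vapply(out$diagnoses, paste, character(1), collapse = diagnosis_sep)
  write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a gene-panel definition
#'
#' Panel files list one gene symbol per line; `#` starts a comment.
#'
#' @param path File path.
#' @param name Panel name; defaults to the file name without extension.
#' @return A list with elements `name` and `genes` (unique, non-empty).
#' @export
read_panel <- function(path, name = NULL) {
  lines <- str_trim(read_lines(path, progress = FALSE))
  lines <- sub("#.*$", "", lines)
  genes <- str_trim(lines[nzchar(str_trim(lines))])
  assert_that(length(genes) > 0L, "panel file '%s' defines no genes", path)
  assert_that(!anyDuplicated(genes), "panel file '%s' has duplicated symbols", path)
  list(name = name %||% sub("\\.[^.]*$", "", basename(path)), genes = genes)
}

#' Write / read a scored-result table
#'
#' Results are written as TSV with a deterministic column order and rows
#' ordered by `(sample_id, chrom, pos, alt)`; fields containing delimiters
#' are quoted so the table round-trips losslessly through
#' [read_result_table()].
#'
#' @param scored A scored-variant tibble (see [score_cohort()]).
#' @param path Output path.
#' @return `read_result_table()` returns the scored tibble.
#' @export
write_result_table <- function(scored, path) {
  cols <- c("sample_id", "chrom", "pos", "ref", "alt", "vclass", "zygosity",
            "map_quality", "depth", "alt_depth", "consequence", "sift",
            "polyphen", "gene", "tier", "tier_basis", "inh_class", "score",
            "reason", "matched_phenotype")
  out <- scored[, intersect(cols, names(scored))]
  out <- arrange(out, .data$sample_id, .data$chrom, .data$pos, .data$alt)
  write_tsv(out, path, progress = FALSE, escape = "double", quote = "needed")
  invisible(path)
}

#' @rdname write_result_table
#' @export
read_result_table <- function(path) {
  read_tsv(path, show_col_types = FALSE, progress = FALSE,
           col_types = cols(chrom = col_character(), pos = col_integer(),
                            tier = col_integer()))
}

#' Write a cohort to disk in the package's exchange formats
#'
#' Produces `vcf/<sample>.vcf` per participant plus
#' `variant_annotation.tsv`, `gene_annotation.tsv`, `participants.tsv` and,
#' when present, `truth.tsv` and `pathogenicity.tsv`.
#'
#' @param cohort A `wes_cohort` (see [generate_cohort()]).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "vcf"), recursive = TRUE, showWarnings = FALSE)
  for (sid in cohort$participants$sample_id) {
    v <- filter(cohort$variants, .data$sample_id == sid)
    write_vcf(v, file.path(dir, "vcf", paste0(sid, ".vcf")), sample_id = sid)
  }
  va <- distinct(select(cohort$variants, all_of(c("chrom", "pos", "ref", "alt",
                                                  "gene", "consequence", "sift",
                                                  "polyphen", af_cols()))))
  write_variant_annotation(va, file.path(dir, "variant_annotation.tsv"))
  write_gene_annotation(cohort$annotations, file.path(dir, "gene_annotation.tsv"))
  write_participants(cohort$participants, file.path(dir, "participants.tsv"))
  if (!is.null(cohort$truth)) {
    write_tsv(cohort$truth, file.path(dir, "truth.tsv"), progress = FALSE)
  }
  if (!is.null(cohort$pathogenicity)) {
    write_tsv(cohort$pathogenicity, file.path(dir, "pathogenicity.tsv"), progress = FALSE)
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory produced by [write_cohort()].
#' @return A `wes_cohort` list with elements `participants`, `variants`,
#'   `annotations` (and `truth`/`pathogenicity` when present on disk).
#' @export
read_cohort <- function(dir) {
  participants <- read_participants(file.path(dir, "participants.tsv"))
  va <- read_variant_annotation(file.path(dir, "variant_annotation.tsv"))
  calls <- bind_rows(lapply(participants$sample_id, function(sid) {
    read_vcf(file.path(dir, "vcf", paste0(sid, ".vcf")), sid)
  }))
  variants <- annotate_variants(calls, va)
  cohort <- list(
    participants = participants,
    variants = variants,
    annotations = read_gene_annotation(file.path(dir, "gene_annotation.tsv"))
  )
  truth_path <- file.path(dir, "truth.tsv")
  if (file.exists(truth_path)) {
    cohort$truth <- read_tsv(truth_path, show_col_types = FALSE, progress = FALSE)
  }
  path_path <- file.path(dir, "pathogenicity.tsv")
  if (file.exists(path_path)) {
    cohort$pathogenicity <- read_tsv(path_path, show_col_types = FALSE, progress = FALSE)
  }
  structure(cohort, class = "wes_cohort")
}
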