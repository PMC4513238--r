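# Gene-panel subsetting (ACMG-56 secondary findings, cancer-predisposition
# 57), per-person burden summaries, manual 1-5 pathogenicity handling, and a
# self-implemented two-sided Fisher's exact test.

#' Bundled gene panels
#'
#' `acmg56_genes()` returns the 56 genes recommended for secondary-findings
#' reporting (ACMG SF v1.0).  `cancer57_genes()` returns a 57-gene
#' cancer-predisposition panel: the 23 cancer genes of the ACMG list plus 34
#' representative genes from clinical cancer NGS panels (a synthetic
#' stand-in for a non-deposited panel definition).
#'
#' @return Character vector of gene symbols.
#' @export
acmg56_genes <- function() {
  read_panel(system.file("extdata", "acmg56.txt", package = "wescorr"),
             name = "acmg56")$genes
}

#' @rdname acmg56_genes
#' @export
cancer57_genes <- function() {
  read_panel(system.file("extdata", "cancer57_synthetic.txt", package = "wescorr"),
             name = "cancer57")$genes
}

#' Subset scored variants to a gene panel
#'
#' @param scored Scored (or tiered) variant tibble.
#' @param panel A panel as returned by [read_panel()], or a character vector
#'   of gene symbols.
#' @return The rows of `scored` whose gene is in the panel, order preserved.
#' @export
subset_to_panel <- function(scored, panel) {
  genes <- if (is.list(panel)) panel$genes else panel
  assert_that(length(genes) > 0L, "empty gene panel")
  filter(scored, .data$gene %in% genes)
}

#' Per-person variant-count summary
#'
#' Counts variants per participant, including participants carrying none.
#'
#' @param variants Variant tibble (any stage).
#' @param participants Participant tibble (non-empty).
#' @return A list: `counts` (named per-person vector in participant order),
#'   `total`, `mean` (exact), `mean_1dp`, `median`, `min`, `max`, `n_zero`,
#'   `n_carriers`.
#' @export
per_person_counts <- function(variants, participants) {
  assert_that(nrow(participants) > 0L, "no participants")
  counts <- table(factor(variants$sample_id, levels = participants$sample_id))
  counts <- setNames(as.integer(counts), participants$sample_id)
  list(
    counts = counts,
    total = sum(counts),
    mean = sum(counts) / length(counts),
    mean_1dp = round(sum(counts) / length(counts), 1),
    median = median(counts),
    min = min(counts),
    max = max(counts),
    n_zero = sum(counts == 0L),
    n_carriers = sum(counts > 0L)
  )
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric test, two-sided by the minimum-likelihood
#' convention: the p-value is the sum of the probabilities of all tables
#' with the observed margins whose probability does not exceed that of the
#' observed table (within a relative tolerance of 1e-7 for ties).
#'
#' @param table A 2x2 matrix (or coercible) of non-negative integer counts.
#' @return The p-value, in (0, 1].
#' @examples
#' fisher_exact_2x2(matrix(c(2, 0, 37, 50), nrow = 2))
#' @export
fisher_exact_2x2 <- function(table) {
  tab <- as.matrix(table)
  assert_that(all(dim(tab) == c(2L, 2L)), "fisher_exact_2x2() expects a 2x2 table")
  assert_that(all(is.finite(tab)) && all(tab >= 0) && all(tab == round(tab)),
              "table cells must be non-negative integers")
  tab <- matrix(as.numeric(tab), 2L, 2L)
  row1 <- sum(tab[1, ]); row2 <- sum(tab[2, ]); col1 <- sum(tab[, 1])
  if (row1 + row2 == 0 || col1 == 0 || col1 == row1 + row2 || row1 == 0 || row2 == 0) {
    return(1)  # a degenerate margin admits a single table
  }
  support <- max(0, col1 - row2):min(row1, col1)
  probs <- dhyper(support, row1, row2, col1)
  p_obs <- dhyper(tab[1, 1], row1, row2, col1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Validate a pathogenicity-score table
#'
#' Manual pathogenicity curation is an input, not a computation: each row
#' assigns a variant key an integer score on the 1-5 scale (1 =
#' neutral/non-pathogenic, 3 = uncertain significance, 4 = likely
#' pathogenic, 5 = pathogenic).
#'
#' @param pathogenicity A tibble with columns `key` and `score`.
#' @return The validated tibble.
#' @export
validate_pathogenicity <- function(pathogenicity) {
  assert_that(all(c("key", "score") %in% names(pathogenicity)),
              "pathogenicity table needs columns key, score")
  sc <- pathogenicity$score
  assert_that(all(sc == round(sc) & sc >= 1 & sc <= 5),
              "pathogenicity scores must be integers in 1..5")
  dup <- pathogenicity$key[duplicated(pathogenicity$key)]
  assert_that(length(dup) == 0L, "duplicated pathogenicity key(s): %s",
              paste(unique(dup), collapse = ", "))
  pathogenicity
}

#' Compare panel-variant burden between cancer and non-cancer participants
#'
#' Splits the cohort by invasive-cancer history, summarises per-person panel
#' variant counts in each group, and tests whether carrying at least one
#' variant at or above the pathogenicity threshold (default: score >= 4,
#' likely pathogenic) is associated with cancer history, using
#' [fisher_exact_2x2()].
#'
#' @param panel_variants Scored variants already subset to the panel
#'   ([subset_to_panel()]).
#' @param participants Participant tibble with `has_invasive_cancer` set.
#' @param pathogenicity Pathogenicity table ([validate_pathogenicity()]);
#'   variants without an assignment are treated as unscored (never above
#'   threshold).
#' @param threshold Minimum score defining a qualifying variant.
#' @return A list of class `wes_burden`: per-group summaries (`cancer`,
#'   `non_cancer`), the carriers-by-group `contingency` matrix, and
#'   `fisher_p`.
#' @export
compare_burden <- function(panel_variants, participants, pathogenicity = NULL,
                           threshold = 4) {
  assert_that(!anyNA(participants$has_invasive_cancer),
              "every participant needs has_invasive_cancer set")
  grp <- split(participants, participants$has_invasive_cancer)
  cancer <- grp[["TRUE"]] %||% participants[0, ]
  non_cancer <- grp[["FALSE"]] %||% participants[0, ]
  in_grp <- function(g) filter(panel_variants, .data$sample_id %in% g$sample_id)
  summaries <- list(
    cancer = per_person_counts(in_grp(cancer), cancer),
    non_cancer = per_person_counts(in_grp(non_cancer), non_cancer)
  )
  qualifying <- character()
  if (!is.null(pathogenicity)) {
    pathogenicity <- validate_pathogenicity(pathogenicity)
    keys <- variant_key(panel_variants$chrom, panel_variants$pos,
                        panel_variants$ref, panel_variants$alt)
    score <- pathogenicity$score[match(keys, pathogenicity$key)]
    qualifying <- unique(panel_variants$sample_id[!is.na(score) & score >= threshold])
  }
  carriers <- c(sum(cancer$sample_id %in% qualifying),
                sum(non_cancer$sample_id %in% qualifying))
  contingency <- matrix(
    c(carriers[1], nrow(cancer) - carriers[1],
      carriers[2], nrow(non_cancer) - carriers[2]),
    nrow = 2, byrow = TRUE,
    dimnames = list(c("cancer", "non_cancer"), c("carrier", "non_carrier"))
  )
  structure(list(summaries = summaries, contingency = contingency,
                 fisher_p = fisher_exact_2x2(contingency),
                 threshold = threshold),
            class = "wes_burden")
}

#' @export
print.wes_burden <- function(x, ...) {
  cat("<wes_burden>\n")
  for (g in names(x$summaries)) {
    s <- x$summaries[[g]]
    cat(sprintf("  %-10s mean %.1f (range %d-%d) over %d participants\n",
                g, s$mean, s$min, s$max, length(s$counts)))
  }
  cat(sprintf("  carriers (score >= %g): %d/%d vs %d/%d; Fisher p = %.4g\n",
              x$threshold,
              x$contingency[1, 1], sum(x$contingency[1, ]),
              x$contingency[2, 1], sum(x$contingency[2, ]), x$fisher_p))
  invisible(x)
}
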