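# Cross-tabulated reporting and end-to-end pipeline orchestration.

#' Build the Yes/No/X cross-tabulation from scored variants
#'
#' Aggregates scored variants into the four (tier x variant-class) panels,
#' one row per inheritance class, with per-panel and grand totals and
#' nearest-integer percentages of the grand total.
#'
#' @param scored Scored variant tibble ([score_cohort()]).
#' @return A `wes_crosstab`: list with `cells` (tier, vclass, inh_class, n,
#'   n_yes, n_no, n_x over the full class grid), `panel_totals`, and `grand`
#'   (n_total, n_yes, n_no, n_x, pct_yes, pct_no, pct_x).
#' @export
build_crosstab <- function(scored) {
  grid <- tidyr::expand_grid(tier = c(1L, 2L), vclass = c("SNV", "INDEL"),
                             inh_class = WES_INH_CLASSES)
  if (nrow(scored) > 0L) {
    counts <- scored |>
      group_by(.data$tier, .data$vclass, .data$inh_class) |>
      summarise(n = n(),
                n_yes = sum(.data$score == "YES"),
                n_no = sum(.data$score == "NO"),
                n_x = sum(.data$score == "X"), .groups = "drop")
  } else {
    counts <- tibble(tier = integer(), vclass = character(),
                     inh_class = character(), n = integer(),
                     n_yes = integer(), n_no = integer(), n_x = integer())
  }
  cells <- grid |>
    left_join(counts, by = c("tier", "vclass", "inh_class")) |>
    mutate(dplyr::across(all_of(c("n", "n_yes", "n_no", "n_x")),
                         ~ replace_na(as.integer(.x), 0L)))
  panel_totals <- cells |>
    group_by(.data$tier, .data$vclass) |>
    summarise(n = sum(.data$n), n_yes = sum(.data$n_yes),
              n_no = sum(.data$n_no), n_x = sum(.data$n_x), .groups = "drop")
  n_total <- sum(cells$n)
  grand <- list(
    n_total = n_total,
    n_yes = sum(cells$n_yes), n_no = sum(cells$n_no), n_x = sum(cells$n_x),
    pct_yes = if (n_total > 0) round(100 * sum(cells$n_yes) / n_total) else 0,
    pct_no = if (n_total > 0) round(100 * sum(cells$n_no) / n_total) else 0,
    pct_x = if (n_total > 0) round(100 * sum(cells$n_x) / n_total) else 0
  )
  structure(list(cells = cells, panel_totals = panel_totals, grand = grand),
            class = "wes_crosstab")
}

#' @export
print.wes_crosstab <- function(x, ...) {
  cat(render_crosstab(x, format = "text"), sep = "\n")
  invisible(x)
}

#' Summarise a scored cohort
#'
#' @param scored Scored variant tibble.
#' @param participants Participant tibble.
#' @param crosstab Optional pre-built [build_crosstab()] result.
#' @param phenotype_view Optional [phenotype_centric_view()] result.
#' @return A `wes_cohort_summary`: participant and tier totals, per-person
#'   count summary (mean to 1 decimal and exact), and phenotype-centric
#'   totals when a view is supplied.  `n_total = n_tier1 + n_tier2`.
#' @export
summarize_cohort <- function(scored, participants, crosstab = NULL,
                             phenotype_view = NULL) {
  crosstab <- crosstab %||% build_crosstab(scored)
  per_person <- per_person_counts(scored, participants)
  out <- list(
    n_participants = nrow(participants),
    n_tier1 = sum(scored$tier == 1L),
    n_tier2 = sum(scored$tier == 2L),
    n_total = nrow(scored),
    per_person = per_person,
    grand = crosstab$grand
  )
  if (!is.null(phenotype_view)) {
    out$n_phenotypes <- phenotype_view$n_phenotypes
    out$n_matched_phenotypes <- phenotype_view$n_matched
    out$n_participants_no_match <- phenotype_view$n_participants_no_match
  }
  structure(out, class = "wes_cohort_summary")
}

#' @export
print.wes_cohort_summary <- function(x, ...) {
  cat(sprintf("<wes_cohort_summary> %d participants, %d variants (%d Tier-1, %d Tier-2)\n",
              x$n_participants, x$n_total, x$n_tier1, x$n_tier2))
  cat(sprintf("  per person: mean %.1f (range %d-%d)\n",
              x$per_person$mean, x$per_person$min, x$per_person$max))
  cat(sprintf("  scores: YES %d (%d%%), NO %d (%d%%), X %d (%d%%)\n",
              x$grand$n_yes, x$grand$pct_yes, x$grand$n_no, x$grand$pct_no,
              x$grand$n_x, x$grand$pct_x))
  if (!is.null(x$n_matched_phenotypes)) {
    cat(sprintf("  phenotype view: %d of %d diagnoses matched; %d participants with no match\n",
                x$n_matched_phenotypes, x$n_phenotypes, x$n_participants_no_match))
  }
  invisible(x)
}

crosstab_tsv_table <- function(crosstab) {
  bind_rows(
    mutate(crosstab$cells, row = .data$inh_class),
    mutate(crosstab$panel_totals, inh_class = NA_character_, row = "TOTAL")
  ) |>
    arrange(.data$tier, dplyr::desc(.data$vclass),
            match(.data$inh_class, WES_INH_CLASSES)) |>
    select(all_of(c("tier", "vclass", "row", "n", "n_yes", "n_no", "n_x")))
}

#' Render a cross-tabulation
#'
#' `format = "tsv"` emits one row per cell plus per-panel totals;
#' `"json"` emits a structure that parses back to an identical
#' cross-tabulation ([parse_crosstab_json()]); `"text"` mirrors the
#' reference table's layout, including the conventional presentation of the
#' GWAS-SNP block as an "All SNP" line that restates its novel/exact
#' sub-rows.
#'
#' @param crosstab A `wes_crosstab`.
#' @param summary Optional `wes_cohort_summary` appended to text output.
#' @param format One of `"tsv"`, `"json"`, `"text"`.
#' @return Character vector of lines (a single JSON string for `"json"`).
#' @export
render_crosstab <- function(crosstab, summary = NULL,
                            format = c("text", "tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- crosstab_tsv_table(crosstab)
    return(strsplit(readr::format_tsv(tab), "\n")[[1]])
  }
  if (format == "json") {
    payload <- list(
      cells = crosstab$cells,
      panel_totals = crosstab$panel_totals,
      grand = crosstab$grand
    )
    return(jsonlite::toJSON(payload, dataframe = "rows", auto_unbox = TRUE,
                            digits = NA))
  }
  lines <- character()
  for (t in c(1L, 2L)) {
    for (vc in c("SNV", "INDEL")) {
      cells <- filter(crosstab$cells, .data$tier == t, .data$vclass == vc)
      tot <- filter(crosstab$panel_totals, .data$tier == t, .data$vclass == vc)
      lines <- c(lines, sprintf("Tier-%d %s  (n / match / no match / cannot assess)", t, vc))
      fmt <- function(label, n, y, no, x) sprintf("  %-22s %6d %6d %6d %6d", label, n, y, no, x)
      for (cl in c("AD", "AD_AR", "DIGENIC", "AR", "XLR", "XLD")) {
        r <- cells[cells$inh_class == cl, ]
        lines <- c(lines, fmt(cl, r$n, r$n_yes, r$n_no, r$n_x))
      }
      sn <- cells[cells$inh_class == "SNP_novel", ]
      se <- cells[cells$inh_class == "SNP_exact", ]
      lines <- c(lines,
                 fmt("All SNP", sn$n + se$n, sn$n_yes + se$n_yes,
                     sn$n_no + se$n_no, sn$n_x + se$n_x),
                 fmt("  Novel SNP in gene", sn$n, sn$n_yes, sn$n_no, sn$n_x),
                 fmt("  Exact variant", se$n, se$n_yes, se$n_no, se$n_x))
      ot <- cells[cells$inh_class == "OTHERS", ]
      lines <- c(lines, fmt("Others", ot$n, ot$n_yes, ot$n_no, ot$n_x),
                 fmt("Total", tot$n, tot$n_yes, tot$n_no, tot$n_x), "")
    }
  }
  g <- crosstab$grand
  lines <- c(lines, sprintf(
    "Grand total %d: match %d (%d%%), no match %d (%d%%), cannot assess %d (%d%%)",
    g$n_total, g$n_yes, g$pct_yes, g$n_no, g$pct_no, g$n_x, g$pct_x))
  if (!is.null(summary)) {
    lines <- c(lines, sprintf("Participants %d; per-person mean %.1f (range %d-%d)",
                              summary$n_participants, summary$per_person$mean,
                              summary$per_person$min, summary$per_person$max))
  }
  lines
}

#' @rdname render_crosstab
#' @param json A JSON string produced by `render_crosstab(format = "json")`.
#' @export
parse_crosstab_json <- function(json) {
  payload <- jsonlite::fromJSON(json)
  structure(list(
    cells = as_tibble(payload$cells),
    panel_totals = as_tibble(payload$panel_totals),
    grand = as.list(payload$grand)
  ), class = "wes_crosstab")
}

#' Run the full pipeline on a cohort
#'
#' Executes filtering, tier classification, inheritance assignment, Yes/No/X
#' scoring, the phenotype-centric view, optional panel/burden analyses, and
#' reporting.  A structured per-stage log is kept and the count-conservation
#' identity (variants in = removed by filtering + unclassifiable + scored)
#' is asserted.
#'
#' @param cohort A `wes_cohort` (e.g. [generate_cohort()], [read_cohort()]).
#' @param config A [filter_config()].
#' @param lexicon Synonym lexicon for phenotype matching.
#' @param panels Optional named list of gene panels (character vectors) to
#'   subset and summarise.
#' @param out_dir Optional directory; when given, the scored table, filter
#'   outcomes, cross-tabulation (TSV and JSON) and summary are written there.
#' @return A list: `scored`, `outcomes`, `crosstab`, `summary`, `view`,
#'   `panel_results` (per panel: variants + per-person summary), `log`.
#' @export
run_pipeline <- function(cohort, config = filter_config(),
                         lexicon = default_lexicon(), panels = NULL,
                         out_dir = NULL) {
  n_samples <- nrow(cohort$participants)
  filt <- apply_filters(cohort$variants, cohort$annotations, config,
                        n_samples = n_samples)
  tiered <- classify_all(filt$retained)
  scored <- score_cohort(tiered, cohort$annotations, cohort$participants, lexicon)
  view <- phenotype_centric_view(scored, cohort$participants, cohort$annotations,
                                 lexicon)
  crosstab <- build_crosstab(scored)
  summary <- summarize_cohort(scored, cohort$participants, crosstab, view)

  n_in <- nrow(cohort$variants)
  n_removed <- sum(!filt$outcomes$passed)
  n_unclassified <- nrow(filt$retained) - nrow(tiered)
  log <- bind_rows(
    tibble(stage = "input", detail = "variant calls", n = n_in),
    filt$outcomes |>
      filter(!.data$passed) |>
      mutate(rule = .data$failed_rules) |>
      tidyr::separate_rows("rule", sep = ",") |>
      count(.data$rule, name = "n") |>
      mutate(stage = "filter", detail = paste0("failed ", .data$rule)) |>
      select(all_of(c("stage", "detail", "n"))),
    tibble(stage = "filter", detail = "removed", n = n_removed),
    tibble(stage = "filter", detail = "retained", n = nrow(filt$retained)),
    tibble(stage = "classify", detail = "not reportable", n = n_unclassified),
    tibble(stage = "classify", detail = "tiered", n = nrow(tiered)),
    tibble(stage = "score", detail = "scored", n = nrow(scored))
  )
  assert_that(n_in == n_removed + n_unclassified + nrow(scored),
              "count conservation violated: %d in != %d removed + %d unclassified + %d scored",
              n_in, n_removed, n_unclassified, nrow(scored))

  panel_results <- NULL
  if (!is.null(panels)) {
    panel_results <- lapply(panels, function(genes) {
      pv <- subset_to_panel(scored, genes)
      list(variants = pv,
           per_person = per_person_counts(pv, cohort$participants))
    })
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_result_table(scored, file.path(out_dir, "scored.tsv"))
    write_tsv(filt$outcomes, file.path(out_dir, "filter_outcomes.tsv"),
              progress = FALSE)
    write_lines(render_crosstab(crosstab, summary, format = "text"),
                file.path(out_dir, "crosstab.txt"))
    write_lines(render_crosstab(crosstab, format = "tsv"),
                file.path(out_dir, "crosstab.tsv"))
    write_lines(render_crosstab(crosstab, format = "json"),
                file.path(out_dir, "crosstab.json"))
    write_tsv(log, file.path(out_dir, "pipeline_log.tsv"), progress = FALSE)
  }

  list(scored = scored, outcomes = filt$outcomes, crosstab = crosstab,
       summary = summary, view = view, panel_results = panel_results, log = log)
}
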