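#' Filtering configuration
#'
#' Thresholds of the variant-filter cascade.  Defaults are the published
#' values of the workflow this package reimplements: PHRED-scaled mapping
#' quality >= 20 (accuracy > 99\%), total depth >= 20 reads, alternate-allele
#' depth >= 5 reads, exclusion of variants with a folded minor-allele
#' frequency of 10\% or more in any consulted reference panel, and exclusion
#' of alleles carried by 10\% or more of the cohort's samples.
#'
#' @param min_map_quality Minimum PHRED mapping quality (inclusive; SNVs only).
#' @param min_depth Minimum mapped-read depth (inclusive; SNVs only).
#' @param min_alt_depth Minimum alternate-supporting read depth (inclusive;
#'   SNVs and INDELs).
#' @param max_maf Variants with folded MAF `>= max_maf` in any consulted panel
#'   are excluded (the pass condition is strict: `maf < max_maf`).
#' @param max_cohort_fraction Alleles carried by
#'   `>= max_cohort_fraction` of the cohort's samples are excluded.
#' @param reference_panels Names of the population panels consulted; each must
#'   correspond to an `af_<panel>` column of the variant table.
#' @return An object of class `wes_filter_config`.
#' @examples
#' filter_config()
#' filter_config(max_maf = 0.05)
#' @export
filter_config <- function(min_map_quality = 20,
                          min_depth = 20,
                          min_alt_depth = 5,
                          max_maf = 0.10,
                          max_cohort_fraction = 0.10,
                          reference_panels = WES_PANELS) {
  assert_that(min_map_quality >= 0 && min_depth >= 0 && min_alt_depth >= 0,
              "filter thresholds must be non-negative")
  assert_that(max_maf > 0 && max_maf <= 1, "max_maf must lie in (0, 1]")
  assert_that(max_cohort_fraction > 0 && max_cohort_fraction <= 1,
              "max_cohort_fraction must lie in (0, 1]")
  assert_that(length(reference_panels) >= 1, "at least one reference panel is required")
  structure(
    list(
      min_map_quality = min_map_quality,
      min_depth = min_depth,
      min_alt_depth = min_alt_depth,
      max_maf = max_maf,
      max_cohort_fraction = max_cohort_fraction,
      reference_panels = reference_panels
    ),
    class = "wes_filter_config"
  )
}

#' @export
print.wes_filter_config <- function(x, ...) {
  cat("<wes_filter_config>\n")
  cat(sprintf("  mapping quality >= %g, depth >= %g, alt depth >= %g\n",
              x$min_map_quality, x$min_depth, x$min_alt_depth))
  cat(sprintf("  folded MAF < %g in panels: %s\n", x$max_maf,
              paste(x$reference_panels, collapse = ", ")))
  cat(sprintf("  cohort carrier fraction < %g\n", x$max_cohort_fraction))
  invisible(x)
}

#' Write / read a filter configuration as JSON
#'
#' @param config A [filter_config()] object.
#' @param path File path.
#' @return `read_filter_config()` returns a `wes_filter_config`.
#' @export
write_filter_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_filter_config
#' @export
read_filter_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(filter_config, raw)
}
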