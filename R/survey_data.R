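#' Published 95th-percentile carcinogenic risk estimates (worked example)
#'
#' Per-area, per-group 95th-percentile carcinogenic risks for Cr, Cd and Pb
#' transcribed from a published nine-area survey of heavy metals in Chinese
#' eggs (five cities, three mining districts; `-F`/`-C` suffixes mark
#' free-range vs commercial sampling in the one city covered by both). The
#' values are inputs for aggregation examples — summing rows with
#' [total_cancer_risk()], classifying with [classify_cr()] — not output of
#' this package.
#'
#' One internal inconsistency of the source is worth knowing: its narrative
#' quotes a highest female total carcinogenic risk of 1.3e-5 (DZ), while
#' the female DZ row of its own risk table sums to about 1.26e-4. The
#' tabulated per-metal values are taken as authoritative here, so the row
#' sum is what this package reproduces.
#'
#' @return Tibble with `area`, `metal` (Cr/Cd/Pb), `group`
#'   (male/female/child) and `cr` (dimensionless lifetime risk).
#' @export
#' @examples
#' cr <- survey_cr_p95()
#' tcr_male <- tapply(cr$cr[cr$group == "male"], cr$area[cr$group == "male"], sum)
#' format_sci(max(tcr_male))
survey_cr_p95 <- function() {
  path <- system.file("extdata", "cr_p95_survey.csv", package = "eggrisk")
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Aggregate a per-metal CR table into per-cell TCR
#'
#' Applies [total_cancer_risk()] to every (area, group) cell of a long CR
#' table such as [survey_cr_p95()], and classifies both the per-metal CRs
#' and the TCR with [classify_cr()].
#'
#' @param cr_table Tibble with `area`, `metal`, `group`, `cr` covering the
#'   three carcinogens per cell.
#' @return Tibble with `area`, `group`, `tcr`, `tcr_class`.
#' @export
aggregate_tcr <- function(cr_table) {
  cr_table %>%
    dplyr::group_by(.data$area, .data$group) %>%
    dplyr::summarise(
      tcr = total_cancer_risk(setNames(
        .data$cr[match(egg_carcinogens(), .data$metal)], egg_carcinogens())),
      .groups = "drop") %>%
    dplyr::mutate(tcr_class = classify_cr(.data$tcr))
}
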