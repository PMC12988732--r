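#' Format values in compact scientific notation
#'
#' Renders numbers the way risk tables print them: two significant figures
#' as `a.b×10-e` (e.g. `5.905e-05` becomes `"5.9×10-5"`). Values of zero
#' render as `"0"`; magnitudes in `[0.01, 1000)` render as plain decimals.
#'
#' @param x Numeric vector.
#' @return Character vector.
#' @export
format_sci <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return(NA_character_)
    if (v == 0) return("0")
    s <- signif(v, 2)
    e <- floor(log10(abs(s)))
    if (e >= -2 && e < 3) {
      return(format(s, trim = TRUE, scientific = FALSE))
    }
    m <- s / 10^e
    sprintf("%.1f×10%d", m, e)
  }, character(1))
}

#' Render a risk-table style CR matrix
#'
#' Builds the areas x (metal x group) matrix of 95th-percentile
#' carcinogenic risks in two-significant-figure scientific notation, with
#' cells at or above the 1e-4 decision threshold wrapped in `**` (the
#' plain-text counterpart of bolding flagged cells).
#'
#' @param results An `eggrisk_mcs` tibble ([run_mcs()]) or any tibble with
#'   `area`, `group`, `metric` (`CR_Cr`, `CR_Cd`, `CR_Pb`) and `p95`.
#' @return A tibble with one row per area and one `<metal>_<group>` column
#'   per carcinogen and group; empty input yields an empty tibble with an
#'   `area` column.
#' @export
render_cr_matrix <- function(results) {
  cr <- results[grepl("^CR_", results$metric), , drop = FALSE]
  if (nrow(cr) == 0) {
    return(tibble::tibble(area = character(0)))
  }
  cr$metal <- sub("^CR_", "", cr$metric)
  cr$cell <- ifelse(cr$p95 >= 1e-4,
                    paste0("**", format_sci(cr$p95), "**"),
                    format_sci(cr$p95))
  metal_order <- metal_levels(cr$metal)
  group_order <- intersect(c(.population_groups, sort(unique(cr$group))),
                           unique(cr$group))
  cr$column <- factor(paste(cr$metal, cr$group, sep = "_"),
                      levels = as.vector(outer(group_order, metal_order,
                                               function(g, m) paste(m, g, sep = "_"))))
  cr %>%
    dplyr::select("area", "column", "cell") %>%
    dplyr::arrange(.data$column) %>%
    tidyr::pivot_wider(names_from = "column", values_from = "cell")
}

#' Run the full assessment pipeline
#'
#' Composes the stages end to end: data input (or synthetic generation) ->
#' deterministic risk -> Monte Carlo risk -> group comparisons ->
#' compliance screening -> rendered report tables. Every stage logs its
#' record counts; any stage failure aborts naming the stage. The bundle is
#' idempotent for a fixed seed.
#'
#' @param records Validated concentration records, a path to a
#'   concentration CSV, or `NULL` to generate synthetic data from
#'   `generator`.
#' @param reference A list with `profiles`, `toxicity`, `limits` (as from
#'   [read_reference_tables()]) or a path to the YAML reference file.
#' @param generator Optional [generator_config()] used when `records` is
#'   `NULL`.
#' @param n_iter,seed Monte Carlo settings (defaults 10000, 1).
#' @param alpha Significance level for comparisons.
#' @param summary Area-level statistic for the deterministic stage.
#' @param out_dir Optional directory; when given, CSV/JSON artifacts are
#'   written there (each stamped with package version, seed and config
#'   hash).
#' @return A list of class `eggrisk_report`: `records`, `deterministic`,
#'   `mcs`, `threshold_report`, `cr_matrix`, `comparisons` (by area and by
#'   production system), `compliance`, and `meta` (version, seed, n_iter,
#'   alpha, config hash).
#' @export
run_pipeline <- function(records = NULL, reference,
                         generator = NULL,
                         n_iter = 10000, seed = 1L, alpha = 0.05,
                         summary = "mean", out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(c(paste0("Pipeline stage `", name, "` failed."),
              x = conditionMessage(e)), class = "eggrisk_stage_error")
    })
  }

  ref <- stage("data_io", {
    if (is.character(reference)) read_reference_tables(reference) else {
      list(profiles = validate_exposure_profiles(reference$profiles),
           toxicity = validate_toxicity(reference$toxicity),
           limits = validate_limits(reference$limits))
    }
  })
  records <- stage("data_io", {
    if (is.null(records)) {
      cfg <- generator %||% generator_config(seed = seed)
      generate_concentrations(cfg)
    } else if (is.character(records)) {
      read_concentration_table(records)
    } else {
      concentration_records(records, basis = attr(records, "basis") %||% "dry")
    }
  })
  inform(paste0("data_io: ", nrow(records), " concentration records, ",
                length(unique(records$area)), " areas."))

  det <- stage("deterministic_risk",
               assess(records, ref$profiles, ref$toxicity, summary = summary))
  inform(paste0("deterministic_risk: ", nrow(det$summary), " area x group cells."))

  specs <- stage("probabilistic_risk",
                 build_default_specs(records, ref$profiles))
  mcs <- stage("probabilistic_risk",
               run_mcs(specs, ref$profiles, ref$toxicity,
                       n_iter = n_iter, seed = seed))
  thresh <- stage("probabilistic_risk", percentile_threshold_report(mcs))
  inform(paste0("probabilistic_risk: ", nrow(mcs), " simulated metrics at n_iter = ",
                n_iter, "."))

  comparisons <- stage("comparison_stats", list(
    by_area = compare_groups(records, "area", alpha = alpha),
    by_production_system = compare_groups(records, "production_system",
                                          alpha = alpha)))
  compliance <- stage("comparison_stats",
                      compliance_screen(records, ref$limits))
  inform(paste0("comparison_stats: ", nrow(compliance), " compliance verdicts."))

  meta <- list(
    package_version = as.character(packageVersion("eggrisk")),
    seed = as.integer(seed), n_iter = as.integer(n_iter), alpha = alpha,
    summary = summary,
    config_hash = rlang::hash(list(ref = ref, n_iter = n_iter, seed = seed,
                                   alpha = alpha, summary = summary)))

  bundle <- structure(list(records = records, deterministic = det, mcs = mcs,
                           threshold_report = thresh,
                           cr_matrix = render_cr_matrix(mcs),
                           comparisons = comparisons, compliance = compliance,
                           meta = meta),
                      class = "eggrisk_report")
  if (!is.null(out_dir)) {
    write_report_bundle(bundle, out_dir)
  }
  bundle
}

#' @export
print.eggrisk_report <- function(x, ...) {
  cat("<eggrisk_report> seed", x$meta$seed, "| n_iter", x$meta$n_iter,
      "| hash", x$meta$config_hash, "\n")
  cat("Deterministic cells:", nrow(x$deterministic$summary),
      "| simulated metrics:", nrow(x$mcs), "\n")
  invisible(x)
}

write_report_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- bundle$meta
  readr::write_csv(bundle$deterministic$summary,
                   file.path(out_dir, "deterministic_summary.csv"))
  readr::write_csv(bundle$deterministic$by_metal,
                   file.path(out_dir, "deterministic_by_metal.csv"))
  readr::write_csv(bundle$mcs, file.path(out_dir, "mcs_summaries.csv"))
  readr::write_csv(bundle$threshold_report,
                   file.path(out_dir, "p95_decision_table.csv"))
  readr::write_csv(bundle$cr_matrix, file.path(out_dir, "cr_matrix.csv"))
  readr::write_csv(bundle$compliance %>%
                     dplyr::mutate(exceeding_samples = vapply(
                       .data$exceeding_samples, paste, "", collapse = ";")),
                   file.path(out_dir, "compliance.csv"))
  jsonlite::write_json(stamp, file.path(out_dir, "run_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
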