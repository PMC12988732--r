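#' Validate a table of per-sample metal concentration records
#'
#' Checks a long-format concentration table (one measurement per row) against
#' the schema used throughout the package and returns it as a validated
#' tibble. Every malformed row is reported with its row number; nothing is
#' silently dropped.
#'
#' Required columns: `sample_id`, `area`, `production_system`
#' (`free_range`/`commercial`), `mining_class` (`mining`/`non_mining`),
#' `metal` (element symbol), `concentration` (mg/kg). Optional columns:
#' `below_lod` (logical; such rows carry the LOD value, not zero) and `unit`
#' (must read `mg/kg` when present).
#'
#' @param x A data frame in long format.
#' @param basis Measurement basis of the concentrations, `"dry"` or
#'   `"fresh"`. Carried as metadata; the package never converts between
#'   bases.
#' @param metals Allowed element symbols (default [egg_metals()]).
#' @return A tibble of validated records with a `basis` attribute.
#' @export
concentration_records <- function(x, basis = c("dry", "fresh"),
                                  metals = egg_metals()) {
  basis <- match.arg(basis)
  x <- tibble::as_tibble(x)

  required <- c("sample_id", "area", "production_system", "mining_class",
                "metal", "concentration")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(c("Concentration table is missing required columns.",
            x = paste("Missing:", paste(missing_cols, collapse = ", "))),
          class = "eggrisk_schema_error")
  }
  if (!is.numeric(x$concentration)) {
    abort("Column `concentration` must be numeric (mg/kg).",
          class = "eggrisk_schema_error")
  }
  if (!"below_lod" %in% names(x)) x$below_lod <- FALSE
  x$below_lod <- as.logical(x$below_lod)

  problems <- character(0)
  row_problem <- function(rows, what) {
    if (length(rows) > 0) {
      sprintf("row %s: %s", paste(rows, collapse = ", "), what)
    } else {
      character(0)
    }
  }
  if ("unit" %in% names(x)) {
    bad <- which(!is.na(x$unit) & x$unit != "mg/kg")
    problems <- c(problems, row_problem(bad, "unit must be 'mg/kg'"))
  }
  bad_conc <- which(is.na(x$concentration) | x$concentration < 0)
  problems <- c(problems, row_problem(bad_conc,
                                      "concentration must be >= 0 and non-missing"))
  bad_metal <- which(!x$metal %in% metals)
  if (length(bad_metal) > 0) {
    problems <- c(problems, row_problem(
      bad_metal,
      paste0("unknown metal symbol (allowed: ",
             paste(metals, collapse = ", "), ")")))
  }
  bad_ps <- which(!x$production_system %in% .production_systems)
  problems <- c(problems, row_problem(
    bad_ps, "production_system must be 'free_range' or 'commercial'"))
  bad_mc <- which(!x$mining_class %in% .mining_classes)
  problems <- c(problems, row_problem(
    bad_mc, "mining_class must be 'mining' or 'non_mining'"))
  bad_lod <- which(is.na(x$below_lod))
  problems <- c(problems, row_problem(bad_lod, "below_lod must be TRUE/FALSE"))

  # an area cannot be simultaneously mining and non-mining
  cls <- tapply(x$mining_class, x$area, function(v) length(unique(v)))
  inconsistent <- names(cls)[cls > 1]
  if (length(inconsistent) > 0) {
    problems <- c(problems,
                  sprintf("area %s carries more than one mining_class",
                          paste(inconsistent, collapse = ", ")))
  }

  if (length(problems) > 0) {
    abort(c("Invalid concentration records.", setNames(problems, rep("x", length(problems)))),
          class = "eggrisk_validation_error")
  }

  out <- x[, c(required, "below_lod")]
  attr(out, "basis") <- basis
  out
}

#' Read a long-format concentration CSV
#'
#' Reads and validates a comma-separated concentration table with one
#' measurement per row (see [concentration_records()] for the schema).
#' Wide-format tables are rejected, not guessed.
#'
#' @inheritParams concentration_records
#' @param path Path to a CSV file.
#' @return A validated tibble of concentration records.
#' @export
read_concentration_table <- function(path, basis = c("dry", "fresh"),
                                     metals = egg_metals()) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "eggrisk_io_error")
  }
  # parse numbers via R's correctly-rounded strtod so that shortest
  # round-trip decimal representations reproduce doubles bit-exactly
  x <- readr::read_csv(path, progress = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  if ("concentration" %in% names(x)) {
    x$concentration <- suppressWarnings(as.numeric(x$concentration))
  }
  if ("below_lod" %in% names(x)) {
    x$below_lod <- as.logical(x$below_lod)
  }
  concentration_records(x, basis = basis, metals = metals)
}

#' Write concentration records to CSV
#'
#' Values round-trip exactly for decimal representations with up to 15
#' significant digits.
#'
#' @param records Validated concentration records.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_concentration_table <- function(records, path) {
  readr::write_csv(records, path)
  invisible(path)
}

#' Substitute below-LOD concentrations
#'
#' Records flagged `below_lod` carry the limit of detection in the
#' `concentration` column. This replaces those values by the chosen
#' substitution convention before risk calculation. The default, LOD/2, is
#' the common convention for left-censored trace measurements.
#'
#' @param records Validated concentration records.
#' @param method One of `"half"` (LOD/2, default), `"sqrt2"` (LOD/sqrt(2)),
#'   `"lod"` (keep the LOD) or `"zero"`.
#' @return Records with substituted concentrations; the `below_lod` flag is
#'   preserved.
#' @export
substitute_lod <- function(records, method = c("half", "sqrt2", "lod", "zero")) {
  method <- match.arg(method)
  fac <- switch(method, half = 0.5, sqrt2 = 1 / sqrt(2), lod = 1, zero = 0)
  idx <- which(records$below_lod)
  if (length(idx) > 0) {
    records$concentration[idx] <- records$concentration[idx] * fac
  }
  records
}

validate_exposure_profiles <- function(x) {
  x <- tibble::as_tibble(x)
  required <- c("group", "BW", "FIR", "EF", "ED", "AT")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(c("Exposure profile table is missing columns.",
            x = paste("Missing:", paste(missing_cols, collapse = ", "))),
          class = "eggrisk_schema_error")
  }
  problems <- character(0)
  for (f in c("BW", "FIR", "EF", "ED", "AT")) {
    bad <- which(is.na(x[[f]]) | x[[f]] <= 0)
    if (length(bad) > 0) {
      problems <- c(problems, sprintf("profile row %s: %s must be > 0",
                                      paste(bad, collapse = ", "), f))
    }
  }
  bad_ef <- which(!is.na(x$EF) & x$EF > 366)
  if (length(bad_ef) > 0) {
    problems <- c(problems, sprintf(
      "profile row %s: EF exceeds 366 days/year", paste(bad_ef, collapse = ", ")))
  }
  if (anyDuplicated(x$group)) {
    problems <- c(problems, "duplicate population group in exposure profiles")
  }
  if (length(problems) > 0) {
    abort(c("Invalid exposure profiles.",
            setNames(problems, rep("x", length(problems)))),
          class = "eggrisk_validation_error")
  }
  x[, required]
}

validate_toxicity <- function(x) {
  x <- tibble::as_tibble(x)
  required <- c("metal", "rfd")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(c("Toxicity table is missing columns.",
            x = paste("Missing:", paste(missing_cols, collapse = ", "))),
          class = "eggrisk_schema_error")
  }
  if (!"sf" %in% names(x)) x$sf <- NA_real_
  problems <- character(0)
  bad_rfd <- which(is.na(x$rfd) | x$rfd <= 0)
  if (length(bad_rfd) > 0) {
    problems <- c(problems, sprintf("toxicity row %s: rfd must be > 0",
                                    paste(bad_rfd, collapse = ", ")))
  }
  bad_sf <- which(!is.na(x$sf) & !x$metal %in% egg_carcinogens())
  if (length(bad_sf) > 0) {
    problems <- c(problems, sprintf(
      "toxicity row %s: slope factor given for non-carcinogen %s (allowed: %s)",
      paste(bad_sf, collapse = ", "),
      paste(x$metal[bad_sf], collapse = ", "),
      paste(egg_carcinogens(), collapse = ", ")))
  }
  neg_sf <- which(!is.na(x$sf) & x$sf < 0)
  if (length(neg_sf) > 0) {
    problems <- c(problems, sprintf("toxicity row %s: sf must be >= 0",
                                    paste(neg_sf, collapse = ", ")))
  }
  if (anyDuplicated(x$metal)) {
    problems <- c(problems, "duplicate metal in toxicity table")
  }
  if (length(problems) > 0) {
    abort(c("Invalid toxicity reference table.",
            setNames(problems, rep("x", length(problems)))),
          class = "eggrisk_validation_error")
  }
  x[, c("metal", "rfd", "sf")]
}

validate_limits <- function(x) {
  x <- tibble::as_tibble(x)
  required <- c("metal", "authority", "limit")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(c("Regulatory limit table is missing columns.",
            x = paste("Missing:", paste(missing_cols, collapse = ", "))),
          class = "eggrisk_schema_error")
  }
  problems <- character(0)
  bad_lim <- which(is.na(x$limit) | x$limit <= 0)
  if (length(bad_lim) > 0) {
    problems <- c(problems, sprintf("limit row %s: limit must be > 0",
                                    paste(bad_lim, collapse = ", ")))
  }
  bad_auth <- which(!x$authority %in% .limit_authorities)
  if (length(bad_auth) > 0) {
    problems <- c(problems, sprintf(
      "limit row %s: authority must be one of %s",
      paste(bad_auth, collapse = ", "),
      paste(.limit_authorities, collapse = ", ")))
  }
  if (anyDuplicated(x[, c("metal", "authority")])) {
    problems <- c(problems, "duplicate (metal, authority) pair in limit table")
  }
  if (length(problems) > 0) {
    abort(c("Invalid regulatory limit table.",
            setNames(problems, rep("x", length(problems)))),
          class = "eggrisk_validation_error")
  }
  x[, required]
}

#' Read exposure, toxicity and regulatory-limit reference tables
#'
#' Reads one hierarchical YAML configuration holding the three reference
#' tables that feed the risk equations:
#'
#' * `exposure_profiles`: per population group, body weight `BW` (kg), egg
#'   intake rate `FIR` (g/person/day), exposure frequency `EF` (days/year),
#'   exposure duration `ED` (years) and averaging time `AT` (days).
#' * `toxicity`: per metal, oral reference dose `rfd` (mg/kg/day) and, for
#'   carcinogens only (Cr, Cd, Pb), cancer slope factor `sf`
#'   ((mg/kg/day)^-1).
#' * `limits`: per metal and authority, the regulatory maximum level (mg/kg).
#'
#' A worked-example file with USEPA-style reference doses and slope factors
#' ships with the package; see
#' `system.file("extdata", "example_reference.yaml", package = "eggrisk")`.
#' Those values are illustrative configuration, not authoritative toxicology.
#'
#' @param path Path to a YAML file with sections `exposure_profiles`,
#'   `toxicity` and `limits`.
#' @return A list with tibbles `profiles`, `toxicity` and `limits`.
#' @export
read_reference_tables <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "eggrisk_io_error")
  }
  cfg <- yaml::read_yaml(path)
  section <- function(name) {
    if (is.null(cfg[[name]])) {
      abort(paste0("Reference file lacks section `", name, "`."),
            class = "eggrisk_schema_error")
    }
    dplyr::bind_rows(lapply(cfg[[name]], tibble::as_tibble))
  }
  list(
    profiles = validate_exposure_profiles(section("exposure_profiles")),
    toxicity = validate_toxicity(section("toxicity")),
    limits   = validate_limits(section("limits"))
  )
}

#' Export a validated dataset as JSON
#'
#' @param records Validated concentration records.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
export_dataset_json <- function(records, path) {
  payload <- list(
    basis = attr(records, "basis") %||% "dry",
    n_records = nrow(records),
    records = records
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
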