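# shared arithmetic kernels: the exported scalar operations and the Monte
# Carlo engine both call these, so degenerate (point-mass) simulations
# reproduce deterministic results bit for bit. FIR is stored in g/day and
# converted to kg/day here and nowhere else.
.edi <- function(conc, fir, bw) {
  conc * (fir / 1000) / bw
}

.thq <- function(conc, fir, bw, ef, ed, at, rfd) {
  (ef * ed * (fir / 1000) * conc) / (rfd * bw * at)
}

check_profile <- function(profile) {
  validate_exposure_profiles(tibble::as_tibble(profile))
}

#' Estimated daily intake (EDI)
#'
#' EDI = C x FIR / BW, with the intake rate FIR converted from g/day to
#' kg/day inside this function (and in [thq()]) only, so the conversion is
#' never double-applied. Units: mg of metal per kg body weight per day.
#'
#' @param conc Concentration in the food item, mg/kg. Vectorised.
#' @param profile A one-row exposure profile (fields `BW`, `FIR`, `EF`,
#'   `ED`, `AT`).
#' @return EDI in mg/kg/day.
#' @export
#' @examples
#' p <- tibble::tibble(group = "male", BW = 60, FIR = 30,
#'                     EF = 365, ED = 70, AT = 25550)
#' edi(10, p)  # 0.005 mg/kg/day
edi <- function(conc, profile) {
  profile <- check_profile(profile)
  if (any(conc < 0)) abort("Concentration must be >= 0.")
  .edi(conc, profile$FIR, profile$BW)
}

#' Target hazard quotient (THQ)
#'
#' THQ = (EF x ED x FIR x C) / (RfD x BW x AT), dimensionless. When the
#' averaging time equals the exposed time (EF x ED = AT) this reduces
#' algebraically to EDI / RfD.
#'
#' @inheritParams edi
#' @param rfd Oral reference dose, mg/kg/day; must be > 0.
#' @return THQ, dimensionless.
#' @export
thq <- function(conc, profile, rfd) {
  profile <- check_profile(profile)
  if (any(conc < 0)) abort("Concentration must be >= 0.")
  if (!is.numeric(rfd) || length(rfd) != 1 || is.na(rfd) || rfd <= 0) {
    abort("`rfd` must be a single positive number (mg/kg/day).")
  }
  .thq(conc, profile$FIR, profile$BW, profile$EF, profile$ED, profile$AT, rfd)
}

#' Hazard index (HI)
#'
#' The cumulative non-carcinogenic risk metric: the sum of target hazard
#' quotients over metals. The HI of an empty set is undefined and raises an
#' error rather than returning 0.
#'
#' @param thqs Numeric vector of non-negative THQ values, optionally named by
#'   metal.
#' @return The hazard index (sum of `thqs`).
#' @export
hazard_index <- function(thqs) {
  if (length(thqs) == 0) {
    abort("Hazard index of an empty THQ set is undefined.")
  }
  if (any(is.na(thqs)) || any(thqs < 0)) {
    abort("All THQ values must be non-negative and non-missing.")
  }
  sum(thqs)
}

#' Carcinogenic risk (CR)
#'
#' Incremental lifetime cancer probability CR = EDI x SF.
#'
#' @param e Estimated daily intake, mg/kg/day. Vectorised.
#' @param sf Cancer slope factor, (mg/kg/day)^-1; must be present and >= 0.
#' @param metal Optional metal name used in error messages.
#' @return CR, a dimensionless lifetime probability.
#' @export
cancer_risk <- function(e, sf, metal = NULL) {
  if (is.null(sf) || length(sf) != 1 || is.na(sf)) {
    abort(paste0("No slope factor available",
                 if (!is.null(metal)) paste0(" for ", metal), "."))
  }
  if (sf < 0) abort("Slope factor must be >= 0.")
  e * sf
}

#' Total carcinogenic risk (TCR)
#'
#' TCR = CR(Cr) + CR(Cd) + CR(Pb); exactly those three keys must be present.
#'
#' @param crs Named numeric vector with entries `Cr`, `Cd` and `Pb`.
#' @return TCR, dimensionless.
#' @export
#' @examples
#' total_cancer_risk(c(Cr = 4.2e-5, Cd = 1.7e-5, Pb = 5.0e-8))
total_cancer_risk <- function(crs) {
  want <- egg_carcinogens()
  if (is.null(names(crs)) || !setequal(names(crs), want) ||
      length(crs) != length(want)) {
    abort(paste0("`crs` must be named with exactly: ",
                 paste(want, collapse = ", ")))
  }
  if (any(is.na(crs)) || any(crs < 0)) {
    abort("All CR values must be non-negative and non-missing.")
  }
  sum(crs[want])
}

#' Classify a hazard index against the USEPA threshold of 1
#'
#' Values below 1 indicate no expected non-carcinogenic effect; values of 1
#' or above flag potential adverse effects (the boundary itself is flagged).
#'
#' @param hi Non-negative hazard index (or THQ). Vectorised.
#' @return Character vector, `"no_concern"` or `"potential_adverse"`.
#' @export
classify_hi <- function(hi) {
  if (any(is.na(hi)) || any(hi < 0)) abort("HI must be non-negative.")
  ifelse(hi < 1, "no_concern", "potential_adverse")
}

#' Classify a carcinogenic risk into the USEPA bands
#'
#' Below 1e-6 the lifetime risk is negligible; between 1e-6 and 1e-4 it is
#' deemed acceptable; at or above 1e-4 it is potentially unacceptable (the
#' 1e-4 boundary is flagged, following the convention that risks >= 1e-4 may
#' pose a potential health risk).
#'
#' @param cr Non-negative carcinogenic risk (CR or TCR). Vectorised.
#' @return Character vector: `"negligible"`, `"acceptable"` or
#'   `"potentially_unacceptable"`.
#' @export
classify_cr <- function(cr) {
  if (any(is.na(cr)) || any(cr < 0)) abort("CR must be non-negative.")
  ifelse(cr < 1e-6, "negligible",
         ifelse(cr < 1e-4, "acceptable", "potentially_unacceptable"))
}

#' Deterministic risk assessment per area and population group
#'
#' Summarises concentrations per (area, metal) with the chosen statistic
#' (arithmetic mean by default, mirroring assessments that integrate the
#' average metal concentration with consumption rates), then applies the
#' EDI/THQ/HI and CR/TCR equations for every population group.
#'
#' @param records Validated concentration records.
#' @param profiles Exposure profile tibble (one row per population group).
#' @param toxicity Toxicity reference tibble (`metal`, `rfd`, `sf`).
#' @param summary Area-level concentration statistic: `"mean"` (default),
#'   `"median"` or `"max"`.
#' @param lod_method Below-LOD substitution convention passed to
#'   [substitute_lod()].
#' @return An object of class `eggrisk_assessment`: a list with
#'   * `by_metal`: tibble with one row per (area, group, metal) holding the
#'     summarised concentration, `edi`, `thq`, and for carcinogens `cr` and
#'     `cr_class`;
#'   * `summary`: tibble with one row per (area, group) holding `hi`,
#'     `hi_class`, and where all three carcinogens are present `tcr` and
#'     `tcr_class`.
#' @export
assess <- function(records, profiles, toxicity,
                   summary = c("mean", "median", "max"),
                   lod_method = "half") {
  summary <- match.arg(summary)
  profiles <- validate_exposure_profiles(profiles)
  toxicity <- validate_toxicity(toxicity)
  if (nrow(records) == 0) abort("No concentration records supplied.")
  records <- substitute_lod(records, lod_method)

  stat <- switch(summary, mean = mean, median = stats::median, max = max)
  conc <- records %>%
    dplyr::group_by(.data$area, .data$metal) %>%
    dplyr::summarise(concentration = stat(.data$concentration),
                     n = dplyr::n(), .groups = "drop")

  missing_rfd <- setdiff(unique(conc$metal), toxicity$metal)
  if (length(missing_rfd) > 0) {
    warn(paste0("No reference dose for: ",
                paste(missing_rfd, collapse = ", "),
                "; these metals are omitted from HI."))
    conc <- conc[!conc$metal %in% missing_rfd, ]
  }
  if (nrow(conc) == 0) abort("No metal has a configured reference dose.")

  by_metal <- tidyr::crossing(conc, group = profiles$group) %>%
    dplyr::left_join(profiles, by = "group") %>%
    dplyr::left_join(toxicity, by = "metal") %>%
    dplyr::mutate(
      edi = .edi(.data$concentration, .data$FIR, .data$BW),
      thq = .thq(.data$concentration, .data$FIR, .data$BW,
                 .data$EF, .data$ED, .data$AT, .data$rfd),
      cr = dplyr::if_else(!is.na(.data$sf), .data$edi * .data$sf, NA_real_),
      cr_class = dplyr::if_else(is.na(.data$cr), NA_character_,
                                classify_cr(dplyr::coalesce(.data$cr, 0)))
    ) %>%
    dplyr::arrange(.data$area, .data$group,
                   factor(.data$metal, levels = metal_levels(.data$metal))) %>%
    dplyr::select("area", "group", "metal", "concentration", "n",
                  "edi", "thq", "cr", "cr_class")

  carc <- egg_carcinogens()
  summary_tbl <- by_metal %>%
    dplyr::group_by(.data$area, .data$group) %>%
    dplyr::summarise(
      hi = hazard_index(.data$thq),
      tcr = if (all(carc %in% .data$metal) &&
                !anyNA(.data$cr[match(carc, .data$metal)])) {
        total_cancer_risk(setNames(.data$cr[match(carc, .data$metal)], carc))
      } else {
        NA_real_
      },
      .groups = "drop"
    ) %>%
    dplyr::mutate(
      hi_class = classify_hi(.data$hi),
      tcr_class = dplyr::if_else(is.na(.data$tcr), NA_character_,
                                 classify_cr(dplyr::coalesce(.data$tcr, 0)))
    )
  if (anyNA(summary_tbl$tcr)) {
    warn("TCR not computed for some (area, group) cells: slope factors or carcinogen records incomplete.")
  }

  structure(list(by_metal = by_metal, summary = summary_tbl,
                 summary_stat = summary),
            class = "eggrisk_assessment")
}

#' @export
print.eggrisk_assessment <- function(x, ...) {
  cat("<eggrisk_assessment> (area-level statistic:", x$summary_stat, ")\n")
  cat("Per-metal rows:", nrow(x$by_metal),
      "| area x group cells:", nrow(x$summary), "\n")
  print(x$summary, ...)
  invisible(x)
}

#' Export assessment results
#'
#' Writes the per-metal table and the area-by-group summary as CSV (one row
#' per area x group x metric) or JSON. Classification columns use the
#' lowercase tokens of [classify_hi()] and [classify_cr()].
#'
#' @param x An `eggrisk_assessment`.
#' @param path Output file path; format chosen by extension (.csv or .json).
#' @return `path`, invisibly.
#' @export
export_assessment <- function(x, path) {
  stopifnot(inherits(x, "eggrisk_assessment"))
  long <- x$by_metal %>%
    tidyr::pivot_longer(c("edi", "thq", "cr"), names_to = "metric",
                        values_to = "value") %>%
    dplyr::filter(!is.na(.data$value)) %>%
    dplyr::select("area", "group", "metal", "metric", "value")
  cells <- x$summary %>%
    tidyr::pivot_longer(c("hi", "tcr"), names_to = "metric",
                        values_to = "value") %>%
    dplyr::mutate(metal = NA_character_) %>%
    dplyr::filter(!is.na(.data$value)) %>%
    dplyr::select("area", "group", "metal", "metric", "value")
  out <- dplyr::bind_rows(long, cells)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  } else {
    readr::write_csv(out, path)
  }
  invisible(path)
}
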