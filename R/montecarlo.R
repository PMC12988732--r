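conc_key <- function(area, metal) paste(area, metal, sep = "||")

#' Build default Monte Carlo input specifications
#'
#' Maps every uncertain input of the risk equations to a [dist_spec]:
#'
#' * concentration, per (area, metal): `"empirical"` (bootstrap of the
#'   area's observed sample values, the default), `"lognormal"`
#'   (moment-matched on the log scale via [fit_lognormal()]) or `"point"`
#'   (the area mean);
#' * body weight `BW`, per group: normal truncated at zero with the profile
#'   value as mean and `bw_cv` as coefficient of variation;
#' * intake rate `FIR`, per group: triangular with mode at the profile value
#'   and range `fir_rel` times that value;
#' * `EF`, `ED`, `AT`: point masses (and, downstream, RfD and SF are treated
#'   as fixed constants).
#'
#' Every choice can be overridden by replacing entries of the returned list
#' before calling [run_mcs()]. A singleton concentration sample requested as
#' empirical or lognormal falls back to a point mass with a warning.
#'
#' @param records Validated concentration records.
#' @param profiles Exposure profile tibble.
#' @param concentration Concentration family: `"empirical"`, `"lognormal"`
#'   or `"point"`.
#' @param vary_exposure If `FALSE`, BW and FIR are point masses too.
#' @param bw_cv Coefficient of variation for body weight (default 0.1).
#' @param fir_rel Length-2 multiplier giving the triangular low/high for FIR
#'   relative to the profile value (default `c(0.5, 1.5)`).
#' @param lod_method Below-LOD substitution passed to [substitute_lod()].
#' @return An object of class `mc_specs`: a list with elements
#'   `concentration` (named `area||metal` -> spec) and `exposure` (named by
#'   group -> list of specs for BW, FIR, EF, ED, AT).
#' @export
build_default_specs <- function(records, profiles,
                                concentration = c("empirical", "lognormal", "point"),
                                vary_exposure = TRUE,
                                bw_cv = 0.1, fir_rel = c(0.5, 1.5),
                                lod_method = "half") {
  concentration <- match.arg(concentration)
  profiles <- validate_exposure_profiles(profiles)
  if (nrow(records) == 0) abort("No concentration records supplied.")
  records <- substitute_lod(records, lod_method)

  cells <- split(records$concentration,
                 list(area = records$area, metal = records$metal), drop = TRUE)
  conc_specs <- list()
  singletons <- character(0)
  for (nm in names(cells)) {
    v <- cells[[nm]]
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    key <- conc_key(parts[1], parts[2])
    if (length(v) < 2 && concentration != "point") {
      singletons <- c(singletons, key)
      conc_specs[[key]] <- dist_point(v)
    } else {
      conc_specs[[key]] <- switch(concentration,
        empirical = dist_empirical(v),
        lognormal = fit_lognormal(v),
        point = dist_point(mean(v)))
    }
  }
  if (length(singletons) > 0) {
    warn(paste0("Singleton samples fell back to point masses for: ",
                paste(singletons, collapse = ", ")))
  }

  exposure <- lapply(seq_len(nrow(profiles)), function(i) {
    p <- profiles[i, ]
    if (vary_exposure) {
      list(BW = dist_normal(p$BW, bw_cv * p$BW),
           FIR = dist_triangular(fir_rel[1] * p$FIR, p$FIR, fir_rel[2] * p$FIR),
           EF = dist_point(p$EF), ED = dist_point(p$ED), AT = dist_point(p$AT))
    } else {
      list(BW = dist_point(p$BW), FIR = dist_point(p$FIR),
           EF = dist_point(p$EF), ED = dist_point(p$ED), AT = dist_point(p$AT))
    }
  })
  names(exposure) <- profiles$group

  structure(list(concentration = conc_specs, exposure = exposure),
            class = "mc_specs",
            areas = sort(unique(records$area)),
            metals = metal_levels(unique(records$metal)))
}

#' @export
print.mc_specs <- function(x, ...) {
  cat("<mc_specs>", length(x$concentration), "concentration specs,",
      length(x$exposure), "exposure groups\n")
  invisible(x)
}

mcs_thresholds <- c(HI = 1, CR_Cr = 1e-4, CR_Cd = 1e-4, CR_Pb = 1e-4,
                    TCR = 1e-4)

#' Run the Monte Carlo risk simulation
#'
#' For every (area, group) cell, draws `n_iter` joint realisations of all
#' uncertain inputs and pushes each through the EDI/THQ/HI and CR/TCR
#' equations. Within one iteration a single concentration draw per metal and
#' a single BW/FIR draw are shared across all metals, preserving the
#' cross-metal dependence induced by body weight and intake so that HI is a
#' per-iteration sum. Summaries use type-7 (linear interpolation) sample
#' percentiles.
#'
#' One master seed spawns one child stream per (area, group) cell,
#' deterministically and in a fixed (sorted) cell order, so results are
#' reproducible bit for bit and invariant to evaluation order. The caller's
#' RNG state is left untouched.
#'
#' @param specs An `mc_specs` object (see [build_default_specs()]), possibly
#'   with entries overridden.
#' @param profiles Exposure profile tibble; defines the population groups to
#'   simulate (each must have an entry in `specs$exposure`).
#' @param toxicity Toxicity reference tibble.
#' @param n_iter Number of iterations (default 10000).
#' @param seed Master seed (integer).
#' @return A tibble of class `eggrisk_mcs` with one row per
#'   (area, group, metric), metric in `HI`, `CR_Cr`, `CR_Cd`, `CR_Pb`,
#'   `TCR`; columns `n_iter`, `seed`, `mean`, `p5`, `p50`, `p95` and
#'   `exceedance_prob` (fraction of draws at or above the metric's decision
#'   threshold: 1 for HI, 1e-4 for CR and TCR).
#' @export
run_mcs <- function(specs, profiles, toxicity, n_iter = 10000, seed = 1L) {
  stopifnot(inherits(specs, "mc_specs"))
  profiles <- validate_exposure_profiles(profiles)
  toxicity <- validate_toxicity(toxicity)
  if (n_iter < 1) abort("`n_iter` must be >= 1.")
  seed <- as.integer(seed)

  keys <- strsplit(names(specs$concentration), "||", fixed = TRUE)
  areas <- attr(specs, "areas") %||% sort(unique(vapply(keys, `[`, "", 1)))
  metals_req <- attr(specs, "metals") %||%
    metal_levels(unique(vapply(keys, `[`, "", 2)))
  groups <- sort(profiles$group)
  missing_grp <- setdiff(groups, names(specs$exposure))
  if (length(missing_grp) > 0) {
    abort(paste0("Missing exposure specs for group(s): ",
                 paste(missing_grp, collapse = ", ")))
  }

  cells <- expand.grid(area = areas, group = groups,
                       stringsAsFactors = FALSE)
  cells <- cells[order(cells$area, cells$group), , drop = FALSE]
  child_seeds <- withr::with_seed(
    seed, sample.int(.Machine$integer.max - 1L, nrow(cells)))

  carc <- egg_carcinogens()
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    area <- cells$area[i]
    group <- cells$group[i]
    metals_here <- metals_req[metals_req %in% toxicity$metal]
    if (length(metals_here) == 0) {
      abort(paste0("No metal with a reference dose for area ", area, "."))
    }
    rfd <- toxicity$rfd[match(metals_here, toxicity$metal)]
    sf <- toxicity$sf[match(metals_here, toxicity$metal)]
    exp_specs <- specs$exposure[[group]]
    for (nm in c("BW", "FIR", "EF", "ED", "AT")) {
      if (is.null(exp_specs[[nm]])) {
        abort(paste0("Missing distribution spec for exposure input ", nm,
                     " (group ", group, ")."))
      }
    }

    res <- withr::with_seed(child_seeds[i], {
      conc <- matrix(0, nrow = n_iter, ncol = length(metals_here),
                     dimnames = list(NULL, metals_here))
      for (m in metals_here) {
        sp <- specs$concentration[[conc_key(area, m)]]
        if (is.null(sp)) {
          abort(paste0("Missing concentration spec for area ", area,
                       ", metal ", m, "."))
        }
        conc[, m] <- dist_draw(sp, n_iter)
      }
      bw <- dist_draw(exp_specs$BW, n_iter)
      fir <- dist_draw(exp_specs$FIR, n_iter)
      ef <- dist_draw(exp_specs$EF, n_iter)
      ed <- dist_draw(exp_specs$ED, n_iter)
      at <- dist_draw(exp_specs$AT, n_iter)

      thq_mat <- conc
      edi_mat <- conc
      for (j in seq_along(metals_here)) {
        edi_mat[, j] <- .edi(conc[, j], fir, bw)
        thq_mat[, j] <- .thq(conc[, j], fir, bw, ef, ed, at, rfd[j])
      }
      draws <- list(HI = rowSums(thq_mat))
      carc_here <- metals_here[metals_here %in% carc & !is.na(sf)]
      for (m in carc_here) {
        draws[[paste0("CR_", m)]] <-
          edi_mat[, m] * sf[match(m, metals_here)]
      }
      if (all(carc %in% carc_here)) {
        draws$TCR <- rowSums(edi_mat[, carc, drop = FALSE] *
                               rep(sf[match(carc, metals_here)],
                                   each = n_iter))
      }
      draws
    })

    out[[i]] <- dplyr::bind_rows(lapply(names(res), function(metric) {
      x <- res[[metric]]
      q <- quantile(x, c(0.05, 0.5, 0.95), type = 7, names = FALSE)
      tibble::tibble(area = area, group = group, metric = metric,
                     n_iter = as.integer(n_iter), seed = seed,
                     mean = mean(x), p5 = q[1], p50 = q[2], p95 = q[3],
                     exceedance_prob = mean(x >= mcs_thresholds[[metric]]))
    }))
  }

  res <- dplyr::bind_rows(out)
  class(res) <- c("eggrisk_mcs", class(res))
  res
}

#' Decision table at the 95th percentile
#'
#' Classifies every simulated metric by its 95th percentile: hazard indices
#' through [classify_hi()], carcinogenic risks through [classify_cr()]. The
#' `flagged` column marks cells whose p95 meets or exceeds the decision
#' threshold (HI >= 1; CR or TCR >= 1e-4), mirroring the convention of
#' bolding risk-table cells at or above 1e-4.
#'
#' @param results An `eggrisk_mcs` tibble from [run_mcs()].
#' @return A tibble with `area`, `group`, `metric`, `p95`, `classification`
#'   and `flagged`.
#' @export
percentile_threshold_report <- function(results) {
  if (nrow(results) == 0) abort("Empty simulation results.")
  bad <- is.na(results$p95)
  if (any(bad)) {
    inform(paste0("Omitting ", sum(bad), " rows with missing p95."))
    results <- results[!bad, , drop = FALSE]
  }
  dplyr::tibble(
    area = results$area,
    group = results$group,
    metric = results$metric,
    p95 = results$p95,
    classification = ifelse(results$metric == "HI",
                            classify_hi(results$p95),
                            classify_cr(results$p95)),
    flagged = results$p95 >= unname(mcs_thresholds[results$metric])
  )
}

#' Monte Carlo convergence diagnostics
#'
#' Recomputes the 95th percentile of one metric in one (area, group) cell at
#' a ladder of iteration counts (same master seed) and reports the relative
#' change between successive sizes. The run is considered converged when the
#' change over the final step is below `tol` (default 1%).
#'
#' @inheritParams run_mcs
#' @param metric Metric to track (default `"HI"`).
#' @param area,group Cell to track; defaults to the first available cell.
#' @param n_grid Iteration counts (default 1e3, 5e3, 1e4, 5e4).
#' @param tol Relative-change tolerance for the final step.
#' @return A tibble with `n_iter`, `p95` and `rel_change`, with attribute
#'   `converged`.
#' @export
convergence_check <- function(specs, profiles, toxicity, seed = 1L,
                              metric = "HI", area = NULL, group = NULL,
                              n_grid = c(1e3, 5e3, 1e4, 5e4), tol = 0.01) {
  p95s <- vapply(n_grid, function(n) {
    r <- run_mcs(specs, profiles, toxicity, n_iter = n, seed = seed)
    if (is.null(area)) area <<- r$area[1]
    if (is.null(group)) group <<- r$group[1]
    row <- r[r$area == area & r$group == group & r$metric == metric, ]
    if (nrow(row) == 0) abort("Requested metric/cell not present in results.")
    row$p95
  }, numeric(1))
  rel <- c(NA_real_, abs(diff(p95s)) /
             ifelse(head(p95s, -1) == 0, 1, abs(head(p95s, -1))))
  out <- tibble::tibble(n_iter = as.integer(n_grid), p95 = p95s,
                        rel_change = rel)
  attr(out, "converged") <- rel[length(rel)] < tol
  out
}
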