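#' Descriptive summaries per (area, metal)
#'
#' @param records Validated concentration records.
#' @return Tibble with `area`, `metal`, `mean`, `sd`, `min`, `max`, `n`.
#' @export
summarize_concentrations <- function(records) {
  if (nrow(records) == 0) abort("No concentration records supplied.")
  records %>%
    dplyr::group_by(.data$area, .data$metal) %>%
    dplyr::summarise(mean = mean(.data$concentration),
                     sd = stats::sd(.data$concentration),
                     min = min(.data$concentration),
                     max = max(.data$concentration),
                     n = dplyr::n(), .groups = "drop") %>%
    dplyr::mutate(sd = dplyr::if_else(is.na(.data$sd), 0, .data$sd))
}

#' Rank metals by mean concentration within an area
#'
#' Orders metals by descending area mean. Exact ties are broken
#' alphabetically and flagged. Metals configured for the panel but absent
#' from the area's records are listed in the `absent` attribute rather than
#' ranked.
#'
#' @param records Validated concentration records.
#' @param area Area code to rank within.
#' @param metals Panel of metals expected (default [egg_metals()]).
#' @return Tibble with `metal`, `mean`, `rank`, `tied`; attribute `absent`
#'   lists panel metals without records.
#' @export
rank_metals <- function(records, area, metals = egg_metals()) {
  sub <- records[records$area == area, , drop = FALSE]
  if (nrow(sub) == 0) abort(paste0("No records for area ", area, "."))
  means <- tapply(sub$concentration, sub$metal, mean)
  tbl <- tibble::tibble(metal = names(means), mean = as.numeric(means))
  tbl <- tbl[order(-tbl$mean, tbl$metal), ]
  tbl$rank <- seq_len(nrow(tbl))
  tbl$tied <- duplicated(tbl$mean) | duplicated(tbl$mean, fromLast = TRUE)
  attr(tbl, "absent") <- setdiff(metals, tbl$metal)
  tbl
}

# Shapiro-Wilk on residuals (sample-size guarded) and Levene's test
# (median-centred, i.e. Brown-Forsythe); screens only, never hard gates
normality_screen <- function(x, g) {
  res <- x - tapply(x, g, mean)[g]
  if (length(res) < 3 || length(res) > 5000 || sd(res) == 0) {
    return(NA_real_)
  }
  tryCatch(shapiro.test(res)$p.value, error = function(e) NA_real_)
}

variance_screen <- function(x, g) {
  if (sd(x) == 0) return(NA_real_)
  tryCatch(car::leveneTest(x ~ g)[1, "Pr(>F)"], error = function(e) NA_real_)
}

#' Compare metal concentrations across groups
#'
#' One-way ANOVA per metal across the chosen grouping, with Tukey HSD
#' pairwise comparisons when the omnibus test is significant at `alpha`.
#' Normality (Shapiro-Wilk on residuals) and variance homogeneity
#' (median-centred Levene) are reported as screens but do not switch the
#' test; a Kruskal-Wallis alternative is available via `method`.
#' Groups with zero variance everywhere yield no finite F statistic and are
#' reported as degenerate, not significant.
#'
#' @param records Validated concentration records.
#' @param grouping `"area"`, `"production_system"` or `"mining_class"`.
#' @param alpha Significance level (default 0.05).
#' @param method `"anova"` (default) or `"kruskal"`.
#' @return Tibble with one row per metal: `metal`, `grouping`, `statistic`
#'   (F or Kruskal-Wallis chi-squared), `p_value`, `significant`,
#'   `degenerate`, `normality_p`, `levene_p`, and a `pairwise` list-column
#'   of Tukey results (`group_a`, `group_b`, `mean_diff`, `adjusted_p`).
#' @export
compare_groups <- function(records,
                           grouping = c("area", "production_system", "mining_class"),
                           alpha = 0.05,
                           method = c("anova", "kruskal")) {
  grouping <- match.arg(grouping)
  method <- match.arg(method)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be in (0, 1).")
  }
  g_all <- factor(records[[grouping]])
  if (nlevels(droplevels(g_all)) < 2) {
    abort(paste0("Need at least 2 groups to compare by ", grouping, "."))
  }

  out <- lapply(sort(unique(records$metal)), function(m) {
    sub <- records[records$metal == m, , drop = FALSE]
    x <- sub$concentration
    g <- droplevels(factor(sub[[grouping]]))
    if (nlevels(g) < 2 || any(table(g) < 2)) {
      abort(paste0("Metal ", m, ": every group needs >= 2 samples."))
    }

    degenerate <- sd(x) == 0 || all(tapply(x, g, sd) == 0)
    pairwise <- tibble::tibble(group_a = character(0), group_b = character(0),
                               mean_diff = numeric(0), adjusted_p = numeric(0))
    if (degenerate) {
      stat <- NA_real_
      p <- NA_real_
    } else if (method == "kruskal") {
      kt <- kruskal.test(x, g)
      stat <- unname(kt$statistic)
      p <- kt$p.value
    } else {
      fit <- aov(x ~ g)
      tab <- anova(fit)
      stat <- tab[["F value"]][1]
      p <- tab[["Pr(>F)"]][1]
      if (!is.na(p) && p < alpha) {
        tk <- TukeyHSD(fit)$g
        # reconstruct pairs positionally (level names may contain hyphens,
        # so rownames cannot be split); TukeyHSD reports pair (i, j) as
        # "level_j-level_i" in combn order
        pairs <- utils::combn(levels(g), 2)
        pairwise <- tibble::tibble(
          group_a = pairs[2, ],
          group_b = pairs[1, ],
          mean_diff = unname(tk[, "diff"]),
          adjusted_p = unname(tk[, "p adj"]))
      }
    }

    tibble::tibble(
      metal = m, grouping = grouping, statistic = stat, p_value = p,
      significant = !is.na(p) && p < alpha,
      degenerate = degenerate,
      normality_p = if (method == "anova") normality_screen(x, g) else NA_real_,
      levene_p = if (method == "anova") variance_screen(x, g) else NA_real_,
      pairwise = list(pairwise))
  })
  dplyr::bind_rows(out)
}

#' Screen concentrations against regulatory maximum levels
#'
#' Compares the maximum observed concentration of each metal against every
#' configured (metal, authority) limit. A concentration exactly equal to
#' the limit passes: limits are maximum permitted levels. Metals present in
#' the data but lacking a configured limit are reported as
#' `"no_limit_configured"`, never as passing.
#'
#' @param records Validated concentration records.
#' @param limits Regulatory limit tibble (`metal`, `authority`, `limit`).
#' @return Tibble with one row per (metal, authority): `max_concentration`,
#'   `limit`, `verdict` (`"pass"`, `"fail"`, `"no_limit_configured"`),
#'   `n_exceeding` and an `exceeding_samples` list-column of offending
#'   sample ids.
#' @export
compliance_screen <- function(records, limits) {
  if (nrow(records) == 0) abort("No concentration records supplied.")
  limits <- validate_limits(limits)

  metals_seen <- sort(unique(records$metal))
  per_limit <- limits[limits$metal %in% metals_seen, , drop = FALSE]
  rows <- lapply(seq_len(nrow(per_limit)), function(i) {
    lm <- per_limit[i, ]
    sub <- records[records$metal == lm$metal, , drop = FALSE]
    over <- sub$concentration > lm$limit
    tibble::tibble(
      metal = lm$metal, authority = lm$authority,
      max_concentration = max(sub$concentration), limit = lm$limit,
      verdict = if (any(over)) "fail" else "pass",
      n_exceeding = sum(over),
      exceeding_samples = list(unique(sub$sample_id[over])))
  })
  uncovered <- setdiff(metals_seen, limits$metal)
  rows_nc <- lapply(uncovered, function(m) {
    tibble::tibble(metal = m, authority = NA_character_,
                   max_concentration = max(records$concentration[records$metal == m]),
                   limit = NA_real_, verdict = "no_limit_configured",
                   n_exceeding = NA_integer_,
                   exceeding_samples = list(character(0)))
  })
  dplyr::bind_rows(c(rows, rows_nc))
}
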