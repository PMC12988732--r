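test_that("descriptive summaries are standard and complete", {
  rec <- generate_concentrations(generator_config(seed = 8, n_per_area = 6))
  s <- summarize_concentrations(rec)
  expect_equal(nrow(s), 9 * 10)
  expect_true(all(s$n == 6))
  expect_true(all(s$min <= s$mean & s$mean <= s$max))
  lims <- default_metal_params()
  j <- dplyr::left_join(s, lims, by = "metal")
  expect_true(all(j$min >= j$range_low & j$max <= j$range_high))

  const <- toy_records(areas = "A1", metals = "Cr", n = 4)
  const$concentration <- 0.5
  sc <- summarize_concentrations(const)
  expect_equal(sc$sd, 0)
  expect_equal(sc$min, sc$mean)
  expect_equal(sc$max, sc$mean)
})

test_that("metals rank by descending area mean with flagged ties", {
  params <- default_metal_params()
  params$base_cv <- 1e-4  # order fixed by the configured means
  rec <- generate_concentrations(generator_config(metals = params, seed = 3))
  rk <- rank_metals(rec, "GY")
  # expected order of the default calibration means (As and Pb midpoints
  # are within 7% of each other; As sits above Pb in this calibration)
  expect_identical(rk$metal,
                   c("Zn", "Cu", "Mn", "Se", "Cr", "Ni", "As", "Pb", "Co", "Cd"))
  expect_false(any(rk$tied))

  # exact ties are flagged and broken alphabetically
  tied <- toy_records(areas = "A1", metals = c("Cr", "Cd"), n = 2)
  tied$concentration <- 0.5
  rt <- rank_metals(tied, "A1")
  expect_true(all(rt$tied))
  expect_identical(rt$metal, c("Cd", "Cr"))

  single <- toy_records(areas = "A1", metals = "Cr", n = 2)
  rs <- rank_metals(single, "A1")
  expect_equal(nrow(rs), 1)
  expect_true("Cd" %in% attr(rs, "absent"))
})

test_that("ranking is invariant to sample order and uniform rescaling", {
  rec <- generate_concentrations(generator_config(seed = 14, n_per_area = 5))
  shuffled <- rec[sample(nrow(rec)), ]
  scaled <- rec
  scaled$concentration <- scaled$concentration * 3.7
  r0 <- rank_metals(rec, "DZ")
  expect_identical(rank_metals(shuffled, "DZ")$metal, r0$metal)
  expect_identical(rank_metals(scaled, "DZ")$metal, r0$metal)
})

test_that("group comparisons run ANOVA with Tukey follow-up", {
  cfg <- generator_config(free_range_factor = 3, clip = FALSE, seed = 42,
                          metals = c("Cd", "Pb"))
  rec <- generate_concentrations(cfg)
  cmp <- compare_groups(rec, "production_system")
  expect_equal(nrow(cmp), 2)
  expect_true(all(cmp$significant))
  expect_true(all(!cmp$degenerate))
  pw <- cmp$pairwise[[1]]
  expect_equal(nrow(pw), 1)  # two production systems -> one pair
  expect_true(all(pw$adjusted_p >= 0 & pw$adjusted_p <= 1))
  # free-range mean exceeds commercial under a 3x elevation
  means <- tapply(rec$concentration[rec$metal == "Cd"],
                  rec$production_system[rec$metal == "Cd"], mean)
  expect_gt(means[["free_range"]], means[["commercial"]])
})

test_that("Tukey-adjusted p-values are no smaller than unadjusted ones", {
  cfg <- generator_config(seed = 6, metals = "Mn")
  rec <- generate_concentrations(cfg)
  # force a significant omnibus by elevating three areas
  idx <- rec$area %in% c("DZ", "EM", "WC")
  rec$concentration[idx] <- rec$concentration[idx] * 1.8
  cmp <- compare_groups(rec, "area")
  pw <- cmp$pairwise[[1]]
  expect_gt(nrow(pw), 0)
  # unadjusted pairwise p from the same pooled error term
  fit <- stats::aov(concentration ~ area, data = rec)
  mse <- sum(stats::residuals(fit)^2) / fit$df.residual
  for (i in seq_len(nrow(pw))) {
    a <- rec$concentration[rec$area == pw$group_a[i]]
    b <- rec$concentration[rec$area == pw$group_b[i]]
    se <- sqrt(mse * (1 / length(a) + 1 / length(b)))
    raw_p <- 2 * stats::pt(-abs(mean(a) - mean(b)) / se, fit$df.residual)
    expect_gte(pw$adjusted_p[i] + 1e-12, raw_p)
  }
})

test_that("degenerate and undersized groups are handled explicitly", {
  const <- toy_records(areas = c("A1", "A2"), metals = "Cr", n = 3)
  const$concentration <- 1
  cmp <- compare_groups(const, "area")
  expect_true(cmp$degenerate)
  expect_false(cmp$significant)
  expect_true(is.na(cmp$statistic))

  one_area <- toy_records(areas = "A1", metals = "Cr", n = 3)
  expect_error(compare_groups(one_area, "area"), "at least 2 groups")

  tiny <- toy_records(areas = c("A1", "A2"), metals = "Cr", n = 1)
  expect_error(compare_groups(tiny, "area"), ">= 2 samples")
})

test_that("the Kruskal-Wallis flag swaps the omnibus test", {
  cfg <- generator_config(free_range_factor = 3, clip = FALSE, seed = 10,
                          metals = "Cd")
  rec <- generate_concentrations(cfg)
  cmp <- compare_groups(rec, "production_system", method = "kruskal")
  expect_true(cmp$significant)
  expect_true(is.na(cmp$normality_p))
})

test_that("compliance screening compares maxima against maximum levels", {
  rec <- generate_concentrations(generator_config(seed = 19, n_per_area = 4))
  limits <- tibble::tibble(metal = c("Pb", "Cd"), authority = "GB2762",
                           limit = c(0.2, 0.05))
  out <- compliance_screen(rec, limits)
  # all generated Pb <= 0.018 mg/kg, far below the 0.2 mg/kg maximum level
  expect_identical(out$verdict[out$metal == "Pb" & out$authority == "GB2762"],
                   "pass")
  expect_true(all(out$verdict[!is.na(out$authority)] == "pass"))
  # metals without a configured limit are reported, not passed
  expect_identical(sort(out$metal[out$verdict == "no_limit_configured"]),
                   sort(setdiff(egg_metals(), c("Pb", "Cd"))))

  # a sample exactly at the limit passes; above it fails with its id listed
  rec2 <- concentration_records(tibble::tibble(
    sample_id = c("s1", "s2"), area = "GY", production_system = "free_range",
    mining_class = "non_mining", metal = "Pb", concentration = c(0.2, 0.25)))
  out2 <- compliance_screen(rec2, limits)
  pb <- out2[out2$metal == "Pb", ]
  expect_identical(pb$verdict, "fail")
  expect_identical(pb$exceeding_samples[[1]], "s2")
  out3 <- compliance_screen(rec2[1, ], limits)
  expect_identical(out3$verdict[out3$metal == "Pb"], "pass")

  # empty limit table: everything is reported unconfigured
  empty <- tibble::tibble(metal = character(0), authority = character(0),
                          limit = numeric(0))
  out4 <- compliance_screen(rec2, empty)
  expect_true(all(out4$verdict == "no_limit_configured"))
})
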