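test_that("default spec building maps each input to its family", {
  rec <- generate_concentrations(generator_config(seed = 3, n_per_area = 5))
  prof <- toy_profiles()
  specs <- build_default_specs(rec, prof)
  expect_s3_class(specs, "mc_specs")
  expect_length(specs$concentration, 9 * 10)
  expect_true(all(vapply(specs$concentration, function(s) s$family, "") ==
                    "empirical"))
  # each empirical spec holds the area's sample values
  expect_length(specs$concentration[["GY||Cr"]]$params$values, 5)
  expect_identical(specs$exposure$male$BW$family, "normal")
  expect_identical(specs$exposure$male$FIR$family, "triangular")
  expect_identical(specs$exposure$male$EF$family, "point")

  # lognormal override is moment-matched per (area, metal)
  sl <- build_default_specs(rec, prof, concentration = "lognormal")
  v <- rec$concentration[rec$area == "GY" & rec$metal == "Cr"]
  expect_equal(sl$concentration[["GY||Cr"]]$params$meanlog, mean(log(v)))

  # point override produces constant draws
  sp <- build_default_specs(rec, prof, concentration = "point",
                            vary_exposure = FALSE)
  expect_equal(dist_draw(sp$concentration[["GY||Cr"]], 3), rep(mean(v), 3))
})

test_that("singleton samples fall back to point masses with a warning", {
  rec <- toy_records(areas = "A1", metals = "Cr", n = 1)
  expect_warning(specs <- build_default_specs(rec, toy_profile()),
                 "point masses")
  expect_identical(specs$concentration[["A1||Cr"]]$family, "point")
})

test_that("point-mass simulations reproduce the deterministic assessment exactly", {
  rec <- generate_concentrations(generator_config(seed = 21, n_per_area = 6))
  ref <- example_reference()
  det <- assess(rec, ref$profiles, ref$toxicity)
  specs <- build_default_specs(rec, ref$profiles, concentration = "point",
                               vary_exposure = FALSE)
  sim <- run_mcs(specs, ref$profiles, ref$toxicity, n_iter = 50, seed = 2)

  for (i in seq_len(nrow(det$summary))) {
    cell <- sim[sim$area == det$summary$area[i] &
                  sim$group == det$summary$group[i], ]
    hi_row <- cell[cell$metric == "HI", ]
    expect_equal(hi_row$p95, det$summary$hi[i], tolerance = 0)
    expect_equal(hi_row$p5, hi_row$p95, tolerance = 0)
    expect_equal(hi_row$mean, hi_row$p95, tolerance = 0)
    expect_equal(cell$p95[cell$metric == "TCR"], det$summary$tcr[i],
                 tolerance = 0)
  }
  crs <- sim[grepl("^CR_", sim$metric), ]
  crs$metal <- sub("^CR_", "", crs$metric)
  merged <- dplyr::inner_join(
    crs, det$by_metal[, c("area", "group", "metal", "cr")],
    by = c("area", "group", "metal"))
  expect_equal(merged$p95, merged$cr, tolerance = 0)
})

test_that("simulations are bit-reproducible and order-invariant under a seed", {
  rec <- generate_concentrations(generator_config(seed = 4, n_per_area = 4))
  ref <- example_reference()
  specs <- build_default_specs(rec, ref$profiles)
  r1 <- run_mcs(specs, ref$profiles, ref$toxicity, n_iter = 300, seed = 99)
  r2 <- run_mcs(specs, ref$profiles, ref$toxicity, n_iter = 300, seed = 99)
  expect_identical(r1, r2)

  # shuffling the profile table does not change any cell's result
  r3 <- run_mcs(specs, ref$profiles[c(3, 1, 2), ], ref$toxicity,
                n_iter = 300, seed = 99)
  expect_identical(r1, r3)

  # a different seed gives different draws
  r4 <- run_mcs(specs, ref$profiles, ref$toxicity, n_iter = 300, seed = 100)
  expect_false(identical(r1$p95, r4$p95))

  # the caller's RNG stream is untouched
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(run_mcs(specs, ref$profiles, ref$toxicity,
                                 n_iter = 50, seed = 5))
  expect_identical(runif(1), before)
})

test_that("summary order statistics are coherent", {
  rec <- generate_concentrations(generator_config(seed = 12, n_per_area = 5))
  ref <- example_reference()
  specs <- build_default_specs(rec, ref$profiles)
  sim <- run_mcs(specs, ref$profiles, ref$toxicity, n_iter = 500, seed = 1)
  expect_equal(nrow(sim), 9 * 3 * 5)  # areas x groups x metrics
  expect_true(all(sim$p5 <= sim$p50 & sim$p50 <= sim$p95))
  expect_true(all(sim$exceedance_prob >= 0 & sim$exceedance_prob <= 1))
  expect_true(all(sim$n_iter == 500L))
  # shared per-iteration draws: mean(HI) equals the sum of mean THQ
  # contributions, here checked as mean(TCR) = sum over metals of mean(CR)
  agg <- sim %>%
    dplyr::group_by(area, group) %>%
    dplyr::summarise(
      tcr = mean[metric == "TCR"],
      cr_sum = sum(mean[metric %in% c("CR_Cr", "CR_Cd", "CR_Pb")]),
      .groups = "drop")
  expect_equal(agg$tcr, agg$cr_sum, tolerance = 1e-12)
})

test_that("missing specs abort naming the gap", {
  rec <- toy_records(areas = "A1", metals = c("Cr", "Cd"))
  specs <- build_default_specs(rec, toy_profile())
  broken <- specs
  broken$concentration[["A1||Cr"]] <- NULL
  expect_error(run_mcs(broken, toy_profile(), toy_toxicity(), 10, 1),
               "A1, metal Cr")
  broken2 <- specs
  broken2$exposure$male$FIR <- NULL
  expect_error(run_mcs(broken2, toy_profile(), toy_toxicity(), 10, 1), "FIR")
})

test_that("the p95 decision table classifies and flags like the risk tables", {
  sim <- tibble::tibble(
    area = "A", group = "child",
    metric = c("HI", "CR_Cr", "CR_Cd", "TCR"),
    p95 = c(0.893, 1.0e-4, 5e-7, 9.7e-5))
  tab <- percentile_threshold_report(sim)
  expect_identical(tab$classification,
                   c("no_concern", "potentially_unacceptable", "negligible",
                     "acceptable"))
  expect_identical(tab$flagged, c(FALSE, TRUE, FALSE, FALSE))
  expect_error(percentile_threshold_report(sim[0, ]), "Empty")
  # rows with missing p95 are omitted, not classified
  sim$p95[2] <- NA
  expect_message(tab2 <- percentile_threshold_report(sim), "Omitting")
  expect_equal(nrow(tab2), 3)
})

test_that("convergence diagnostics detect the point-mass fixed point", {
  rec <- toy_records(areas = "A1", metals = c("Cr", "Cd"))
  specs <- build_default_specs(rec, toy_profile(), concentration = "point",
                               vary_exposure = FALSE)
  conv <- convergence_check(specs, toy_profile(), toy_toxicity(), seed = 6,
                            n_grid = c(100, 500, 1000))
  expect_equal(conv$rel_change[-1], rep(0, 2))
  expect_true(attr(conv, "converged"))
})

test_that("p95 estimates tighten as iterations grow", {
  rec <- generate_concentrations(generator_config(seed = 9, n_per_area = 10,
                                                  metals = c("Cr", "Se")))
  prof <- toy_profile()
  specs <- build_default_specs(rec, prof)
  spread <- vapply(c(250, 4000), function(n) {
    p95s <- vapply(1:8, function(s) {
      r <- run_mcs(specs, prof, toy_toxicity(), n_iter = n, seed = s)
      r$p95[r$area == "GY" & r$metric == "HI"]
    }, numeric(1))
    sd(p95s)
  }, numeric(1))
  expect_lt(spread[2], spread[1])
})
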