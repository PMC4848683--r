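test_that("identical config and seed reproduce the cohort byte for byte", {
  cfg <- small_config(seed = 11)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  tum <- generate_cohort(cfg)
  expect_identical(generate_field_counts(tum, cfg),
                   generate_field_counts(tum, cfg))
  expect_identical(generate_ki67(tum, cfg), generate_ki67(tum, cfg))
  expect_identical(generate_protein_panel(tum, cfg),
                   generate_protein_panel(tum, cfg))
  # different seed changes the draw
  expect_false(identical(tum, generate_cohort(small_config(seed = 12))))
})

test_that("noiseless growth is exactly linear from the detection threshold", {
  cfg <- cohort_config(n_rats_per_strain = c(DR = 30, DS = 30),
                       slope_g_per_week = c(DR = 0.5, DS = 0.5),
                       mass_noise_sd = 0, detection_threshold_g = 0.1,
                       seed = 3)
  tum <- generate_cohort(cfg)
  expect_equal(tum$necropsy_mass_g, 0.1 + 0.5 * tum$week_prior_to_end)
  expect_equal(tum$necropsy_mass_g[tum$week_prior_to_end == 4][1], 2.1)
})

test_that("configuration errors name the offending field", {
  expect_error(cohort_config(incidence = c(DR = 1.2, DS = 0.9)),
               "incidence")
  expect_error(cohort_config(ki67_mean_pct = c(DR = 101, DS = 9.4)),
               "ki67_mean_pct")
  expect_error(cohort_config(nb_dispersion = 0), "nb_dispersion")
  expect_error(cohort_config(n_fields_per_tumor = 0),
               "n_fields_per_tumor")
  bad <- default_panel()
  bad$means$DR <- bad$means$DR[1:28]
  expect_error(cohort_config(panel_means = bad$means,
                             panel_sds = bad$sds),
               "panel_means")
})

test_that("field counts follow gamma-Poisson moments", {
  one <- data.frame(tumor_id = "t1", rat_id = "r1", strain = "DR",
                    week_prior_to_end = 1, necropsy_mass_g = 0.5)
  # Poisson limit: enormous gamma shape makes variance/mean -> 1
  cfg <- cohort_config(mitotic_mean = c(DR = 0.448, DS = 0.448),
                       nb_dispersion = 1e6, n_fields_per_tumor = 1e5,
                       seed = 21)
  f <- generate_field_counts(one, cfg)
  expect_gt(var(f$mitotic_count) / mean(f$mitotic_count), 0.98)
  expect_lt(var(f$mitotic_count) / mean(f$mitotic_count), 1.02)
  # negative-binomial variance identity: var = m + m^2/k within 5%
  k <- 1.5
  cfg2 <- cohort_config(apoptotic_mean = c(DR = 2.616, DS = 2.616),
                        nb_dispersion = k, n_fields_per_tumor = 1e5,
                        seed = 22)
  f2 <- generate_field_counts(one, cfg2)
  expect_equal(var(f2$apoptotic_count), 2.616 + 2.616^2 / k,
               tolerance = 0.05)
  # variance >= mean holds across dispersions
  for (kk in c(0.5, 2, 10)) {
    cfgk <- cohort_config(nb_dispersion = kk, n_fields_per_tumor = 2000,
                          seed = 23)
    fk <- generate_field_counts(one, cfgk)
    expect_gte(var(fk$mitotic_count), 0.9 * mean(fk$mitotic_count))
  }
  expect_error(
    generate_field_counts(one, cohort_config(n_fields_per_tumor = 0)),
    "n_fields_per_tumor")
})

test_that("cell censuses stay in the clipped range around the mean", {
  cfg <- small_config(seed = 5)
  tum <- generate_cohort(cfg)
  f <- generate_field_counts(tum, cfg)
  expect_true(all(f$total_cells >= 500 & f$total_cells <= 1500))
  expect_equal(mean(f$total_cells), cfg$cells_per_field_mean,
               tolerance = 0.02)
  expect_true(all(f$mitotic_count <= f$total_cells))
})

test_that("Ki67 generation hits the configured mean and degenerates cleanly", {
  tum <- generate_cohort(small_config(seed = 6))
  cfg0 <- small_config(seed = 6, ki67_sd_pct = c(DR = 0, DS = 0))
  k0 <- generate_ki67(tum, cfg0)
  expect_true(all(k0$ki67_pct[k0$strain == "DR"] == 9.0))
  expect_true(all(k0$ki67_pct[k0$strain == "DS"] == 9.4))
  # CLT check: mean over 20 tumors within 3 SEM of the target in >= 99%
  sd20 <- 0.7 * sqrt(20)
  hits <- vapply(1:200, function(s) {
    set.seed(s)
    abs(mean(rnorm(20, 9.0, sd20)) - 9.0) <= 3 * 0.7
  }, TRUE)
  expect_gte(mean(hits), 0.99)
  got <- replicate(50, {
    t20 <- tum[sample(nrow(tum), 20), ]
    cfg <- small_config(seed = sample.int(1e6, 1),
                        ki67_mean_pct = c(DR = 9, DS = 9),
                        ki67_sd_pct = c(DR = sd20, DS = sd20))
    abs(mean(generate_ki67(t20, cfg)$ki67_pct) - 9.0) <= 3 * 0.7
  })
  expect_gte(mean(got), 0.9)
  expect_true(all(generate_ki67(tum, small_config(seed = 7))$ki67_pct > 0))
})

test_that("protein panel respects strain structure and dimensions", {
  tum <- generate_cohort(small_config(seed = 8))
  pnl <- default_panel()
  zero <- lapply(pnl$sds, function(x) x * 0)
  same <- list(DR = pnl$means$DR, DS = pnl$means$DR)
  cfg <- small_config(seed = 8, panel_means = same, panel_sds = zero)
  p <- generate_protein_panel(tum, cfg)
  xcols <- setdiff(names(p), c("tumor_id", "strain"))
  expect_equal(length(xcols), 29L)
  dr <- colMeans(p[p$strain == "DR", xcols])
  ds <- colMeans(p[p$strain == "DS", xcols])
  expect_equal(unname(dr - ds), rep(0, 29))
})
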