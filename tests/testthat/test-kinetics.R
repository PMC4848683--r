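test_that("cell-cycle duration reproduces the group-mean arithmetic", {
  # Ki67 % over mitotic figures per field, as-published unit mode
  expect_equal(cell_cycle_duration(9.0, 0.448), 20.09, tolerance = 1e-3)
  expect_equal(cell_cycle_duration(9.4, 0.571), 16.46, tolerance = 1e-3)
  expect_equal(cell_cycle_duration(10, 10), 1)
  # per-cell mode divides by the mitotic percentage instead
  expect_equal(cell_cycle_duration(9.0, 0.448, mode = "per-cell",
                                   cells_per_field = 850),
               9.0 / (100 * 0.448 / 850))
  expect_error(cell_cycle_duration(9.0, 0), "mitotic")
  expect_error(cell_cycle_duration(0, 0.4), "fraction")
})

test_that("duration estimators are monotone in their inputs", {
  pn <- seq(2, 20, by = 2)
  expect_true(all(diff(cell_cycle_duration(pn, 0.5)) > 0))
  mi <- seq(0.1, 2, by = 0.1)
  expect_true(all(diff(cell_cycle_duration(9, mi)) < 0))
  dn <- seq(0.5, 5, by = 0.5)
  dd <- apoptotic_duration(dn, pn = 10, pd = 20, delta_s = 0.2, n_rate = 1)
  expect_true(all(diff(dd) > 0))
  ds <- seq(0.05, 0.45, by = 0.05)
  dd2 <- apoptotic_duration(2, pn = 10, pd = 20, delta_s = ds, n_rate = 1)
  expect_true(all(diff(dd2) > 0))
})

test_that("unit conversions match hand arithmetic and round-trip", {
  expect_equal(grams_per_week_to_cells_per_hour(0.533),
               0.533 / (168 * 1e-9))
  expect_equal(round(grams_per_week_to_cells_per_hour(0.533) / 1e6, 3),
               3.173)
  expect_equal(round(grams_per_week_to_cells_per_hour(0.968) / 1e6, 3),
               5.762)
  expect_equal(grams_per_week_to_cells_per_hour(0), 0)
  expect_error(grams_per_week_to_cells_per_hour(-1), ">= 0")
  r <- c(0, 0.1, 0.533, 3.7)
  expect_equal(cells_per_hour_to_grams_per_week(
    grams_per_week_to_cells_per_hour(r)), r)
  expect_equal(delta_s_rate(1, 672), 1e9 / 672)
  expect_equal(delta_s_rate(0, 672), 0)
  expect_equal(delta_s_rate(2.1, 672), 3.125e6)
  expect_error(delta_s_rate(1, 0), "elapsed")
})

test_that("apoptotic duration solves the balance and flags undefined cases", {
  expect_equal(apoptotic_duration(dn = 2, pn = 10, pd = 20,
                                  delta_s = 0.25, n_rate = 1)[[1]], 8)
  # growth consuming the whole proliferative supply: undefined, not negative
  dd <- apoptotic_duration(dn = 1, pn = 10, pd = 20, delta_s = 0.5,
                           n_rate = 1)
  expect_true(is.na(dd[[1]]))
  expect_equal(attr(dd, "n_undefined"), 1L)
  over <- apoptotic_duration(dn = 1, pn = 10, pd = 20, delta_s = 0.9,
                             n_rate = 1)
  expect_true(is.na(over[[1]]))
  expect_error(apoptotic_duration(1, 10, 0, 0.1, 1), "cell-cycle")
  expect_error(apoptotic_duration(1, 10, 20, 0.1, 0), "growth rate")
  # no combination of positive inputs ever yields a negative duration
  set.seed(8)
  for (i in 1:200) {
    dd <- apoptotic_duration(runif(1, 0.1, 5), runif(1, 1, 20),
                             runif(1, 5, 40), runif(1, 0, 2),
                             runif(1, 0.5, 3))
    expect_true(is.na(dd[[1]]) || dd[[1]] > 0)
  }
})

test_that("noiseless forward simulation is recovered exactly", {
  # construct tumors satisfying the balance exactly, then invert it
  set.seed(9)
  n <- 50
  pn <- runif(n, 5, 15)
  pd <- runif(n, 10, 30)
  dn <- runif(n, 0.5, 4)
  dd_true <- runif(n, 2, 10)
  ratio <- pn / pd - dn / dd_true     # = delta_s / n_rate
  n_rate <- runif(n, 1e6, 6e6)
  delta_s <- ratio * n_rate
  # the balance always leaves a positive denominator here, so every
  # tumor's duration is recovered exactly (even where delta_s < 0)
  dd_hat <- apoptotic_duration(dn, pn, pd, delta_s, n_rate)
  expect_equal(as.numeric(dd_hat), dd_true, tolerance = 1e-12)
  expect_equal(attr(dd_hat, "n_undefined"), 0L)
})

test_that("percent differences reproduce the printed contrasts", {
  expect_equal(round(percent_difference(21.2, 17.7), 1), -16.5)
  expect_equal(round(percent_difference(4.7, 5.9), 1), 25.5)
  expect_equal(percent_difference(3.7, 3.7), 0)
  expect_error(percent_difference(0, 1), "nonzero")
})

test_that("group summaries report mean, SEM and percent difference", {
  est <- data.frame(tumor_id = sprintf("t%d", 1:4),
                    strain = c("DR", "DR", "DS", "DS"),
                    Pn = c(9, 9, 9.4, 9.4), mitotic_index = 0.5,
                    Dn = 2, Pd = c(20, 22, 17, 19),
                    delta_s_rate = 1, n_rate = 2, Dd = c(5, 5, 6, 6))
  s <- summarize_kinetics(est)
  dr_pd <- s$summary[s$summary$group == "DR" &
                       s$summary$variable == "Pd", ]
  expect_equal(dr_pd$mean, 21)
  expect_equal(dr_pd$sem, 1)
  dr_dd <- s$summary[s$summary$group == "DR" &
                       s$summary$variable == "Dd", ]
  expect_equal(dr_dd$sem, 0)
  expect_equal(unname(s$percent_difference["Pd:DS_vs_DR"]),
               percent_difference(21, 18))
  est$Dd[3] <- NA
  expect_error(summarize_kinetics(est), "fewer than 2")
})

test_that("percent difference of cycle durations lands near the target band", {
  # forward-constructed cohorts with group cycle durations 21.2 / 17.7 h
  hits <- vapply(1:200, function(s) {
    set.seed(10000 + s)
    pn_dr <- rnorm(20, 9.0, 0.3); pd_dr <- rnorm(20, 21.2, 1.0)
    pn_ds <- rnorm(20, 9.4, 0.3); pd_ds <- rnorm(20, 17.7, 1.0)
    est <- data.frame(
      tumor_id = sprintf("t%d", 1:40),
      strain = rep(c("DR", "DS"), each = 20),
      Pn = c(pn_dr, pn_ds),
      mitotic_index = c(pn_dr / pd_dr, pn_ds / pd_ds),
      Dn = 2, Pd = NA, delta_s_rate = 1, n_rate = 2, Dd = 5)
    est$Pd <- cell_cycle_duration(est$Pn, est$mitotic_index)
    pct <- summarize_kinetics(est)$percent_difference["Pd:DS_vs_DR"]
    pct >= -20 && pct <= -13
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("estimate_kinetics joins tables and flags week-0 tumors", {
  cfg <- small_config(seed = 13)
  tum <- generate_cohort(cfg)
  f <- generate_field_counts(tum, cfg)
  k <- generate_ki67(tum, cfg)
  est <- estimate_kinetics(tum, f, k,
                           c(DR = 0.533, DS = 0.968))
  expect_equal(nrow(est), nrow(tum))
  w0 <- est$tumor_id %in% tum$tumor_id[tum$week_prior_to_end == 0]
  expect_true(all(is.na(est$delta_s_rate[w0])))
  expect_true(all(is.na(est$Dd[w0])))
  ok <- !is.na(est$Dd)
  expect_true(all(est$Dd[ok] > 0))
  # Pn carried through from the Ki67 table
  expect_equal(est$Pn, k$ki67_pct[match(est$tumor_id, k$tumor_id)])
})
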