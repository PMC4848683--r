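test_that("index summaries match hand arithmetic and ignore row order", {
  f <- data.frame(tumor_id = "t1", field_index = 1:5,
                  total_cells = rep(5L, 5),
                  mitotic_count = c(0L, 1L, 1L, 2L, 1L),
                  apoptotic_count = 0L)
  idx <- compute_indices(f, "mitotic")
  expect_equal(idx$per_tumor$mean_per_field, 1.0)
  expect_equal(idx$per_tumor$mean_fraction, 0.2)
  zero <- compute_indices(f, "apoptotic")
  expect_equal(zero$per_tumor$mean_per_field, 0)
  expect_equal(zero$per_tumor$mean_fraction, 0)
  # invariance to field and tumor order
  f2 <- rbind(f, transform(f, tumor_id = "t0", mitotic_count = 2L))
  a <- compute_indices(f2, "mitotic")$per_tumor
  b <- compute_indices(f2[sample(nrow(f2)), ], "mitotic")$per_tumor
  expect_equal(a, b)
  expect_error(compute_indices(f[0, ], "mitotic"), "insufficient")
})

test_that("group index means recover the configured generating mean", {
  # CLT check against the configured apoptotic mean
  hits <- vapply(1:60, function(s) {
    cfg <- cohort_config(n_rats_per_strain = c(DR = 2, DS = 25),
                         incidence = c(DR = 1, DS = 1),
                         multiplicity_mean = c(DR = 1.01, DS = 1.01),
                         apoptotic_mean = c(DR = 2.616, DS = 2.616),
                         n_fields_per_tumor = 10L, seed = 400 + s)
    tum <- generate_cohort(cfg)
    f <- generate_field_counts(tum, cfg)
    grp <- setNames(tum$strain, tum$tumor_id)
    gs <- compute_indices(f, "apoptotic", groups = grp)$group_summary
    ds <- gs[gs$group == "DS", ]
    abs(ds$mean_per_field - 2.616) <= 3 * ds$sem_per_field
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("Poisson fit is the sample-mean ML fit", {
  f0 <- fit_poisson(c(1L, 1L, 1L, 1L))
  expect_equal(f0$mean, 1)
  expect_equal(f0$variance_mean_ratio, 0)
  set.seed(14)
  big <- rpois(1e5, 2)
  fb <- fit_poisson(big)
  expect_gt(fb$mean, 1.98); expect_lt(fb$mean, 2.02)
  expect_equal(fb$log_likelihood, sum(dpois(big, mean(big), log = TRUE)))
  expect_error(fit_poisson(integer(0)), "empty")
  expect_error(fit_poisson(c(1L, -1L)), "non-negative")
})

test_that("negative-binomial ML recovers parameters and matches a grid oracle", {
  set.seed(15)
  x <- rnbinom(1e5, mu = 2.6, size = 1.5)
  fit <- fit_negbin(x)
  expect_equal(fit$mean, 2.6, tolerance = 0.02)
  expect_equal(fit$dispersion, 1.5, tolerance = 0.10)
  # brute-force joint grid oracle on a small sample
  set.seed(16)
  xs <- rnbinom(40, mu = 3, size = 2)
  small <- fit_negbin(xs)
  mu_grid <- seq(0.5, 8, by = 0.01)
  k_grid <- exp(seq(log(0.05), log(80), length.out = 700))
  best <- c(-Inf, NA, NA)
  for (k in k_grid) {
    ll <- vapply(mu_grid,
                 function(m) sum(dnbinom(xs, mu = m, size = k, log = TRUE)),
                 0)
    j <- which.max(ll)
    if (ll[j] > best[1]) best <- c(ll[j], mu_grid[j], k)
  }
  expect_equal(small$mean, best[2], tolerance = 0.011)
  expect_equal(log(small$dispersion), log(best[3]), tolerance = 0.02)
  expect_gte(small$log_likelihood, best[1] - 1e-6)
})

test_that("equidispersed data hits the Poisson limit instead of failing", {
  x <- c(2L, 2L, 2L, 2L, 1L, 3L, 2L, 2L)  # var < mean
  fit <- fit_negbin(x)
  expect_true(fit$poisson_limit)
  expect_equal(fit$dispersion, Inf)
  expect_gte(fit$aic, fit_poisson(x)$aic - 2)
  expect_error(fit_negbin(c(0L, 0L, 0L, 0L, 0L)), "degenerate")
})

test_that("AIC never favors the mixture strongly when data are Poisson", {
  set.seed(17)
  wins <- vapply(1:100, function(i) {
    x <- rpois(200, 2)
    fit_negbin(x)$aic < fit_poisson(x)$aic - 2
  }, TRUE)
  expect_lte(mean(wins), 0.10)
})

test_that("overdispersion test detects gamma mixing and respects preconditions", {
  set.seed(18)
  od <- overdispersion_test(rnbinom(1e4, mu = 1, size = 0.5))
  expect_lt(od$p_value, 0.001)
  expect_gt(od$variance_mean_ratio, 1)
  expect_error(overdispersion_test(rpois(5, 1)), "at least 10")
  expect_error(overdispersion_test(rep(2L, 20)), "degenerate")
})

test_that("group comparison handles null, signal and probability scales", {
  set.seed(19)
  x <- rnbinom(200, mu = 2, size = 2)
  same <- compare_groups_nb(x, x, cells_a = rep(850, 200),
                            cells_b = rep(850, 200))
  expect_equal(same$ratio, 1)
  expect_gt(same$p_value, 0.99)
  expect_equal(same$prob_a, mean(x) / 850)
  expect_error(compare_groups_nb(rep(0L, 10), rep(0L, 10)), "degenerate")
  # 20 tumors x 10 fields per group at the strain mitotic means:
  # two-sided p distribution spans the reported-scale outcomes
  run_p <- function(seed, mean_a, mean_b) {
    set.seed(seed)
    compare_groups_nb(rnbinom(200, mu = mean_a, size = 1.5),
                      rnbinom(200, mu = mean_b, size = 1.5))$p_value
  }
  p_mit <- vapply(1:200, run_p, 0, mean_a = 0.448, mean_b = 0.571)
  expect_gte(median(p_mit), 0.01)
  expect_lte(median(p_mit), 0.5)
  # apoptotic means give >= 40% rejection at the 5% level
  p_apo <- vapply(201:400, run_p, 0, mean_a = 1.877, mean_b = 2.616)
  expect_gte(mean(p_apo < 0.05), 0.40)
  # likelihood-ratio variant agrees in order of magnitude
  set.seed(20)
  a <- rnbinom(200, mu = 1.877, size = 1.5)
  b <- rnbinom(200, mu = 2.616, size = 1.5)
  pw <- compare_groups_nb(a, b)$p_value
  pl <- compare_groups_nb(a, b, test = "lrt")$p_value
  expect_lt(abs(log10(pw) - log10(pl)), 1)
})
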