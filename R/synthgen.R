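# Synthetic cohort generation: two rat strains (DR = dietary obesity
# resistant, DS = sensitive), MNU-initiated mammary carcinomas detected by
# twice-weekly palpation at ~100 mg, necropsy at study end. Downstream
# modules (growth regression, kinetic deconvolution, count models,
# multivariate analysis) are all exercisable on these cohorts.

#' Configuration for a synthetic two-strain tumor cohort
#'
#' Builds and validates the parameter set used by [generate_cohort()],
#' [generate_field_counts()], [generate_ki67()] and
#' [generate_protein_panel()]. Defaults describe a cohort of dietary
#' obesity-resistant (DR) and obesity-sensitive (DS) rats carrying
#' chemically induced mammary carcinomas: palpation detects tumors at about
#' 0.1 g, the study runs nine weeks post-carcinogen, and necropsy mass
#' accumulates linearly in expectation with strain-specific slopes.
#'
#' @param n_rats_per_strain named integer vector, rats per strain.
#' @param incidence named numeric in \[0,1\], probability a rat bears at
#'   least one carcinoma.
#' @param multiplicity_mean named numeric > 1, mean carcinomas per
#'   tumor-bearing rat (truncated-Poisson mean).
#' @param slope_g_per_week named numeric > 0, expected necropsy-mass gain
#'   per week of growth after detection (g/week).
#' @param mass_noise_sd numeric >= 0, standard deviation (g) of the
#'   Gaussian noise on post-detection mass gain; tumors detected in the
#'   final study week carry no growth noise (they are pinned near the
#'   palpation threshold).
#' @param detection_threshold_g numeric > 0, palpation detection mass (g).
#' @param detection_window_weeks integer >= 1, detection weeks run from 0
#'   (found at termination) back to this many weeks prior to study end.
#' @param study_weeks integer >= 1, weeks from carcinogen to termination.
#' @param cells_per_field_mean,cells_per_field_sd per-field cell census
#'   (counts are clipped to \[500, 1500\]).
#' @param mitotic_mean,apoptotic_mean named numeric > 0, expected figures
#'   per field per strain.
#' @param nb_dispersion numeric > 0, gamma-mixing shape k of the
#'   negative-binomial counts (variance = mean + mean^2/k).
#' @param ki67_mean_pct,ki67_sd_pct named numeric, Ki67 immunoreactive
#'   percent per strain; means must lie in (0, 100).
#' @param n_fields_per_tumor integer >= 1, fields sampled per tumor.
#' @param hotspot_percent numeric in \[0,100\], fraction of fields flagged
#'   as Ki67 hotspots (rounded up to whole fields).
#' @param panel_means,panel_sds per-strain named lists of length-29 numeric
#'   vectors for the protein/count/IHC predictor panel; see
#'   [default_panel()].
#' @param seed integer RNG seed; each generator derives its own child seed
#'   so stages can be re-run in isolation.
#'
#' @return A validated list of class `"cohort_config"`.
#' @seealso [generate_cohort()], [default_panel()]
#' @export
#' @examples
#' cfg <- cohort_config(seed = 1)
#' tum <- generate_cohort(cfg)
#' table(tum$strain)
cohort_config <- function(n_rats_per_strain = c(DR = 103, DS = 101),
                          incidence = c(DR = 0.65, DS = 0.91),
                          multiplicity_mean = c(DR = 2.14, DS = 2.82),
                          slope_g_per_week = c(DR = 0.533, DS = 0.968),
                          mass_noise_sd = 0.6,
                          detection_threshold_g = 0.1,
                          detection_window_weeks = 4L,
                          study_weeks = 9L,
                          cells_per_field_mean = 850,
                          cells_per_field_sd = 80,
                          mitotic_mean = c(DR = 0.448, DS = 0.571),
                          apoptotic_mean = c(DR = 1.877, DS = 2.616),
                          nb_dispersion = 1.5,
                          ki67_mean_pct = c(DR = 9.0, DS = 9.4),
                          ki67_sd_pct = c(DR = 3.0, DS = 3.0),
                          n_fields_per_tumor = 10L,
                          hotspot_percent = 0,
                          panel_means = NULL,
                          panel_sds = NULL,
                          seed = 1L) {
  if (is.null(panel_means) || is.null(panel_sds)) {
    pnl <- default_panel()
    if (is.null(panel_means)) panel_means <- pnl$means
    if (is.null(panel_sds)) panel_sds <- pnl$sds
  }
  cfg <- list(
    n_rats_per_strain = n_rats_per_strain,
    incidence = incidence,
    multiplicity_mean = multiplicity_mean,
    slope_g_per_week = slope_g_per_week,
    mass_noise_sd = mass_noise_sd,
    detection_threshold_g = detection_threshold_g,
    detection_window_weeks = as.integer(detection_window_weeks),
    study_weeks = as.integer(study_weeks),
    cells_per_field_mean = cells_per_field_mean,
    cells_per_field_sd = cells_per_field_sd,
    mitotic_mean = mitotic_mean,
    apoptotic_mean = apoptotic_mean,
    nb_dispersion = nb_dispersion,
    ki67_mean_pct = ki67_mean_pct,
    ki67_sd_pct = ki67_sd_pct,
    n_fields_per_tumor = as.integer(n_fields_per_tumor),
    hotspot_percent = hotspot_percent,
    panel_means = panel_means,
    panel_sds = panel_sds,
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_config(cfg)
  cfg
}

#' @keywords internal
config_error <- function(field, why) {
  stop(sprintf("invalid configuration field '%s': %s", field, why),
       call. = FALSE)
}

#' Validate a cohort configuration
#'
#' Checks every invariant (probabilities in \[0,1\], positive means and
#' dispersions, panel dimensions) and stops with an error naming the
#' offending field.
#'
#' @param config a `"cohort_config"` list.
#' @return `config`, invisibly, if valid.
#' @export
validate_config <- function(config) {
  strains <- names(config$n_rats_per_strain)
  if (is.null(strains) || length(strains) < 1L)
    config_error("n_rats_per_strain", "must be a named vector of counts")
  chk_named <- function(x, nm) {
    if (!all(strains %in% names(config[[nm]])))
      config_error(nm, "must carry one entry per strain")
  }
  for (nm in c("incidence", "multiplicity_mean", "slope_g_per_week",
               "mitotic_mean", "apoptotic_mean", "ki67_mean_pct",
               "ki67_sd_pct"))
    chk_named(config[[nm]], nm)
  if (any(config$n_rats_per_strain < 1))
    config_error("n_rats_per_strain", "must be >= 1")
  if (any(config$incidence < 0 | config$incidence > 1))
    config_error("incidence", "probabilities must lie in [0, 1]")
  if (any(config$multiplicity_mean <= 1))
    config_error("multiplicity_mean",
                 "mean tumors per tumor-bearing rat must exceed 1")
  if (any(config$slope_g_per_week < 0))
    config_error("slope_g_per_week", "must be >= 0")
  if (config$mass_noise_sd < 0)
    config_error("mass_noise_sd", "must be >= 0")
  if (config$detection_threshold_g <= 0)
    config_error("detection_threshold_g", "must be > 0")
  if (config$study_weeks < 1)
    config_error("study_weeks", "must be >= 1")
  if (config$detection_window_weeks < 1 ||
      config$detection_window_weeks > config$study_weeks)
    config_error("detection_window_weeks",
                 "must lie in [1, study_weeks]")
  if (config$cells_per_field_mean <= 0 || config$cells_per_field_sd < 0)
    config_error("cells_per_field_mean", "census mean must be > 0, sd >= 0")
  if (any(config$mitotic_mean <= 0))
    config_error("mitotic_mean", "must be > 0")
  if (any(config$apoptotic_mean <= 0))
    config_error("apoptotic_mean", "must be > 0")
  if (config$nb_dispersion <= 0)
    config_error("nb_dispersion", "gamma shape must be > 0")
  if (any(config$ki67_mean_pct <= 0 | config$ki67_mean_pct >= 100))
    config_error("ki67_mean_pct", "means must lie strictly in (0, 100)")
  if (any(config$ki67_sd_pct < 0))
    config_error("ki67_sd_pct", "must be >= 0")
  if (config$n_fields_per_tumor < 1)
    config_error("n_fields_per_tumor", "must be >= 1")
  if (config$hotspot_percent < 0 || config$hotspot_percent > 100)
    config_error("hotspot_percent", "must lie in [0, 100]")
  for (s in strains) {
    if (length(config$panel_means[[s]]) != 29L)
      config_error("panel_means",
                   sprintf("strain %s needs exactly 29 entries, got %d",
                           s, length(config$panel_means[[s]])))
    if (length(config$panel_sds[[s]]) != 29L)
      config_error("panel_sds",
                   sprintf("strain %s needs exactly 29 entries, got %d",
                           s, length(config$panel_sds[[s]])))
    if (any(config$panel_sds[[s]] < 0))
      config_error("panel_sds", "must be >= 0")
  }
  invisible(config)
}

#' Default 29-variable predictor panel
#'
#' Per-strain means and standard deviations for the predictor panel fed to
#' the multivariate stage: G1/S checkpoint and apoptosis regulators
#' (GAPDH-normalized expression, arbitrary units) plus histology count and
#' immunohistochemistry variables. The DS strain carries upward shifts in
#' XIAP, cleaved caspase 3, cytochrome c, phospho-Rb, cyclin E, E2F1 and
#' cdc6 and downward shifts in p21, Apaf-1 and Bax, mirroring the direction
#' of the group differences the analysis is designed to detect.
#'
#' @return list with `variables` (29 names), `means` and `sds`
#'   (per-strain named lists of length-29 named numeric vectors).
#' @export
default_panel <- function() {
  vars <- c("p21", "p27", "cdk2", "cdk4", "cyclin_D1", "cyclin_E", "E2F1",
            "phospho_Rb", "total_Rb", "cdc6", "IP_E2F1_Rb", "IP_E2F1",
            "XIAP", "cleaved_caspase3", "total_caspase3", "cytochrome_c",
            "Apaf1", "Bax", "Bcl2", "survivin", "PCNA", "GAPDH_qc",
            "mitotic_index", "apoptotic_index", "ki67_pct",
            "cells_per_field", "necrosis_pct", "phospho_total_Rb_ratio",
            "cdc25A")
  base <- c(p21 = 1.0, p27 = 1.0, cdk2 = 1.2, cdk4 = 1.1, cyclin_D1 = 0.9,
            cyclin_E = 0.8, E2F1 = 0.7, phospho_Rb = 1.0, total_Rb = 1.5,
            cdc6 = 0.6, IP_E2F1_Rb = 0.5, IP_E2F1 = 0.4, XIAP = 1.0,
            cleaved_caspase3 = 0.5, total_caspase3 = 1.2,
            cytochrome_c = 0.9, Apaf1 = 1.1, Bax = 1.0, Bcl2 = 0.8,
            survivin = 0.6, PCNA = 1.3, GAPDH_qc = 1.0,
            mitotic_index = 0.448, apoptotic_index = 1.877,
            ki67_pct = 9.0, cells_per_field = 838.7, necrosis_pct = 2.0,
            phospho_total_Rb_ratio = 0.67, cdc25A = 0.7)
  shift <- c(p21 = -0.15, cyclin_E = 0.15, E2F1 = 0.15, phospho_Rb = 0.4,
             cdc6 = 0.2, IP_E2F1_Rb = -0.1, XIAP = 0.5,
             cleaved_caspase3 = 0.25, cytochrome_c = 0.35, Apaf1 = -0.2,
             Bax = -0.15, mitotic_index = 0.123, apoptotic_index = 0.739,
             ki67_pct = 0.4, cells_per_field = 24.5,
             phospho_total_Rb_ratio = 0.25, cdc25A = 0.1)
  ds <- base
  ds[names(shift)] <- ds[names(shift)] + shift
  sds <- pmax(0.2 * base, 1e-3)
  sds[c("mitotic_index", "apoptotic_index")] <- c(0.25, 0.8)
  sds["ki67_pct"] <- 3.0
  sds["cells_per_field"] <- 80
  list(variables = vars,
       means = list(DR = base, DS = ds),
       sds = list(DR = sds, DS = sds))
}

# Deterministic child seed per pipeline stage, so each generator is
# reproducible in isolation. Kept below 2^31 - 1.
#' @keywords internal
child_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

# Truncated (>= 1) Poisson sampler with target mean m: solves
# lambda / (1 - exp(-lambda)) = m, then inverse-CDF samples.
#' @keywords internal
rtruncpois <- function(n, m) {
  stopifnot(m > 1)
  lam <- stats::uniroot(function(l) l / (1 - exp(-l)) - m,
                        interval = c(1e-8, 4 * m))$root
  u <- stats::runif(n, stats::ppois(0, lam), 1)
  stats::qpois(u, lam)
}

#' Generate a synthetic tumor cohort
#'
#' Simulates tumor-bearing rats and their carcinomas for each strain.
#' Tumor-bearing status is Bernoulli with the configured incidence;
#' multiplicity per bearing rat is truncated Poisson (at least one tumor);
#' detection week prior to study end is uniform over the detection window.
#' Necropsy mass is the detection threshold plus `slope * week` in
#' expectation: tumors detected before the final week add Gaussian growth
#' noise, and masses are bounded below by the detection threshold.
#'
#' @param config a [cohort_config()] object.
#' @return data.frame with columns `tumor_id`, `rat_id`, `strain`,
#'   `week_prior_to_end`, `necropsy_mass_g` (one row per carcinoma).
#' @export
#' @examples
#' tum <- generate_cohort(cohort_config(seed = 42))
#' head(tum)
generate_cohort <- function(config) {
  validate_config(config)
  set.seed(child_seed(config$seed, "cohort"))
  out <- list()
  for (s in names(config$n_rats_per_strain)) {
    n_rats <- config$n_rats_per_strain[[s]]
    bearing <- which(stats::runif(n_rats) < config$incidence[[s]])
    if (length(bearing) == 0L) next
    mult <- rtruncpois(length(bearing), config$multiplicity_mean[[s]])
    rat_id <- rep(sprintf("%s_rat%03d", s, bearing), mult)
    n_tum <- sum(mult)
    week <- sample(0:config$detection_window_weeks, n_tum, replace = TRUE)
    mu <- config$detection_threshold_g + config$slope_g_per_week[[s]] * week
    eps <- stats::rnorm(n_tum, 0, config$mass_noise_sd) * (week > 0)
    mass <- pmax(mu + eps, config$detection_threshold_g)
    out[[s]] <- data.frame(
      tumor_id = sprintf("%s_t%04d", s, seq_len(n_tum)),
      rat_id = rat_id,
      strain = s,
      week_prior_to_end = week,
      necropsy_mass_g = mass,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Generate per-field histology counts for a cohort
#'
#' For each tumor, draws `n_fields_per_tumor` high-power fields. The cell
#' census per field is rounded Gaussian clipped to \[500, 1500\]; mitotic
#' figures and apoptotic bodies are gamma-mixed Poisson (negative binomial)
#' draws with strain-specific means and shared dispersion k, so the
#' per-field variance is mean + mean^2/k. A leading block of fields is
#' flagged as Ki67 hotspots according to `hotspot_percent` (rounded up).
#'
#' @param tumors data.frame from [generate_cohort()].
#' @param config a [cohort_config()] object.
#' @return data.frame with columns `tumor_id`, `field_index`,
#'   `total_cells`, `mitotic_count`, `apoptotic_count`, `is_hotspot`.
#' @export
generate_field_counts <- function(tumors, config) {
  validate_config(config)
  if (config$n_fields_per_tumor < 1)
    config_error("n_fields_per_tumor", "must be >= 1")
  set.seed(child_seed(config$seed, "fields"))
  nf <- config$n_fields_per_tumor
  n_hot <- ceiling(nf * config$hotspot_percent / 100)
  n_tot <- nrow(tumors) * nf
  total <- round(stats::rnorm(n_tot, config$cells_per_field_mean,
                              config$cells_per_field_sd))
  total <- pmin(pmax(total, 500L), 1500L)
  strain <- rep(tumors$strain, each = nf)
  mit <- stats::rnbinom(n_tot, mu = config$mitotic_mean[strain],
                        size = config$nb_dispersion)
  apo <- stats::rnbinom(n_tot, mu = config$apoptotic_mean[strain],
                        size = config$nb_dispersion)
  data.frame(
    tumor_id = rep(tumors$tumor_id, each = nf),
    field_index = rep(seq_len(nf), times = nrow(tumors)),
    total_cells = as.integer(total),
    mitotic_count = pmin(mit, total),
    apoptotic_count = pmin(apo, total),
    is_hotspot = rep(seq_len(nf) <= n_hot, times = nrow(tumors)),
    stringsAsFactors = FALSE
  )
}

#' Generate per-tumor Ki67 immunoreactive fractions
#'
#' Draws one Ki67 nuclear-immunoreactivity percentage per tumor from a
#' strain-specific Gaussian, bounded to the open interval (0, 100).
#'
#' @param tumors data.frame from [generate_cohort()].
#' @param config a [cohort_config()] object.
#' @return data.frame with columns `tumor_id`, `strain`, `ki67_pct`.
#' @export
generate_ki67 <- function(tumors, config) {
  validate_config(config)
  set.seed(child_seed(config$seed, "ki67"))
  x <- stats::rnorm(nrow(tumors),
                    config$ki67_mean_pct[tumors$strain],
                    config$ki67_sd_pct[tumors$strain])
  x <- pmin(pmax(x, 1e-6), 100 - 1e-6)
  data.frame(tumor_id = tumors$tumor_id, strain = tumors$strain,
             ki67_pct = x, stringsAsFactors = FALSE)
}

#' Generate a 29-variable protein/count predictor panel
#'
#' Draws each panel variable independently per strain from the configured
#' per-strain means and standard deviations. Expression-type variables are
#' bounded below at zero (signals are non-negative).
#'
#' @param tumors data.frame from [generate_cohort()].
#' @param config a [cohort_config()] object.
#' @return data.frame in wide format: `tumor_id`, `strain`, then 29
#'   predictor columns.
#' @export
generate_protein_panel <- function(tumors, config) {
  validate_config(config)
  set.seed(child_seed(config$seed, "panel"))
  vars <- names(config$panel_means[[tumors$strain[1]]])
  n <- nrow(tumors)
  mat <- matrix(NA_real_, n, length(vars), dimnames = list(NULL, vars))
  for (j in seq_along(vars)) {
    mu <- vapply(tumors$strain,
                 function(s) config$panel_means[[s]][[j]], 0)
    sd <- vapply(tumors$strain,
                 function(s) config$panel_sds[[s]][[j]], 0)
    mat[, j] <- pmax(stats::rnorm(n, mu, sd), 0)
  }
  cbind(data.frame(tumor_id = tumors$tumor_id, strain = tumors$strain,
                   stringsAsFactors = FALSE),
        as.data.frame(mat))
}

#' Write a synthetic cohort to CSV files
#'
#' Generates all four tables (tumors, per-field counts, Ki67, protein
#' panel) and writes `tumors.csv`, `fields.csv`, `ki67.csv`, `panel.csv`
#' to `dir`.
#'
#' @param config a [cohort_config()] object.
#' @param dir output directory (created if needed).
#' @return invisibly, a named list of the four data.frames.
#' @export
write_cohort <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tumors <- generate_cohort(config)
  tabs <- list(
    tumors = tumors,
    fields = generate_field_counts(tumors, config),
    ki67 = generate_ki67(tumors, config),
    panel = generate_protein_panel(tumors, config)
  )
  for (nm in names(tabs))
    utils::write.csv(tabs[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  invisible(tabs)
}
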