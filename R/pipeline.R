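# End-to-end orchestration: simulate (or load) a cohort, then run growth
# regression, kinetic deconvolution, count models and the multivariate
# stage, writing CSV tables and a consolidated JSON report. One seed in
# the configuration fans out to deterministic per-stage child seeds, so
# any stage can be re-run in isolation and the whole run is reproducible.

#' @keywords internal
read_required_csv <- function(dir, name) {
  path <- file.path(dir, name)
  if (!file.exists(path))
    stop(sprintf("input file not found: %s", path), call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Run the full tumor-kinetics pipeline
#'
#' Executes simulate -> growth -> kinetics -> counts -> multivariate and
#' writes all tables plus `report.json` to `out_dir`. With `input_dir`
#' supplied, the four cohort tables (`tumors.csv`, `fields.csv`,
#' `ki67.csv`, `panel.csv`) are read from disk instead of simulated; a
#' missing file aborts with an error naming it.
#'
#' @param config a [cohort_config()]; also controls simulation when
#'   `input_dir` is NULL.
#' @param out_dir output directory (created if needed).
#' @param input_dir optional directory holding pre-existing cohort CSVs.
#' @param n_components components for the PCA stage (default 4).
#' @return invisibly, the report list with elements `growth`, `kinetics`,
#'   `counts`, `multivariate`, `manifest`.
#' @export
#' @examples
#' \donttest{
#' rpt <- run_pipeline(cohort_config(seed = 7), tempfile("run"))
#' names(rpt)
#' }
run_pipeline <- function(config, out_dir, input_dir = NULL,
                         n_components = 4L) {
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(input_dir)) {
    tabs <- write_cohort(config, out_dir)
  } else {
    tabs <- list(tumors = read_required_csv(input_dir, "tumors.csv"),
                 fields = read_required_csv(input_dir, "fields.csv"),
                 ki67 = read_required_csv(input_dir, "ki67.csv"),
                 panel = read_required_csv(input_dir, "panel.csv"))
  }
  tumors <- tabs$tumors
  strains <- sort(unique(tumors$strain))

  # growth: per-strain OLS plus pooled-interaction comparison
  fits <- lapply(strains, function(s)
    fit_mass_on_week(tumors[tumors$strain == s, ]))
  names(fits) <- strains
  growth <- list(fits = lapply(fits, function(f)
    f[c("slope", "slope_se", "intercept", "n", "r_squared")]))
  if (length(strains) == 2L) {
    cmpr <- compare_slopes(tumors[tumors$strain == strains[1], ],
                           tumors[tumors$strain == strains[2], ])
    growth$comparison <- unclass(cmpr)
  }

  # kinetics: per-tumor estimates and group summaries
  slopes <- vapply(fits, function(f) f$slope, 0)
  est <- estimate_kinetics(tumors, tabs$fields, tabs$ki67, slopes)
  utils::write.csv(est, file.path(out_dir, "kinetics.csv"),
                   row.names = FALSE)
  ksum <- summarize_kinetics(est)
  kinetics <- list(summary = ksum$summary,
                   percent_difference = as.list(ksum$percent_difference))

  # counts: index summaries, NB fits, overdispersion, group comparison
  grp <- stats::setNames(tumors$strain, tumors$tumor_id)
  counts <- list()
  strain_of_field <- grp[tabs$fields$tumor_id]
  for (ev in c("mitotic", "apoptotic")) {
    col <- paste0(ev, "_count")
    idx <- compute_indices(tabs$fields, ev, groups = grp)
    per_strain <- lapply(strains, function(s) {
      x <- tabs$fields[[col]][strain_of_field == s]
      nb <- fit_negbin(x)
      od <- overdispersion_test(x)
      list(nb_mean = nb$mean, nb_dispersion = nb$dispersion,
           nb_aic = nb$aic, poisson_aic = fit_poisson(x)$aic,
           overdispersion_p = od$p_value)
    })
    names(per_strain) <- strains
    ev_out <- list(group_summary = idx$group_summary,
                   models = per_strain)
    if (length(strains) == 2L) {
      a <- strain_of_field == strains[1]
      b <- strain_of_field == strains[2]
      cg <- compare_groups_nb(tabs$fields[[col]][a],
                              tabs$fields[[col]][b],
                              cells_a = tabs$fields$total_cells[a],
                              cells_b = tabs$fields$total_cells[b])
      ev_out$group_test <- cg
    }
    counts[[ev]] <- ev_out
  }

  # multivariate: PCA/Q2/Hotelling on the panel, PLS1 against tumor mass
  panel <- tabs$panel
  xcols <- setdiff(names(panel), c("tumor_id", "strain"))
  X <- as.matrix(panel[, xcols])
  nc <- min(n_components, nrow(X) - 1L, ncol(X))
  pca <- pca_fit(X, nc)
  q2 <- q2_crossval(X, nc)
  mv <- list(n_components = nc, r2x = pca$r2x,
             r2x_cumulative = pca$r2x_cumulative,
             q2 = q2$q2, q2_cumulative = q2$q2_cumulative)
  if (length(strains) == 2L) {
    ht <- hotelling_two_group(pca$scores[, 1:min(2L, nc), drop = FALSE],
                              panel$strain)
    mv$hotelling <- ht[c("t2", "f_statistic", "df1", "df2", "p_value")]
  }
  y <- tumors$necropsy_mass_g[match(panel$tumor_id, tumors$tumor_id)]
  pls <- pls1_fit(X, y)
  mv$pls1 <- list(coefficients = as.list(pls$coefficients),
                  r2y = pls$r2y, top_positive = pls$top_positive,
                  top_negative = pls$top_negative)
  utils::write.csv(data.frame(tumor_id = panel$tumor_id, pca$scores),
                   file.path(out_dir, "scores.csv"), row.names = FALSE)
  utils::write.csv(data.frame(variable = rownames(pca$loadings),
                              pca$loadings),
                   file.path(out_dir, "loadings.csv"), row.names = FALSE)

  manifest <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("tumorkinetics")),
    config = config[setdiff(names(config), c("panel_means", "panel_sds"))],
    input_digests = as.list(tools::md5sum(
      file.path(if (is.null(input_dir)) out_dir else input_dir,
                c("tumors.csv", "fields.csv", "ki67.csv", "panel.csv")))),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  names(manifest$input_digests) <-
    basename(names(manifest$input_digests))

  report <- list(growth = growth, kinetics = kinetics, counts = counts,
                 multivariate = mv, manifest = manifest)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", force = TRUE)
  invisible(report)
}

#' Read a pipeline configuration from a YAML file
#'
#' Any field accepted by [cohort_config()] may appear in the file; named
#' per-strain entries are given as mappings. Omitted fields take the
#' package defaults.
#'
#' @param path YAML file path.
#' @param seed optional seed overriding the file's value.
#' @return a validated [cohort_config()].
#' @export
read_config <- function(path, seed = NULL) {
  if (!file.exists(path))
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  raw <- yaml::read_yaml(path)
  for (nm in c("n_rats_per_strain", "incidence", "multiplicity_mean",
               "slope_g_per_week", "mitotic_mean", "apoptotic_mean",
               "ki67_mean_pct", "ki67_sd_pct"))
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  if (!is.null(seed)) raw$seed <- seed
  do.call(cohort_config, raw)
}
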