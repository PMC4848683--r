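# Kinetic deconvolution of tumor growth. The mass-balance view models
# tissue-size change as dS = n (kP - kD): in homeostasis proliferation
# balances death and dS = 0; every tumor has dS > 0. The per-cell rates
# split into pool sizes and process durations: kP = Pn / Pd (proliferative
# fraction over cell-cycle duration), kD = Dn / Dd (apoptotic index over
# apoptotic duration). With Pn, Pd, Dn, dS and the growth rate n measured,
# apoptotic duration is recovered as
#   Dd = Dn / ((Pn / Pd) - (dS / n)).

#' Kinetic constants
#'
#' Mass of a single tumor cell (grams) and hours per week, used by the
#' unit conversions.
#' @export
kinetic_constants <- list(cell_mass_g = 1e-9, hours_per_week = 168)

#' Cell-cycle duration from proliferative fraction and mitotic index
#'
#' Estimates cell-cycle duration (hours) as the Ki67 proliferative
#' fraction divided by the mitotic index. Two unit modes are supported.
#' `"as-published"` divides Ki67 percent by mitotic figures per field;
#' with group means near 9% Ki67 and 0.45-0.6 figures per field this
#' yields durations of 16-21 h, in line with the ~24 h textbook cell
#' cycle. `"per-cell"` divides Ki67 percent by the per-cell mitotic
#' percentage, 100 * figures / total cells, which is the dimensionally
#' homogeneous form but yields durations near 170 h on the same data; the
#' discrepancy between the modes is a factor of `cells_per_field / 100`.
#' See the package vignette for discussion.
#'
#' @param pn Ki67 proliferative fraction, percent in (0, 100].
#' @param mitotic_index mitotic figures per field (`"as-published"`) or
#'   the same raw figures with `cells_per_field` supplied (`"per-cell"`).
#' @param mode `"as-published"` (default) or `"per-cell"`.
#' @param cells_per_field cell census per field, required for
#'   `"per-cell"`.
#' @return cell-cycle duration in hours (vectorized).
#' @export
#' @examples
#' cell_cycle_duration(9.0, 0.448)   # ~20.1 h
#' cell_cycle_duration(9.4, 0.571)   # ~16.5 h
cell_cycle_duration <- function(pn, mitotic_index,
                                mode = c("as-published", "per-cell"),
                                cells_per_field = NULL) {
  mode <- match.arg(mode)
  if (any(pn <= 0 | pn > 100))
    stop("proliferative fraction must lie in (0, 100]", call. = FALSE)
  if (any(mitotic_index <= 0))
    stop("undefined duration: mitotic index must be > 0", call. = FALSE)
  if (mode == "per-cell") {
    if (is.null(cells_per_field))
      stop("per-cell mode needs cells_per_field", call. = FALSE)
    mitotic_index <- 100 * mitotic_index / cells_per_field
  }
  pn / mitotic_index
}

#' Convert a growth rate from g/week to cells gained per hour
#'
#' Divides by hours per week and by the mass of a single cell
#' (1e-9 g by default).
#'
#' @param rate_g_per_week growth rate, g/week, >= 0.
#' @param cell_mass_g mass of one cell in grams.
#' @return cells gained per hour.
#' @export
#' @examples
#' grams_per_week_to_cells_per_hour(0.533)  # ~3.17e6 cells/h
grams_per_week_to_cells_per_hour <- function(rate_g_per_week,
                                             cell_mass_g = kinetic_constants$cell_mass_g) {
  if (any(rate_g_per_week < 0))
    stop("growth rate must be >= 0", call. = FALSE)
  rate_g_per_week / (kinetic_constants$hours_per_week * cell_mass_g)
}

#' Inverse of [grams_per_week_to_cells_per_hour()]
#' @param rate_cells_per_hour cells gained per hour, >= 0.
#' @param cell_mass_g mass of one cell in grams.
#' @return growth rate in g/week.
#' @export
cells_per_hour_to_grams_per_week <- function(rate_cells_per_hour,
                                             cell_mass_g = kinetic_constants$cell_mass_g) {
  if (any(rate_cells_per_hour < 0))
    stop("growth rate must be >= 0", call. = FALSE)
  rate_cells_per_hour * kinetic_constants$hours_per_week * cell_mass_g
}

#' Per-tumor tissue-size change rate (cells per hour)
#'
#' Final tumor mass converted to cell number (dividing by the single-cell
#' mass) over the hours elapsed between first palpation and study
#' termination.
#'
#' @param necropsy_mass_g tumor mass at necropsy, grams, >= 0.
#' @param elapsed_hours hours between palpation and termination, > 0.
#' @param cell_mass_g mass of one cell in grams.
#' @return cells per hour (vectorized).
#' @export
#' @examples
#' delta_s_rate(1, 672)  # ~1.49e6 cells/h
delta_s_rate <- function(necropsy_mass_g, elapsed_hours,
                         cell_mass_g = kinetic_constants$cell_mass_g) {
  if (any(necropsy_mass_g < 0))
    stop("mass must be >= 0", call. = FALSE)
  if (any(elapsed_hours <= 0))
    stop("elapsed hours must be > 0", call. = FALSE)
  (necropsy_mass_g / cell_mass_g) / elapsed_hours
}

#' Apoptotic duration from the kinetic balance
#'
#' Solves the balance `Dd = Dn / ((Pn / Pd) - (dS / n))` for the duration
#' of the apoptotic process. When the denominator is not positive the
#' observed growth meets or exceeds the proliferative supply under the
#' model and the duration is undefined: the result is `NA` (never a
#' negative duration), and the count of undefined entries is attached as
#' attribute `"n_undefined"`.
#'
#' @param dn apoptotic index (bodies per field, same unit family as the
#'   mitotic index used for `pd`).
#' @param pn Ki67 proliferative fraction, percent.
#' @param pd cell-cycle duration, hours, > 0.
#' @param delta_s tissue-size change rate, cells/hour (per tumor).
#' @param n_rate growth rate, cells gained/hour (strain-level slope
#'   converted with [grams_per_week_to_cells_per_hour()]), > 0.
#' @return apoptotic duration in hours, `NA` where undefined; attribute
#'   `"n_undefined"` holds the number of undefined entries.
#' @export
#' @examples
#' apoptotic_duration(dn = 2, pn = 10, pd = 20, delta_s = 0.25, n_rate = 1)
apoptotic_duration <- function(dn, pn, pd, delta_s, n_rate) {
  if (any(pd <= 0)) stop("cell-cycle duration must be > 0", call. = FALSE)
  if (any(n_rate <= 0)) stop("growth rate n must be > 0", call. = FALSE)
  denom <- pn / pd - delta_s / n_rate
  dd <- ifelse(denom > 0, dn / denom, NA_real_)
  bad <- sum(denom <= 0, na.rm = TRUE) + sum(is.na(denom))
  attr(dd, "n_undefined") <- bad
  dd
}

#' Signed percent difference relative to a reference
#'
#' `100 * (other - reference) / reference`; negative means `other` is
#' smaller (e.g. a shorter cell cycle), positive means larger.
#'
#' @param reference reference value, nonzero.
#' @param other comparison value.
#' @return percent difference (vectorized).
#' @export
#' @examples
#' percent_difference(21.2, 17.7)  # -16.5: DS cell cycle shorter
#' percent_difference(4.7, 5.9)    # +25.5: DS apoptosis longer
percent_difference <- function(reference, other) {
  if (any(reference == 0))
    stop("reference must be nonzero", call. = FALSE)
  100 * (other - reference) / reference
}

#' Per-tumor kinetic estimates for a cohort
#'
#' Joins tumors, per-field counts, Ki67 fractions and strain-level growth
#' slopes into one kinetic estimate per tumor: proliferative fraction Pn,
#' mitotic and apoptotic indices (per-field means), cell-cycle duration Pd
#' (default `"as-published"` unit mode), the per-tumor tissue-change rate
#' dS, the strain growth rate n in cells/hour, and apoptotic duration Dd.
#' Tumors detected at termination (week 0) have no elapsed growth window,
#' so their dS and Dd are undefined (`NA`).
#'
#' @param tumors data.frame from [generate_cohort()] or equivalent.
#' @param fields data.frame of per-field counts.
#' @param ki67 data.frame with `tumor_id`, `ki67_pct`.
#' @param strain_slopes named numeric, fitted growth slope (g/week) per
#'   strain.
#' @param mode unit mode passed to [cell_cycle_duration()].
#' @return data.frame, one row per tumor: `tumor_id`, `strain`, `Pn`,
#'   `mitotic_index`, `Dn`, `Pd`, `delta_s_rate`, `n_rate`, `Dd`.
#' @export
estimate_kinetics <- function(tumors, fields, ki67, strain_slopes,
                              mode = c("as-published", "per-cell")) {
  mode <- match.arg(mode)
  mit <- tapply(fields$mitotic_count, fields$tumor_id, mean)
  apo <- tapply(fields$apoptotic_count, fields$tumor_id, mean)
  cells <- tapply(fields$total_cells, fields$tumor_id, mean)
  id <- tumors$tumor_id
  pn <- ki67$ki67_pct[match(id, ki67$tumor_id)]
  mi <- as.numeric(mit[id]); dn <- as.numeric(apo[id])
  cf <- as.numeric(cells[id])
  pd <- ifelse(mi > 0 & pn > 0,
               suppressWarnings(pn / (if (mode == "per-cell")
                 100 * mi / cf else mi)),
               NA_real_)
  elapsed_h <- tumors$week_prior_to_end * kinetic_constants$hours_per_week
  ds <- ifelse(elapsed_h > 0,
               (tumors$necropsy_mass_g / kinetic_constants$cell_mass_g) /
                 elapsed_h, NA_real_)
  nr <- grams_per_week_to_cells_per_hour(strain_slopes[tumors$strain])
  ok <- !is.na(pd) & !is.na(ds)
  dd <- rep(NA_real_, length(id))
  if (any(ok))
    dd[ok] <- as.numeric(apoptotic_duration(dn[ok], pn[ok], pd[ok],
                                            ds[ok], nr[ok]))
  data.frame(tumor_id = id, strain = tumors$strain, Pn = pn,
             mitotic_index = mi, Dn = dn, Pd = pd,
             delta_s_rate = ds, n_rate = as.numeric(nr), Dd = dd,
             stringsAsFactors = FALSE)
}

#' Group summaries of per-tumor kinetic estimates
#'
#' Per-group mean and SEM (sd / sqrt(n)) of each kinetic quantity,
#' computed over tumors with defined values, plus the signed percent
#' difference of the comparison group relative to the reference on the
#' group means. Undefined (NA) durations are excluded and counted.
#'
#' @param estimates data.frame from [estimate_kinetics()].
#' @param group name of the grouping column (default `"strain"`).
#' @param reference reference group for percent differences (default the
#'   first group in sort order).
#' @return list with `summary` (long data.frame: group, variable, n,
#'   mean, sem, n_undefined) and `percent_difference` (named vector, one
#'   entry per variable, comparison vs reference).
#' @export
summarize_kinetics <- function(estimates, group = "strain",
                               reference = NULL) {
  g <- estimates[[group]]
  groups <- sort(unique(g))
  if (is.null(reference)) reference <- groups[1]
  vars <- c("Pn", "mitotic_index", "Dn", "Pd", "Dd")
  rows <- list()
  for (gr in groups) for (v in vars) {
    x <- estimates[g == gr, v]
    xs <- x[!is.na(x)]
    if (length(xs) < 2L)
      stop(sprintf("group '%s' has fewer than 2 tumors with defined %s",
                   gr, v), call. = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      group = gr, variable = v, n = length(xs), mean = mean(xs),
      sem = stats::sd(xs) / sqrt(length(xs)),
      n_undefined = sum(is.na(x)), stringsAsFactors = FALSE)
  }
  sm <- do.call(rbind, rows)
  others <- setdiff(groups, reference)
  pct <- c()
  for (v in vars) {
    ref_m <- sm$mean[sm$group == reference & sm$variable == v]
    for (o in others) {
      oth_m <- sm$mean[sm$group == o & sm$variable == v]
      pct[paste0(v, ":", o, "_vs_", reference)] <-
        percent_difference(ref_m, oth_m)
    }
  }
  list(summary = sm, percent_difference = pct)
}
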