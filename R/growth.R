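# Tumor growth-rate estimation: ordinary least squares of necropsy mass on
# detection week, and a between-strain slope comparison. The x axis is
# "weeks prior to end of study": a tumor at week 4 was detected four weeks
# before termination and had the longest growth window, week 0 means
# detected at termination. Do not invert the sign.

#' Regress necropsy mass on detection week for one strain
#'
#' Ordinary least squares of `necropsy_mass_g` on `week_prior_to_end`,
#' treating tumors as independent observations. The fitted slope is the
#' strain's mass-accumulation rate in g/week; a positive slope means tumors
#' with a longer growth window were heavier at necropsy, i.e. tissue size
#' homeostasis has failed in favor of net cell gain.
#'
#' @param tumors data.frame with columns `week_prior_to_end` and
#'   `necropsy_mass_g` (rows for a single strain).
#' @return object of class `"growth_fit"`: list with `slope`, `slope_se`
#'   (g/week), `intercept` (g), `n`, `r_squared`, and the underlying `lm`
#'   fit in `$model`.
#' @export
#' @examples
#' d <- data.frame(week_prior_to_end = 0:3,
#'                 necropsy_mass_g = c(0.1, 0.6, 1.1, 1.6))
#' fit_mass_on_week(d)
fit_mass_on_week <- function(tumors) {
  stopifnot(is.data.frame(tumors),
            all(c("week_prior_to_end", "necropsy_mass_g") %in%
                  names(tumors)))
  if (nrow(tumors) < 3L)
    stop("need at least 3 tumors to fit a growth regression", call. = FALSE)
  if (length(unique(tumors$week_prior_to_end)) < 2L)
    stop("singular design: all tumors detected in the same week",
         call. = FALSE)
  fit <- stats::lm(necropsy_mass_g ~ week_prior_to_end, data = tumors)
  sm <- summary(fit)
  out <- list(slope = unname(stats::coef(fit)[2]),
              slope_se = unname(sm$coefficients[2, 2]),
              intercept = unname(stats::coef(fit)[1]),
              n = nrow(tumors),
              r_squared = sm$r.squared,
              model = fit)
  class(out) <- "growth_fit"
  out
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf(
    "Growth fit: slope %.3f +/- %.3f g/week, intercept %.3f g, n = %d, r^2 = %.3f\n",
    x$slope, x$slope_se, x$intercept, x$n, x$r_squared))
  invisible(x)
}

#' Compare tumor growth slopes between two strains
#'
#' With raw data for both strains, fits a pooled linear model with a
#' strain-by-week interaction and reports the t-test on the interaction
#' coefficient (the primary method). With two fitted [fit_mass_on_week()]
#' summaries and no raw data, falls back to a Welch-style z test on the
#' slope difference using the fitted standard errors.
#'
#' @param reference tumors data.frame or `"growth_fit"` for the reference
#'   strain (the denominator of the fold change, e.g. DR).
#' @param comparison tumors data.frame or `"growth_fit"` for the other
#'   strain (e.g. DS).
#' @return list of class `"slope_comparison"`: `ratio`
#'   (comparison slope / reference slope), `difference`, `difference_se`
#'   (g/week), `p_value`, `method`.
#' @export
#' @examples
#' a <- data.frame(week_prior_to_end = rep(0:4, 10),
#'                 necropsy_mass_g = 0.1 + 0.5 * rep(0:4, 10) + rnorm(50, 0, .2))
#' b <- data.frame(week_prior_to_end = rep(0:4, 10),
#'                 necropsy_mass_g = 0.1 + 1.0 * rep(0:4, 10) + rnorm(50, 0, .2))
#' compare_slopes(a, b)
compare_slopes <- function(reference, comparison) {
  if (inherits(reference, "growth_fit") &&
      inherits(comparison, "growth_fit")) {
    s1 <- reference$slope; s2 <- comparison$slope
    se <- sqrt(reference$slope_se^2 + comparison$slope_se^2)
    diff <- s2 - s1
    z <- if (se > 0) diff / se else 0
    p <- 2 * stats::pnorm(-abs(z))
    method <- "summary z test on slope difference"
  } else if (is.data.frame(reference) && is.data.frame(comparison)) {
    ref <- fit_mass_on_week(reference)  # validates designs
    cmp <- fit_mass_on_week(comparison)
    pooled <- rbind(
      data.frame(week = reference$week_prior_to_end,
                 mass = reference$necropsy_mass_g, grp = 0),
      data.frame(week = comparison$week_prior_to_end,
                 mass = comparison$necropsy_mass_g, grp = 1))
    fit <- stats::lm(mass ~ week * grp, data = pooled)
    co <- summary(fit)$coefficients
    s1 <- ref$slope; s2 <- cmp$slope
    diff <- unname(co["week:grp", 1])
    se <- unname(co["week:grp", 2])
    p <- unname(co["week:grp", 4])
    method <- "pooled-model interaction t test"
  } else {
    stop("supply two data.frames or two growth_fit objects", call. = FALSE)
  }
  if (s1 == 0)
    stop("reference slope is zero: fold change undefined", call. = FALSE)
  out <- list(ratio = s2 / s1, difference = diff, difference_se = se,
              p_value = min(p, 1), method = method)
  class(out) <- "slope_comparison"
  out
}

#' @export
print.slope_comparison <- function(x, ...) {
  cat(sprintf(
    "Slope comparison: %.2f-fold, difference %.3f +/- %.3f g/week, p = %.3g (%s)\n",
    x$ratio, x$difference, x$difference_se, x$p_value, x$method))
  invisible(x)
}
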