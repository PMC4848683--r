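# Per-field mitotic/apoptotic count analysis. Counts from H&E fields are
# typically overdispersed relative to Poisson (positive correlation among
# cells within a field is one mechanism), so the working model is the
# gamma-mixed Poisson, i.e. negative binomial with variance
# mean + mean^2 / k for gamma shape k.

#' Mitotic or apoptotic index summaries from per-field counts
#'
#' Computes, per tumor, the mean events per field and the mean per-cell
#' fraction (events / total cells), then summarizes per-tumor means within
#' groups as mean +/- SEM. "Probability of a given cell undergoing" the
#' event is operationalized on the per-cell scale; the per-field-count
#' scale matches how indices are usually reported.
#'
#' @param fields data.frame with `tumor_id`, `total_cells` and the event
#'   count column (`mitotic_count` or `apoptotic_count`).
#' @param event `"mitotic"` or `"apoptotic"`.
#' @param groups optional data.frame (`tumor_id`, `group`) or named
#'   vector mapping tumor_id to group; when supplied, group summaries are
#'   returned.
#' @return list with `per_tumor` (tumor_id, n_fields, mean_per_field,
#'   mean_fraction) and, when groups are given, `group_summary` (group,
#'   n_tumors, mean/sem on both scales).
#' @export
#' @examples
#' f <- data.frame(tumor_id = "t1", total_cells = rep(5, 5),
#'                 mitotic_count = c(0, 1, 1, 2, 1),
#'                 apoptotic_count = 0)
#' compute_indices(f, "mitotic")$per_tumor
compute_indices <- function(fields, event = c("mitotic", "apoptotic"),
                            groups = NULL) {
  event <- match.arg(event)
  col <- paste0(event, "_count")
  stopifnot(is.data.frame(fields),
            all(c("tumor_id", "total_cells", col) %in% names(fields)))
  if (nrow(fields) == 0L)
    stop("insufficient data: no fields supplied", call. = FALSE)
  if (any(fields$total_cells <= 0))
    stop("total_cells must be > 0", call. = FALSE)
  if (any(fields[[col]] < 0))
    stop("counts must be >= 0", call. = FALSE)
  per_field <- tapply(fields[[col]], fields$tumor_id, mean)
  frac <- tapply(fields[[col]] / fields$total_cells, fields$tumor_id, mean)
  nf <- tapply(fields[[col]], fields$tumor_id, length)
  per_tumor <- data.frame(tumor_id = names(per_field),
                          n_fields = as.integer(nf),
                          mean_per_field = as.numeric(per_field),
                          mean_fraction = as.numeric(frac),
                          stringsAsFactors = FALSE)
  rownames(per_tumor) <- NULL
  out <- list(event = event, per_tumor = per_tumor)
  if (!is.null(groups)) {
    if (is.data.frame(groups))
      groups <- stats::setNames(groups[[2]], groups[[1]])
    gr <- groups[per_tumor$tumor_id]
    if (anyNA(gr))
      stop("insufficient data: some tumors have no group label",
           call. = FALSE)
    sem <- function(x) stats::sd(x) / sqrt(length(x))
    gs <- do.call(rbind, lapply(split(per_tumor, gr), function(d) {
      data.frame(n_tumors = nrow(d),
                 mean_per_field = mean(d$mean_per_field),
                 sem_per_field = sem(d$mean_per_field),
                 mean_fraction = mean(d$mean_fraction),
                 sem_fraction = sem(d$mean_fraction))
    }))
    gs <- cbind(group = rownames(gs), gs)
    rownames(gs) <- NULL
    out$group_summary <- gs
  }
  out
}

#' @keywords internal
check_counts <- function(counts, min_n) {
  if (length(counts) == 0L) stop("empty input", call. = FALSE)
  if (any(is.na(counts)) || any(counts < 0) ||
      any(counts != floor(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (length(counts) < min_n)
    stop(sprintf("need at least %d counts", min_n), call. = FALSE)
  invisible(counts)
}

#' Maximum-likelihood Poisson fit to event counts
#'
#' The ML mean is the sample mean; log-likelihood and AIC are reported so
#' the fit is comparable with [fit_negbin()].
#'
#' @param counts non-negative integer vector, non-empty (an
#'   underdispersed sample, even a constant one, is still a valid fit).
#' @return list of class `"count_model_fit"`: `family`, `mean`,
#'   `log_likelihood`, `aic`, `variance_mean_ratio`.
#' @export
fit_poisson <- function(counts) {
  check_counts(counts, 1L)
  m <- mean(counts)
  ll <- sum(stats::dpois(counts, m, log = TRUE))
  out <- list(family = "poisson", mean = m, dispersion = Inf,
              log_likelihood = ll, aic = -2 * ll + 2,
              variance_mean_ratio = if (m > 0)
                stats::var(counts) / m else 0)
  class(out) <- "count_model_fit"
  out
}

#' Maximum-likelihood negative-binomial fit to event counts
#'
#' Gamma-mixed Poisson with variance = mean + mean^2/k. The ML mean is
#' the sample mean; the gamma shape k is estimated by profile likelihood
#' (one-dimensional optimization over log k). When the sample variance
#' does not exceed the mean the dispersion estimate diverges; the fit is
#' then returned at the Poisson limit (`poisson_limit = TRUE`,
#' `dispersion = Inf`) with an AIC penalized for the extra parameter
#' rather than failing.
#'
#' @param counts non-negative integer vector, length >= 5, not all equal.
#' @return list of class `"count_model_fit"`: `family`, `mean`,
#'   `dispersion` (k), `log_likelihood`, `aic`, `poisson_limit`.
#' @export
#' @examples
#' set.seed(1)
#' fit_negbin(rnbinom(1000, mu = 2.6, size = 1.5))
fit_negbin <- function(counts) {
  check_counts(counts, 5L)
  if (stats::var(counts) == 0)
    stop("degenerate data: counts are constant", call. = FALSE)
  m <- mean(counts)
  if (stats::var(counts) <= m) {
    po <- fit_poisson(counts)
    out <- list(family = "negative_binomial", mean = m, dispersion = Inf,
                log_likelihood = po$log_likelihood,
                aic = -2 * po$log_likelihood + 4, poisson_limit = TRUE,
                variance_mean_ratio = po$variance_mean_ratio)
    class(out) <- "count_model_fit"
    return(out)
  }
  prof <- function(logk)
    sum(stats::dnbinom(counts, mu = m, size = exp(logk), log = TRUE))
  op <- stats::optimize(prof, interval = c(-12, 15), maximum = TRUE,
                        tol = 1e-8)
  k <- exp(op$maximum)
  ll <- op$objective
  out <- list(family = "negative_binomial", mean = m, dispersion = k,
              log_likelihood = ll, aic = -2 * ll + 4,
              poisson_limit = FALSE,
              variance_mean_ratio = stats::var(counts) / m)
  class(out) <- "count_model_fit"
  out
}

#' @export
print.count_model_fit <- function(x, ...) {
  cat(sprintf("%s fit: mean %.3f%s, logLik %.2f, AIC %.2f\n", x$family,
              x$mean,
              if (is.finite(x$dispersion))
                sprintf(", dispersion k = %.3f", x$dispersion) else "",
              x$log_likelihood, x$aic))
  invisible(x)
}

#' Score test for overdispersion relative to Poisson
#'
#' Fisher's dispersion-index test: under a Poisson model the statistic
#' sum((x - xbar)^2) / xbar is approximately chi-squared with n - 1
#' degrees of freedom. The reported p-value is one-sided for variance
#' exceeding the mean.
#'
#' @param counts non-negative integer vector, length >= 10, not constant.
#' @return list: `statistic`, `df`, `p_value`, `variance_mean_ratio`.
#' @export
overdispersion_test <- function(counts) {
  check_counts(counts, 10L)
  if (stats::var(counts) == 0)
    stop("degenerate data: counts are constant", call. = FALSE)
  m <- mean(counts)
  n <- length(counts)
  stat <- sum((counts - m)^2) / m
  list(statistic = stat, df = n - 1L,
       p_value = stats::pchisq(stat, n - 1L, lower.tail = FALSE),
       variance_mean_ratio = stats::var(counts) / m)
}

#' Negative-binomial comparison of event counts between two groups
#'
#' Fits a negative-binomial regression (log link) with a group indicator
#' and tests the group coefficient. The default is the Wald test; a
#' likelihood-ratio variant against the intercept-only model is also
#' available. When per-field cell censuses are supplied, the per-cell
#' event probability (mean events per field / mean cells per field) is
#' reported for each group.
#'
#' @param counts_a,counts_b non-negative integer vectors (>= 5 each).
#' @param cells_a,cells_b optional per-field total-cell counts matching
#'   each group.
#' @param test `"wald"` (default) or `"lrt"`.
#' @return list: `p_value`, `mean_a`, `mean_b`, `ratio` (b/a),
#'   `dispersion`, `prob_a`, `prob_b` (NA without censuses), `test`.
#' @export
compare_groups_nb <- function(counts_a, counts_b,
                              cells_a = NULL, cells_b = NULL,
                              test = c("wald", "lrt")) {
  test <- match.arg(test)
  check_counts(counts_a, 5L)
  check_counts(counts_b, 5L)
  if (stats::var(c(counts_a, counts_b)) == 0)
    stop("degenerate data: all counts identical", call. = FALSE)
  d <- data.frame(y = c(counts_a, counts_b),
                  grp = factor(rep(c("a", "b"),
                                   c(length(counts_a), length(counts_b)))))
  fit <- tryCatch(
    suppressWarnings(MASS::glm.nb(y ~ grp, data = d)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # equidispersed or sparse data: dispersion diverges, use Poisson GLM
    fit <- stats::glm(y ~ grp, family = stats::poisson(), data = d)
    theta <- Inf
  } else theta <- fit$theta
  if (test == "wald") {
    co <- summary(fit)$coefficients
    p <- unname(co["grpb", 4])
  } else {
    fit0 <- if (is.finite(theta))
      suppressWarnings(MASS::glm.nb(y ~ 1, data = d))
    else stats::glm(y ~ 1, family = stats::poisson(), data = d)
    lr <- 2 * (as.numeric(stats::logLik(fit)) -
                 as.numeric(stats::logLik(fit0)))
    p <- stats::pchisq(max(lr, 0), df = 1, lower.tail = FALSE)
  }
  ma <- mean(counts_a); mb <- mean(counts_b)
  list(p_value = p, mean_a = ma, mean_b = mb,
       ratio = if (ma > 0) mb / ma else NA_real_,
       dispersion = theta,
       prob_a = if (!is.null(cells_a)) ma / mean(cells_a) else NA_real_,
       prob_b = if (!is.null(cells_b)) mb / mean(cells_b) else NA_real_,
       test = test)
}
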