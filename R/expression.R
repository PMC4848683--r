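# Protein-expression normalization. Blot/capillary signals arrive as
# extracted densities or peak areas (arbitrary units); everything here is
# downstream of image analysis. Signals are expressed relative to the
# GAPDH loading control, so common gain cancels.

#' Normalize a signal to the GAPDH loading control
#'
#' @param raw_signal band density or peak area, arbitrary units, >= 0.
#' @param gapdh_signal loading-control signal in the same units, > 0.
#' @return normalized expression (AUOD), vectorized.
#' @export
#' @examples
#' normalize_to_loading_control(10, 2)  # 5
normalize_to_loading_control <- function(raw_signal, gapdh_signal) {
  if (any(raw_signal < 0))
    stop("raw signal must be >= 0", call. = FALSE)
  if (any(gapdh_signal <= 0))
    stop("loading-control signal must be > 0", call. = FALSE)
  raw_signal / gapdh_signal
}

#' Phosphorylated-to-total protein ratio
#'
#' Ratio of normalized phospho-protein signal to normalized total-protein
#' signal (e.g. phospho-Rb over total Rb, an index of G1/S checkpoint
#' inactivation).
#'
#' @param phospho_norm normalized phospho signal, >= 0.
#' @param total_norm normalized total signal, > 0.
#' @return ratio, vectorized.
#' @export
phospho_total_ratio <- function(phospho_norm, total_norm) {
  if (any(phospho_norm < 0))
    stop("phospho signal must be >= 0", call. = FALSE)
  if (any(total_norm <= 0))
    stop("total signal must be > 0", call. = FALSE)
  phospho_norm / total_norm
}

#' Fold-changes and percent differences for an adiposity table
#'
#' Given per-depot group means for a reference and a comparison group
#' (e.g. fat-pad mass per tibia length, or adipocyte area per field),
#' reports the comparison/reference fold change and the signed percent
#' difference per depot.
#'
#' @param depots data.frame with columns `depot`, `reference_mean`,
#'   `comparison_mean`.
#' @return data.frame: `depot`, `reference_mean`, `comparison_mean`,
#'   `fold`, `percent_difference`.
#' @export
#' @examples
#' table1_ratio_report(data.frame(depot = "mammary_adipocytes",
#'                                reference_mean = 1128,
#'                                comparison_mean = 1561))
table1_ratio_report <- function(depots) {
  stopifnot(is.data.frame(depots),
            all(c("depot", "reference_mean", "comparison_mean") %in%
                  names(depots)))
  if (nrow(depots) == 0L)
    stop("missing group data", call. = FALSE)
  if (any(is.na(depots$reference_mean)) ||
      any(is.na(depots$comparison_mean)))
    stop("missing group mean", call. = FALSE)
  if (any(depots$reference_mean == 0))
    stop("reference mean of zero: fold undefined", call. = FALSE)
  data.frame(depot = depots$depot,
             reference_mean = depots$reference_mean,
             comparison_mean = depots$comparison_mean,
             fold = depots$comparison_mean / depots$reference_mean,
             percent_difference = percent_difference(
               depots$reference_mean, depots$comparison_mean),
             stringsAsFactors = FALSE)
}

#' Long-to-wide reshape of a normalized panel table
#'
#' Converts a long panel table (`tumor_id`, `analyte`, `raw_signal`,
#' `gapdh_signal`) into the wide matrix the multivariate stage consumes,
#' normalizing each signal to its loading control.
#'
#' @param panel_long data.frame with columns `tumor_id`, `analyte`,
#'   `raw_signal`, `gapdh_signal`.
#' @return data.frame: `tumor_id` plus one normalized column per analyte.
#' @export
panel_to_wide <- function(panel_long) {
  stopifnot(all(c("tumor_id", "analyte", "raw_signal", "gapdh_signal")
                %in% names(panel_long)))
  panel_long$norm <- normalize_to_loading_control(panel_long$raw_signal,
                                                  panel_long$gapdh_signal)
  wide <- stats::reshape(
    panel_long[, c("tumor_id", "analyte", "norm")],
    idvar = "tumor_id", timevar = "analyte", direction = "wide")
  names(wide) <- sub("^norm\\.", "", names(wide))
  rownames(wide) <- NULL
  wide
}
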