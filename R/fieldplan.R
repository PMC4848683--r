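# Ki67 image-field sampling rule: the number of 400x fields captured per
# tumor section is set by the section's long-axis category, and fields are
# split between intensely stained "hotspot" regions and typical regions in
# proportion to the hotspot area, rounding partial fields up.

#' Plan Ki67 image-field sampling for a tumor section
#'
#' Total fields by long-axis category: < 10 mm -> 5 fields; 10 to < 15 mm
#' -> 10; 15 to < 20 mm -> 15; 20 mm and above -> 20 (the category
#' boundaries are half-open so exactly 20 mm falls in the largest
#' category). Hotspot fields are `ceiling(total * hotspot_percent / 100)`
#' — a 12 mm section with 30% hotspot area gets 3 hotspot and 7 typical
#' fields of 10 — and the remainder are captured from typical regions.
#'
#' @param long_axis_mm tumor section long axis, mm, > 0.
#' @param hotspot_percent percent of section area intensely stained, in
#'   \[0, 100\].
#' @return list of class `"sampling_plan"`: `long_axis_mm`,
#'   `hotspot_percent`, `total_fields`, `hotspot_fields`,
#'   `typical_fields`.
#' @export
#' @examples
#' plan_fields(12, 30)   # 3 hotspot + 7 typical of 10
#' plan_fields(17, 0)    # 15 fields, all typical
plan_fields <- function(long_axis_mm, hotspot_percent) {
  if (!is.numeric(long_axis_mm) || length(long_axis_mm) != 1L ||
      is.na(long_axis_mm) || long_axis_mm <= 0)
    stop("long_axis_mm must be a single positive number", call. = FALSE)
  if (!is.numeric(hotspot_percent) || length(hotspot_percent) != 1L ||
      is.na(hotspot_percent) || hotspot_percent < 0 ||
      hotspot_percent > 100)
    stop("hotspot_percent must lie in [0, 100]", call. = FALSE)
  total <- if (long_axis_mm < 10) 5L
  else if (long_axis_mm < 15) 10L
  else if (long_axis_mm < 20) 15L
  else 20L
  hot <- as.integer(ceiling(total * hotspot_percent / 100))
  out <- list(long_axis_mm = long_axis_mm,
              hotspot_percent = hotspot_percent,
              total_fields = total,
              hotspot_fields = hot,
              typical_fields = total - hot)
  class(out) <- "sampling_plan"
  out
}

#' @export
print.sampling_plan <- function(x, ...) {
  cat(sprintf(
    "Sampling plan (%g mm, %g%% hotspot): %d fields = %d hotspot + %d typical\n",
    x$long_axis_mm, x$hotspot_percent, x$total_fields, x$hotspot_fields,
    x$typical_fields))
  invisible(x)
}
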