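# Small cohort configuration for fast pipeline-level tests.
small_config <- function(seed = 1, ...) {
  cohort_config(n_rats_per_strain = c(DR = 40, DS = 40),
                incidence = c(DR = 0.8, DS = 0.9),
                multiplicity_mean = c(DR = 1.8, DS = 2.2),
                n_fields_per_tumor = 5L,
                seed = seed, ...)
}

# Summary-only growth fit (slope, SE) for the z-test comparison path.
summary_fit <- function(slope, se, n = 100) {
  structure(list(slope = slope, slope_se = se, intercept = 0.1,
                 n = n, r_squared = NA_real_),
            class = "growth_fit")
}
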