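#' Reference in-vivo study summaries
#'
#' Per-subject summaries from the eight-rabbit radioembolization study the
#' package's methods were validated on, shipped as plain-text reference
#' data: background HU statistics and calibration intercepts, administered
#' and image-recovered activities with recovery coefficients
#' (`subject_activity_table()`), the share of PET activity beyond the
#' extended liver volume (`pet_activity_ratio_table()`), and per-structure
#' dose metrics for the CT- and PET-based dose distributions
#' (`reported_dose_metrics_table()`). These are inputs for self-contained
#' arithmetic (recovery coefficients, agreement statistics), not outputs
#' of this package.
#'
#' @return A data frame.
#' @export
subject_activity_table <- function() {
  read.csv(system.file("extdata", "subject_activity.csv", package = "y90ct"))
}

#' @rdname subject_activity_table
#' @export
pet_activity_ratio_table <- function() {
  read.csv(system.file("extdata", "pet_activity_ratio.csv", package = "y90ct"))
}

#' @rdname subject_activity_table
#' @export
reported_dose_metrics_table <- function() {
  read.csv(system.file("extdata", "dose_metrics.csv", package = "y90ct"))
}

#' Microspheres per milligram from the mean sphere mass
#'
#' With a measured mean microsphere mass (mg), the count per milligram is
#' its reciprocal: a 4.09e-5 mg sphere gives ~24,460 spheres/mg.
#'
#' @param sphere_mass_mg mean microsphere mass in mg (> 0).
#' @return Microspheres per milligram.
#' @export
microspheres_per_mg <- function(sphere_mass_mg = 4.09e-5) {
  stopifnot(sphere_mass_mg > 0)
  1 / sphere_mass_mg
}
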