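# Printed summary tables of the motivating Silene nutans field study
# (eight parapatric populations, Viroin and Ourthe valleys, southern
# Belgium), shipped as plain-text fixtures: the per-population-year
# seed-predator abundances, the infrared camera recordings, and the fitted
# per-population kernel/autocorrelation summaries.

field_file <- function(name) {
  p <- system.file("extdata", name, package = "pollenflow")
  if (!nzchar(p)) stop("bundled data file not found: ", name)
  p
}

#' Bundled field summary tables
#'
#' Loaders for the study's printed summary data shipped with the package:
#'
#' * `load_predator_counts()` — seed-predator abundances per population and
#'   year, grouped in five taxonomic groups (a community table).
#' * `load_camera_records()` — per-recording infrared camera results
#'   (duration, flowers filmed/visited, moths observed, per-hour rates).
#' * `load_kernel_parameters()` — per-population fitted kernel extent
#'   `alpha`, shape `beta`, mean transfer distance `delta_k`, Moran's I and
#'   the Gamma distance-decay coefficient (with `gamma_p_upper` the printed
#'   upper bound on its p-value). Populations whose chi-squared fit was
#'   degenerate (extent pinned near zero) or unavailable carry `alpha =
#'   1e-4` or `NA`.
#'
#' @return a validated data.frame (community or camera table) or a plain
#'   data.frame for the kernel parameters.
#' @name field_tables
NULL

#' @rdname field_tables
#' @export
load_predator_counts <- function() {
  read_community_table(field_file("seed_predator_counts.csv"))
}

#' @rdname field_tables
#' @export
load_camera_records <- function() {
  read_camera_table(field_file("camera_observations.csv"))
}

#' @rdname field_tables
#' @export
load_kernel_parameters <- function() {
  read.csv(field_file("kernel_parameters.csv"), stringsAsFactors = FALSE)
}
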