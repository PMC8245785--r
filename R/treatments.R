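#' Define an experimental treatment
#'
#' A treatment fixes the environmental conditions and conversion constants in
#' force for a set of cultures: the irradiance, the target prey density the
#' cultures are diluted back to each day, the photoperiod, and the two carbon
#' conversion constants (per-cell prey carbon and the carbon-to-biovolume
#' factor for the ciliate).
#'
#' @param treatment_id character label, e.g. `"I40_P5e3"`.
#' @param irradiance photon flux, umol photons m-2 s-1 (> 0).
#' @param prey_target prey density the culture is returned to at each daily
#'   dilution, cells mL-1 (>= 0; 0 denotes a starvation phase with no prey
#'   additions).
#' @param light_hours hours of light per day (default 14, a 14:10 h
#'   light:dark cycle).
#' @param prey_carbon carbon content per prey cell, pg C (default 10).
#' @param carbon_per_volume ciliate carbon-to-biovolume conversion,
#'   pg C um-3 (default 0.19).
#'
#' @return A one-row `data.frame` of class `kc_treatment` with the six fields.
#' @examples
#' treatment("I40_high", irradiance = 40, prey_target = 4e4)
#' @export
treatment <- function(treatment_id, irradiance, prey_target,
                      light_hours = 14, prey_carbon = 10,
                      carbon_per_volume = 0.19) {
  stopifnot(is.character(treatment_id), length(treatment_id) == 1L)
  if (!is.finite(irradiance) || irradiance <= 0)
    stop("irradiance must be > 0 (umol photons m-2 s-1)")
  if (!is.finite(prey_target) || prey_target < 0)
    stop("prey_target must be >= 0 (cells mL-1)")
  if (!is.finite(light_hours) || light_hours <= 0 || light_hours > 24)
    stop("light_hours must satisfy 0 < light_hours <= 24")
  if (!is.finite(prey_carbon) || prey_carbon <= 0)
    stop("prey_carbon must be > 0 (pg C cell-1)")
  if (!is.finite(carbon_per_volume) || carbon_per_volume <= 0)
    stop("carbon_per_volume must be > 0 (pg C um-3)")
  out <- data.frame(
    treatment_id = treatment_id, irradiance = irradiance,
    prey_target = prey_target, light_hours = light_hours,
    prey_carbon = prey_carbon, carbon_per_volume = carbon_per_volume,
    stringsAsFactors = FALSE
  )
  class(out) <- c("kc_treatment", "data.frame")
  out
}

#' Bind treatments into a treatment table
#'
#' @param ... `kc_treatment` rows from [treatment()].
#' @return A `data.frame` with one row per treatment.
#' @export
treatment_table <- function(...) {
  rows <- list(...)
  stopifnot(length(rows) > 0L)
  out <- do.call(rbind, lapply(rows, as.data.frame))
  if (anyDuplicated(out$treatment_id))
    stop("duplicate treatment_id in treatment table")
  class(out) <- c("kc_treatment", "data.frame")
  out
}

# Look up a single treatment row by id; errors if absent.
treatment_row <- function(treatments, treatment_id) {
  i <- match(treatment_id, treatments$treatment_id)
  if (is.na(i)) stop("unknown treatment_id: ", treatment_id)
  treatments[i, , drop = FALSE]
}
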