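#' Biovolume from linear cell dimensions
#'
#' Lugol-fixed ciliate cells are classified as spherical or ellipsoidal from
#' their length/width ratio and their biovolume computed from the two linear
#' dimensions. "Ellipsoid" is implemented as a prolate spheroid (length is
#' the rotation axis, width the two equal equatorial axes), the standard
#' convention in ciliate biometry: `Bv = (pi/6) * length * width^2`. For a
#' sphere the diameter is taken as the mean of the two measured axes, so the
#' result does not depend on which axis happened to be labelled length:
#' `Bv = (pi/6) * ((length + width)/2)^3`. The two formulas coincide when
#' `length == width`.
#'
#' @param length cell length, um (> 0). Vectorised.
#' @param width cell width, um (> 0).
#' @param shape `"sphere"` or `"ellipsoid"` (recycled).
#' @param volume_correction multiplicative volume correction (e.g. for
#'   fixation shrinkage); default 1 (none applied).
#' @return Biovolume, um^3.
#' @examples
#' biovolume(10, 10, "sphere")        # (pi/6) * 1000
#' biovolume(40, 20, "ellipsoid")     # (pi/6) * 40 * 400
#' @export
biovolume <- function(length, width, shape = "ellipsoid",
                      volume_correction = 1) {
  if (any(!is.finite(length) | length <= 0) ||
      any(!is.finite(width) | width <= 0))
    stop("biovolume: length and width must be > 0 (um)")
  if (!all(shape %in% c("sphere", "ellipsoid")))
    stop("biovolume: shape must be 'sphere' or 'ellipsoid'")
  n <- max(length(length), length(width), length(shape))
  length <- rep_len(length, n); width <- rep_len(width, n)
  shape <- rep_len(shape, n)
  bv <- ifelse(shape == "sphere",
               pi / 6 * ((length + width) / 2)^3,
               pi / 6 * length * width^2)
  bv * volume_correction
}

#' Ciliate carbon content from biovolume
#'
#' Linear biovolume-to-carbon conversion, `C_y = carbon_per_volume * Bv`
#' with the default factor 0.19 pg C um-3.
#'
#' @param Bv biovolume, um^3 (>= 0). Vectorised.
#' @param treatment a [treatment()] row supplying `carbon_per_volume`.
#' @return Cell carbon content, pg C cell-1.
#' @export
ciliate_carbon <- function(Bv, treatment) {
  if (any(!is.finite(Bv) | Bv < 0)) stop("ciliate_carbon: Bv must be >= 0")
  treatment$carbon_per_volume * Bv
}

#' Prey density in carbon units
#'
#' Converts a prey cell density to its carbon equivalent,
#' `density * prey_carbon / 1000` (pg to ng), with the default 10 pg C per
#' prey cell. The three acclimation prey-density treatments 5e3, 1e4 and
#' 4e4 cells mL-1 correspond to 50, 100 and 400 ng C mL-1.
#'
#' @param density prey density, cells mL-1 (>= 0). Vectorised.
#' @param treatment a [treatment()] row supplying `prey_carbon`.
#' @return Carbon-equivalent density, ng C mL-1.
#' @export
prey_carbon_density <- function(density, treatment) {
  if (any(!is.finite(density) | density < 0))
    stop("prey_carbon_density: density must be >= 0")
  density * treatment$prey_carbon / 1000
}
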