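#' Sphere and disc conversions between 2D and 3D spine-head measurements
#'
#' Spine heads reconstructed in 3D are approximated as spheres; spine-head
#' profiles measured on single sections are approximated as circles, taken to
#' be the largest section of that sphere. Membrane apposition lengths measured
#' in 2D (PSD length, synaptic apposition length) are converted to areas by
#' treating each length as the diameter of a disc. These four functions form
#' the complete conversion algebra; all are vectorised and use micrometre
#' units throughout (lengths um, areas um^2, volumes um^3).
#'
#' @name geometry
#' @keywords internal
NULL

.check_nonneg <- function(x, what) {
  if (!is.numeric(x)) stop(what, " must be numeric", call. = FALSE)
  if (anyNA(x)) stop(what, " contains missing values", call. = FALSE)
  if (any(x < 0)) stop(what, " must be non-negative", call. = FALSE)
  invisible(x)
}

#' Radius of the sphere with a given volume
#'
#' Inverts \eqn{V = \frac{4}{3}\pi R^3}, giving \eqn{R = (3V/4\pi)^{1/3}}.
#'
#' @param volume Sphere volume(s), um^3. Must be non-negative.
#' @return Radius (um), same length as `volume`; exactly zero for zero volume.
#' @examples
#' sphere_radius_from_volume(4 * pi / 3) # unit sphere
#' @export
sphere_radius_from_volume <- function(volume) {
  .check_nonneg(volume, "volume")
  (3 * volume / (4 * pi))^(1 / 3)
}

#' Equivalent circle area of a sphere of given volume
#'
#' Maps a 3D head volume onto the area of the sphere's equatorial (largest)
#' section: \eqn{A = \pi R^2} with \eqn{R = (3V/4\pi)^{1/3}}. This is how
#' reconstructed head volumes are made comparable with areas measured on
#' single-section micrographs.
#'
#' @param volume Head volume(s), um^3. Must be non-negative.
#' @return Equivalent profile area(s), um^2. Strictly increasing in `volume`.
#' @seealso [area_to_equivalent_volume()] for the exact inverse.
#' @export
volume_to_equivalent_area <- function(volume) {
  r <- sphere_radius_from_volume(volume)
  pi * r^2
}

#' Equivalent sphere volume of a measured profile area
#'
#' Treats a spine-head profile area as the largest section of a sphere and
#' returns that sphere's volume: \eqn{V = \frac{4}{3}\pi (A/\pi)^{3/2}}.
#' Exact inverse of [volume_to_equivalent_area()].
#'
#' @param area Profile area(s), um^2. Must be non-negative.
#' @return Equivalent head volume(s), um^3.
#' @export
area_to_equivalent_volume <- function(area) {
  .check_nonneg(area, "area")
  r <- sqrt(area / pi)
  (4 / 3) * pi * r^3
}

#' Disc area of a membrane apposition length
#'
#' Converts a length measured on a 2D section (PSD length or synaptic
#' apposition length) to the area of the disc having that length as its
#' diameter: \eqn{A = \pi (L/2)^2}. The resulting PSD_S and SAL_S areas are
#' directly comparable with the synaptic apposition surface (SAS) measured on
#' 3D reconstructions.
#'
#' @param length Apposition length(s), um. Must be non-negative.
#' @return Disc area(s), um^2.
#' @export
length_to_disc_area <- function(length) {
  .check_nonneg(length, "length")
  pi * (length / 2)^2
}

#' Round a value the way it is reported
#'
#' Reported tables round half-to-even at three decimals (the precision of the
#' printed morphometric literature this package compares against); internal
#' computation is always carried at full precision.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 3).
#' @return Rounded vector.
#' @export
report_round <- function(x, digits = 3) round(x, digits)
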