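# Differential geometry of helices and of membrane tubes wound around them.
# All lengths are in nanometres; angles are radians internally. A helix of
# radius R and reduced pitch P (axial pitch = 2*pi*P) has Frenet curvature
# kappa_c = R/(R^2+P^2) and torsion tau = P/(R^2+P^2).

#' Specify a helix by radius and reduced pitch
#'
#' A helix is parametrized as `(R cos t, R sin t, P t)`: `radius_R` is the
#' distance of the curve from its axis and `reduced_pitch_P` is the axial rise
#' per radian, so the familiar axial pitch (rise per full turn) is `2*pi*P`.
#' The reduced pitch is the natural variable of the mechanics: curvature and
#' torsion are rational functions of `(R, P)`.
#'
#' @param radius_R Helix radius (nm), strictly positive.
#' @param reduced_pitch_P Reduced pitch (nm), non-negative; `P = 0` is a
#'   planar circle.
#' @param handedness `"left"` or `"right"`. Metadata only: every energy in
#'   this package is invariant under mirror reflection, and the experimental
#'   handedness could not be confirmed against a chiral standard.
#' @return An object of class `helix_spec`.
#' @seealso [helix_curvature()], [helix_torsion()],
#'   [helix_from_curvature_torsion()], [helix_axial_pitch()]
#' @examples
#' h <- helix_spec(29.2, 8.451)
#' helix_curvature(h)
#' helix_axial_pitch(h)
#' @export
helix_spec <- function(radius_R, reduced_pitch_P, handedness = c("left", "right")) {
  check_number(radius_R, "radius_R", lower = 0, strict_lower = TRUE)
  check_number(reduced_pitch_P, "reduced_pitch_P", lower = 0)
  handedness <- match.arg(handedness)
  structure(
    list(radius_R = radius_R, reduced_pitch_P = reduced_pitch_P,
         handedness = handedness),
    class = "helix_spec"
  )
}

#' @export
print.helix_spec <- function(x, ...) {
  cat(sprintf(
    "<helix_spec> R = %.4g nm, P = %.4g nm (axial pitch %.4g nm), %s-handed\n",
    x$radius_R, x$reduced_pitch_P, helix_axial_pitch(x), x$handedness))
  cat(sprintf("  curvature %.4g 1/nm, torsion %.4g 1/nm\n",
              helix_curvature(x), helix_torsion(x)))
  invisible(x)
}

as_helix_spec <- function(h, name = "h") {
  if (!inherits(h, "helix_spec"))
    stop_escrtube(sprintf("`%s` must be a helix_spec", name),
                  "escrtube_invalid_input")
  h
}

#' Axial pitch of a helix
#'
#' Rise of the helix per full turn, `2*pi*P`, the quantity reported by the
#' tomographic measurements.
#'
#' @param h A [helix_spec()].
#' @return Axial pitch (nm).
#' @export
helix_axial_pitch <- function(h) {
  2 * pi * as_helix_spec(h)$reduced_pitch_P
}

#' Frenet curvature of a helix
#'
#' @param h A [helix_spec()].
#' @return Curvature `R/(R^2 + P^2)` (1/nm), strictly positive.
#' @examples
#' helix_curvature(helix_spec(10, 0)) # a circle: 1/10
#' @export
helix_curvature <- function(h) {
  h <- as_helix_spec(h)
  h$radius_R / (h$radius_R^2 + h$reduced_pitch_P^2)
}

#' Frenet torsion of a helix
#'
#' @param h A [helix_spec()].
#' @return Torsion `P/(R^2 + P^2)` (1/nm); zero exactly when `P = 0`.
#' @export
helix_torsion <- function(h) {
  h <- as_helix_spec(h)
  h$reduced_pitch_P / (h$radius_R^2 + h$reduced_pitch_P^2)
}

#' Reconstruct a helix from curvature and torsion
#'
#' Inverse of [helix_curvature()] and [helix_torsion()]: a helix with
#' curvature `kappa_c > 0` and torsion `tau >= 0` has
#' `R = kappa_c/(kappa_c^2 + tau^2)` and `P = tau/(kappa_c^2 + tau^2)`.
#'
#' @param kappa_c Curvature (1/nm), strictly positive.
#' @param tau Torsion (1/nm), non-negative.
#' @param handedness Passed to [helix_spec()].
#' @return A [helix_spec()].
#' @examples
#' h <- helix_from_curvature_torsion(0.1, 0) # circle of radius 10
#' h$radius_R
#' @export
helix_from_curvature_torsion <- function(kappa_c, tau, handedness = "left") {
  check_number(kappa_c, "kappa_c", lower = 0, strict_lower = TRUE)
  check_number(tau, "tau", lower = 0)
  q <- kappa_c^2 + tau^2
  helix_spec(kappa_c / q, tau / q, handedness)
}

#' Membrane tube around a helical centerline
#'
#' A tube of radius `tube_radius_r` whose centerline is the helix `centerline`
#' (a canal surface). The tube is locally embedded (no self-intersection of
#' the surface) only when `kappa_c * r < 1`; this is enforced. When two
#' adjacent helical turns of the tube would touch (`2 r >= 2 pi P`), the
#' geometry is still returned but carries a `clearance_ok = FALSE` flag and a
#' warning, since the measured structures never violate it by much and the
#' energy model ignores turn-turn contact.
#'
#' @param centerline A [helix_spec()].
#' @param tube_radius_r Tube (membrane) radius (nm), strictly positive.
#' @return An object of class `tube_geometry` with fields `centerline`,
#'   `tube_radius_r` and `clearance_ok`.
#' @seealso [tube_from_measurements()]
#' @export
tube_geometry <- function(centerline, tube_radius_r) {
  centerline <- as_helix_spec(centerline, "centerline")
  check_number(tube_radius_r, "tube_radius_r", lower = 0, strict_lower = TRUE)
  kc <- helix_curvature(centerline)
  if (tube_radius_r * kc >= 1)
    stop_escrtube(sprintf(
      "tube is not embeddable: r * kappa_c = %.3f >= 1 (self-intersecting canal surface)",
      tube_radius_r * kc), "escrtube_embedding_error")
  clearance_ok <- 2 * tube_radius_r < helix_axial_pitch(centerline)
  if (!clearance_ok)
    warn_escrtube(sprintf(
      "adjacent helical turns overlap: tube diameter %.3g nm >= axial pitch %.3g nm",
      2 * tube_radius_r, helix_axial_pitch(centerline)),
      "escrtube_clearance_warning")
  structure(
    list(centerline = centerline, tube_radius_r = tube_radius_r,
         clearance_ok = clearance_ok),
    class = "tube_geometry"
  )
}

#' @export
print.tube_geometry <- function(x, ...) {
  cat(sprintf("<tube_geometry> r = %.4g nm around\n  ", x$tube_radius_r))
  print(x$centerline)
  if (!x$clearance_ok) cat("  [adjacent-turn clearance violated]\n")
  invisible(x)
}

as_tube_geometry <- function(t, name = "t") {
  if (!inherits(t, "tube_geometry"))
    stop_escrtube(sprintf("`%s` must be a tube_geometry", name),
                  "escrtube_invalid_input")
  t
}

#' Build a tube geometry from measured dimensions
#'
#' Converts the dimensions reported for helical membrane tubes -- outer
#' diameter of the superhelix, axial pitch, and tube diameter -- to the model
#' parameters. The convention is that the outer diameter is the outermost
#' extent of the membrane, so the centerline helix radius is
#' `R = (outer_diameter - tube_diameter)/2`, the reduced pitch is
#' `P = axial_pitch/(2 pi)`, and the tube radius is `tube_diameter/2`.
#'
#' @param outer_diameter Outermost diameter of the superhelix (nm).
#' @param axial_pitch Axial pitch of the superhelix (nm).
#' @param tube_diameter Diameter of the membrane tube (nm). Must be smaller
#'   than `outer_diameter`, else there is no room for a centerline helix.
#' @return A [tube_geometry()].
#' @examples
#' tube_from_measurements(82.3, 53.1, 23.9) # the measured mean geometry
#' @export
tube_from_measurements <- function(outer_diameter, axial_pitch, tube_diameter) {
  check_number(outer_diameter, "outer_diameter", lower = 0, strict_lower = TRUE)
  check_number(axial_pitch, "axial_pitch", lower = 0, strict_lower = TRUE)
  check_number(tube_diameter, "tube_diameter", lower = 0, strict_lower = TRUE)
  if (outer_diameter <= tube_diameter)
    stop_escrtube(sprintf(
      "outer_diameter (%.3g) must exceed tube_diameter (%.3g): no room for a centerline helix",
      outer_diameter, tube_diameter), "escrtube_invalid_input")
  tube_geometry(
    helix_spec((outer_diameter - tube_diameter) / 2, axial_pitch / (2 * pi)),
    tube_diameter / 2
  )
}

#' Filament arc length per unit axial length
#'
#' The contour length of a helix per unit length of its axis,
#' `sqrt(R^2 + P^2)/P >= 1`. Used to convert between energies per unit
#' filament (= centerline) length and per unit axial length of the
#' superhelix. Diverges as `P -> 0` (a circle advances nowhere axially);
#' this degenerate geometry is signalled as a distinct error.
#'
#' @param h A [helix_spec()] with `P > 0`.
#' @return Dimensionless ratio `>= 1`.
#' @export
arc_per_axial <- function(h) {
  h <- as_helix_spec(h)
  if (h$reduced_pitch_P <= 0)
    stop_escrtube("arc length per axial length is infinite for P = 0",
                  "escrtube_degenerate_geometry")
  sqrt(h$radius_R^2 + h$reduced_pitch_P^2) / h$reduced_pitch_P
}

#' Helical arc length occupied by one filament subunit
#'
#' From the helical symmetry of the filament (twist rotation per subunit and
#' axial rise per subunit) and the filament helix radius, the contour length
#' of filament per monomer is `sqrt((radius * twist)^2 + rise^2)` with the
#' twist in radians. This converts the differential binding energy `mu`
#' between per-unit-length and per-monomer units.
#'
#' @param filament_helix_radius Radius of the filament helix (nm).
#' @param twist_per_subunit Twist rotation angle per subunit (degrees).
#' @param rise_per_subunit Axial rise per subunit (nm).
#' @return Arc length per monomer (nm).
#' @examples
#' # measured helical symmetry (twist 6.7 deg, rise 1.06 nm) on the zigzag
#' # ribbon radius:
#' monomer_arc_length(23.1, 6.7, 1.06)
#' @export
monomer_arc_length <- function(filament_helix_radius, twist_per_subunit,
                               rise_per_subunit) {
  check_number(filament_helix_radius, "filament_helix_radius", lower = 0,
               strict_lower = TRUE)
  check_number(twist_per_subunit, "twist_per_subunit", lower = 0)
  check_number(rise_per_subunit, "rise_per_subunit", lower = 0)
  if (twist_per_subunit <= 0 && rise_per_subunit <= 0)
    stop_escrtube("twist and rise cannot both be zero",
                  "escrtube_invalid_input")
  sqrt((filament_helix_radius * twist_per_subunit * pi / 180)^2 +
         rise_per_subunit^2)
}

# default monomer arc: measured helical symmetry on the zigzag-ribbon radius
default_monomer_arc <- function() monomer_arc_length(23.1, 6.7, 1.06)
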