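#' Define an axisymmetric cell geometry
#'
#' Three shapes cover the in-silico protocols:
#' \describe{
#'   \item{`disk`}{a cylindrical disk (radius x thickness), used for
#'     localised indentation; the classic choice to minimise edge effects.}
#'   \item{`elliptical_cap`}{a half-ellipse of revolution (semi-axes
#'     `radius` horizontally and `thickness` vertically) attached to a
#'     substrate, idealising an adherent interphase cell; used for
#'     microinjection and depressurisation.}
#'   \item{`column`}{a laterally confined cylinder, the 1D consolidation
#'     (Terzaghi) benchmark geometry.}
#' }
#'
#' @param shape `"disk"`, `"elliptical_cap"` or `"column"`.
#' @param radius Domain radius, um (for the cap: the horizontal semi-axis,
#'   i.e. half the footprint diameter).
#' @param thickness Domain height, um (for the cap: apex height).
#' @param cortex_thickness Thickness of the low-permeability surface layer,
#'   um; 0 means a single-layer material.
#' @param indenter_radius Spherical indenter radius R, um (indentation only).
#' @param contact_radius Radius of the pipette contact / sink region on the
#'   top surface, um.
#' @return A list of class `scenario_geometry`.
#' @examples
#' scenario_geometry("disk", radius = 20, thickness = 20)
#' scenario_geometry("elliptical_cap", radius = 20, thickness = 4.5,
#'                   cortex_thickness = 0.25)
#' @export
scenario_geometry <- function(shape = c("disk", "elliptical_cap", "column"),
                              radius, thickness, cortex_thickness = 0,
                              indenter_radius = 2, contact_radius = 1) {
  shape <- match.arg(shape)
  num1 <- function(x, nm, min_ok = FALSE) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
        (if (min_ok) x < 0 else x <= 0))
      abort(sprintf("`%s` must be a single %s number.",
                    nm, if (min_ok) "non-negative" else "positive"))
    x
  }
  radius <- num1(radius, "radius")
  thickness <- num1(thickness, "thickness")
  cortex_thickness <- num1(cortex_thickness, "cortex_thickness", min_ok = TRUE)
  indenter_radius <- num1(indenter_radius, "indenter_radius")
  contact_radius <- num1(contact_radius, "contact_radius")
  if (cortex_thickness >= thickness)
    abort("`cortex_thickness` must be smaller than `thickness`.")
  if (contact_radius >= radius)
    abort("`contact_radius` must be smaller than `radius`.")
  structure(
    list(shape = shape, radius = radius, thickness = thickness,
         cortex_thickness = cortex_thickness,
         indenter_radius = indenter_radius,
         contact_radius = contact_radius),
    class = "scenario_geometry")
}

#' @export
print.scenario_geometry <- function(x, ...) {
  cat(sprintf("<scenario_geometry> %s: radius %g um, thickness %g um",
              x$shape, x$radius, x$thickness))
  if (x$cortex_thickness > 0)
    cat(sprintf(", cortex %g um", x$cortex_thickness))
  cat("\n")
  invisible(x)
}

# Cap height profile h(r); vectorised.
cap_height <- function(geom, r) {
  geom$thickness * sqrt(pmax(0, 1 - (r / geom$radius)^2))
}
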