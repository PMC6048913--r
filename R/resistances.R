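# Hydraulic resistance of each network element kind, in Pa s/m^3.
# Flow obeys the hydraulic Ohm's law  dp = R q  with constant R over the
# pulse cycle (the pulse amplitude is small enough that the free-fluid PVS
# resistance varies by < 5%, so R is evaluated at the time-averaged radii).

#' Annular Poiseuille resistance of a free-fluid PVS segment
#'
#' Hydraulic resistance of steady pressure-driven axial flow through a
#' straight concentric annulus (Navier-Stokes solution):
#' \deqn{R = \frac{8 \mu l}{\pi R_o^4 \left[1 - E^4 +
#'   (E^2 - 1)^2 / \ln E\right]}}
#' where \eqn{E = R_i / R_o} is the radius ratio.  Because the oscillation
#' wavelength is much longer than the segment and the Womersley number is
#' small, the quasi-steady profile applies at each instant.
#'
#' @param mu dynamic viscosity (Pa s).
#' @param l segment length modeled by the resistor (m).
#' @param R_o annulus outer radius (m).
#' @param E inner:outer radius ratio, in (0, 1).
#' @return resistance (Pa s/m^3); 0 when `l == 0`.
#' @examples
#' annular_poiseuille_resistance(0.9e-3, 100e-6, 30e-6, 1 / 3)  # ~1.05e12
#' @export
annular_poiseuille_resistance <- function(mu, l, R_o, E) {
  stopifnot(mu > 0, l >= 0, R_o > 0)
  if (E <= 0 || E >= 1)
    stop("radius ratio E must lie strictly in (0, 1); got ", E,
         call. = FALSE)
  bracket <- 1 - E^4 + (E^2 - 1)^2 / log(E)
  if (bracket <= 0) stop("degenerate annulus: non-positive shape factor")
  8 * mu * l / (pi * R_o^4 * bracket)
}

#' Radial Darcy resistance of a parenchyma cylindrical shell
#'
#' One-dimensional radial Darcy flow through a rigid porous cylindrical
#' shell of height `h`:
#' \deqn{R = \ln(R_o^{PCY}/R_i^{PCY}) / (2 \pi h K_{PCY})}
#'
#' @param K_PCY parenchyma hydraulic conductivity (m^3 s/kg).
#' @param h shell height (m).
#' @param R_i_PCY,R_o_PCY shell inner and outer radii (m), `R_i_PCY <
#'   R_o_PCY` (equal radii give zero resistance).
#' @return resistance (Pa s/m^3).
#' @examples
#' radial_shell_resistance(5.63e-12, 100e-6, 10e-6, 300e-6)  # ~9.6e14
#' @export
radial_shell_resistance <- function(K_PCY, h, R_i_PCY, R_o_PCY) {
  stopifnot(K_PCY > 0, h > 0, R_i_PCY > 0)
  if (R_o_PCY < R_i_PCY)
    stop("shell radii out of order: R_o_PCY < R_i_PCY", call. = FALSE)
  log(R_o_PCY / R_i_PCY) / (2 * pi * h * K_PCY)
}

#' Axial Darcy resistance of a porous-media annulus
#'
#' Alternative PVS resistance accounting for solid components in the
#' perivascular space: axial Darcy flow through an annulus of rigid porous
#' media, \eqn{R = l / (\pi (R_o^2 - R_i^2) K_{PVS})}.
#'
#' @param K_PVS PVS hydraulic conductivity (m^3 s/kg).
#' @param l segment length (m); 0 gives zero resistance.
#' @param R_i,R_o annulus radii (m), `R_i < R_o`.
#' @return resistance (Pa s/m^3).
#' @export
porous_annulus_resistance <- function(K_PVS, l, R_i, R_o) {
  stopifnot(K_PVS > 0, l >= 0, R_i > 0)
  if (R_o <= R_i)
    stop("degenerate annulus: R_o <= R_i", call. = FALSE)
  l / (pi * (R_o^2 - R_i^2) * K_PVS)
}

#' Darcy resistance of a rectangular parenchyma slab
#'
#' Plane Darcy flow through a rigid porous slab of length `l` (flow
#' direction), height `h` and depth `d`: \eqn{R = l / (K_{PCY} h d)}.  Used
#' for the two-vessel parenchyma grid elements.
#'
#' @param K_PCY hydraulic conductivity (m^3 s/kg).
#' @param l element length along the flow (m).
#' @param h,d cross-section height and depth (m).
#' @return resistance (Pa s/m^3).
#' @export
darcy_slab_resistance <- function(K_PCY, l, h, d) {
  stopifnot(K_PCY > 0, l > 0, h > 0, d > 0)
  l / (K_PCY * h * d)
}

#' Womersley number of the PVS annular gap
#'
#' \eqn{\alpha = 2 (R_o - R_i) \sqrt{2 \pi f \rho / \mu}}, using twice the
#' gap thickness as the hydrodynamic radius.  Small values (baseline ~0.24)
#' justify the quasi-steady velocity profile used throughout.
#'
#' @param R_i,R_o annulus radii (m).
#' @param f pulse frequency (Hz); 0 gives the static limit `alpha = 0`.
#' @param rho fluid density (kg/m^3).
#' @param mu dynamic viscosity (Pa s).
#' @return dimensionless Womersley number.
#' @export
womersley_number <- function(R_i, R_o, f, rho, mu) {
  stopifnot(R_o > R_i, f >= 0, rho > 0, mu > 0)
  2 * (R_o - R_i) * sqrt(2 * pi * f * rho / mu)
}

# --- resistance elements -----------------------------------------------

#' Construct a network resistance element
#'
#' Bundles an element kind with its geometry, its hydraulic resistance and
#' the cross-section areas used to convert volumetric flow to velocity.
#'
#' Velocity conventions: full annuli use the annular section
#' \eqn{\pi(R_o^2 - R_i^2)}; half-annulus elements (two-vessel model)
#' carry twice the full-annulus resistance and half its geometric section,
#' but report velocity through the full annular section so that one- and
#' two-vessel PVS velocities are directly comparable; slabs use `h d`;
#' radial shells have a radius-dependent section \eqn{2 \pi r h} (see
#' [element_velocity()]) and store the section at the PVS outer radius as
#' their default.  All velocities are superficial (Darcy) velocities.
#'
#' @param kind one of `"annular_free"`, `"annular_porous"`,
#'   `"radial_shell"`, `"darcy_slab"`.
#' @param p a `pvs_parameters` object supplying material properties.
#' @param l element length (m) for axial/slab kinds.
#' @param half_annulus logical; model only half the annular section
#'   (doubles the resistance, halves the geometric area).
#' @param eval_radius radius at which a radial shell reports velocity
#'   (defaults to the PVS outer radius `p$R_o`).
#' @return list of class `resistance_element` with fields `kind`, `R`
#'   (Pa s/m^3), `area` (geometric section, m^2), `velocity_area`
#'   (section used for velocity conversion, m^2), `l`, `half_annulus`, and
#'   the geometry used.
#' @export
resistance_element <- function(kind = c("annular_free", "annular_porous",
                                        "radial_shell", "darcy_slab"),
                               p, l = NA_real_, half_annulus = FALSE,
                               eval_radius = NULL) {
  kind <- match.arg(kind)
  ann_area <- pi * (p$R_o^2 - p$R_i^2)
  el <- switch(kind,
    annular_free = {
      R <- annular_poiseuille_resistance(p$mu, l, p$R_o, p$R_i / p$R_o)
      list(R = R, area = ann_area, velocity_area = ann_area)
    },
    annular_porous = {
      R <- porous_annulus_resistance(p$K_PVS, l, p$R_i, p$R_o)
      list(R = R, area = ann_area, velocity_area = ann_area)
    },
    radial_shell = {
      r <- if (is.null(eval_radius)) p$R_o else eval_radius
      R <- radial_shell_resistance(p$K_PCY, p$h, p$R_i_PCY, p$R_o_PCY)
      list(R = R, area = 2 * pi * r * p$h, velocity_area = 2 * pi * r * p$h,
           eval_radius = r, h = p$h, R_i_PCY = p$R_i_PCY,
           R_o_PCY = p$R_o_PCY)
    },
    darcy_slab = {
      R <- darcy_slab_resistance(p$K_PCY, l, p$h, p$d)
      list(R = R, area = p$h * p$d, velocity_area = p$h * p$d)
    })
  if (half_annulus) {
    if (!kind %in% c("annular_free", "annular_porous"))
      stop("half_annulus applies only to annular elements")
    el$R <- 2 * el$R
    el$area <- el$area / 2      # geometric section available for flow
    # velocity_area stays the full annulus: reported velocities refer to
    # the full symmetric vessel of which the planar model represents half
  }
  el$kind <- kind
  el$l <- l
  el$half_annulus <- half_annulus
  if (el$R < 0 || el$area <= 0) stop("invalid element geometry")
  class(el) <- "resistance_element"
  el
}
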