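# Regime diagnostics: Peclet numbers comparing convective to diffusive
# solute transport rates, and the pulse wavelength underpinning the
# uniform-wall-motion assumption.

#' PVS Peclet number
#'
#' \eqn{Pe = L_{PVS} v / D^*} with the full vessel segment length as the
#' characteristic length and `v` the peak section-averaged axial velocity.
#'
#' @param v axial velocity (m/s).
#' @param D_star effective solute diffusivity (m^2/s).
#' @param L_PVS vessel segment length (m), default 300 um.
#' @return dimensionless Peclet number.
#' @examples
#' peclet_pvs(30e-6, 10e-12)  # ~900: convection-relevant
#' @export
peclet_pvs <- function(v, D_star, L_PVS = 300e-6) {
  stopifnot(v >= 0, D_star > 0, L_PVS > 0)
  L_PVS * v / D_star
}

#' Parenchyma Peclet number
#'
#' Two characteristic-length conventions: the inter-vessel distance
#' \eqn{Pe = L_{PCY} v / (\phi D^*)}, or the parenchyma pore size
#' \eqn{Pe = \eta v / (\phi D^*)} (used for the smallest diffusivities, as
#' is common for porous media).  `v` is the superficial velocity, hence
#' the porosity in the denominator.
#'
#' @param v superficial velocity (m/s).
#' @param D_star effective solute diffusivity (m^2/s).
#' @param length_mode `"inter_vessel"` or `"pore"`.
#' @param L_PCY inter-vessel distance (m), default 200 um.
#' @param eta pore size (m), default 60 nm.
#' @param phi porosity, default 0.2.
#' @return dimensionless Peclet number.
#' @examples
#' peclet_parenchyma(3.6e-9, 100e-12)          # ~0.036: diffusion-dominated
#' peclet_parenchyma(3.6e-9, 10e-12, "pore")   # ~1e-4
#' @export
peclet_parenchyma <- function(v, D_star,
                              length_mode = c("inter_vessel", "pore"),
                              L_PCY = 200e-6, eta = 60e-9, phi = 0.2) {
  length_mode <- match.arg(length_mode)
  stopifnot(v >= 0, D_star > 0, phi > 0, phi <= 1)
  L <- if (length_mode == "inter_vessel") L_PCY else eta
  L * v / (phi * D_star)
}

#' Pulse wavelength and long-wavelength ratio
#'
#' @param wave_speed arterial pulse wave speed (m/s).
#' @param f pulse frequency (Hz).
#' @param L_PVS modeled segment length (m) for the validity ratio.
#' @return list with `wavelength` (m) and `ratio` (wavelength / segment
#'   length; values much greater than 1 justify uniform wall motion along
#'   the segment).
#' @examples
#' wavelength(1, 5)$wavelength  # 0.2 m = 20 cm
#' @export
wavelength <- function(wave_speed, f, L_PVS = 300e-6) {
  stopifnot(wave_speed > 0, f > 0, L_PVS > 0)
  wl <- wave_speed / f
  list(wavelength = wl, ratio = wl / L_PVS)
}

#' Peclet table for a solved model
#'
#' Computes PVS and parenchyma Peclet numbers over a span of diffusivities
#' from a solved network's peak velocities.  PVS velocity is the peak
#' section-averaged velocity over the (free or porous) PVS elements;
#' parenchyma velocity is the peak superficial velocity over parenchyma
#' elements.  For the parenchyma, the inter-vessel distance is the
#' characteristic length except for the smallest diffusivity in the span,
#' where the pore size is used.
#'
#' @param solution a solved network from [solve_period()].
#' @param D_star diffusivities to tabulate (m^2/s); default
#'   10-1000 um^2/s.
#' @return data.frame with columns `region`, `D_star`, `length_mode`,
#'   `velocity`, `Pe`.
#' @export
peclet_table <- function(solution,
                         D_star = c(10, 100, 1000) * 1e-12) {
  p <- solution$network$layout$params
  pk <- solution$peaks
  pvs_v <- max(pk$peak_velocity[pk$kind %in% c("annular_free",
                                               "annular_porous")])
  pcy_v <- max(pk$peak_velocity[pk$kind %in% c("radial_shell",
                                               "darcy_slab")])
  rows <- list()
  for (D in D_star) {
    rows[[length(rows) + 1L]] <- data.frame(
      region = "PVS", D_star = D, length_mode = "segment",
      velocity = pvs_v, Pe = peclet_pvs(pvs_v, D, p$L_PVS))
    mode <- if (D == min(D_star)) "pore" else "inter_vessel"
    rows[[length(rows) + 1L]] <- data.frame(
      region = "parenchyma", D_star = D, length_mode = mode,
      velocity = pcy_v,
      Pe = peclet_parenchyma(pcy_v, D, mode, p$L_PCY, p$eta, p$phi))
  }
  do.call(rbind, rows)
}
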