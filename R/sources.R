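# Volumetric fluid sources: the rate of volume displacement produced by
# uniform sinusoidal motion of the PVS inner boundary.  These sources are
# the only drivers of fluid motion; no pressure gradients are imposed.

#' Construct a pulsatile volumetric source
#'
#' The PVS inner radius varies as \eqn{r_i(t) = R_i - b \cos(2 \pi f t)}
#' uniformly along the segment (the 20 cm pulse wavelength dwarfs the
#' 300 um segment).  Differentiating the contained volume
#' \eqn{V = \pi l r_i^2} gives the exact displaced flow rate
#' \eqn{q = 2 \pi l r_i \dot r_i}; because \eqn{b \ll R_i} the linearized
#' form \eqn{q \approx g\, l f b R_i \sin(2 \pi f t - \theta)} is used by
#' default, with geometry factor \eqn{g = 4 \pi^2} when the whole radial
#' outflow enters the model (one-vessel) and \eqn{g = 2 \pi^2} when only
#' half does (two-vessel planar model).
#'
#' @param l segment length modeled by the source (m).
#' @param R_i time-averaged inner radius (m).
#' @param b pulse amplitude (m), `b < R_i`.
#' @param f pulse frequency (Hz).
#' @param theta phase shift (rad) of the waveform.
#' @param geometry factor selector: `"full"` (g = 4 pi^2) or `"half"`
#'   (g = 2 pi^2).
#' @param mode `"linearized"` (default) or `"exact"` waveform.
#' @return object of class `pulsatile_source`.
#' @export
pulsatile_source <- function(l, R_i, b, f, theta = 0,
                             geometry = c("full", "half"),
                             mode = c("linearized", "exact")) {
  geometry <- match.arg(geometry)
  mode <- match.arg(mode)
  stopifnot(l > 0, R_i > 0, b >= 0, f > 0)
  if (b >= R_i) stop("pulse amplitude b must be smaller than R_i")
  structure(list(l = l, R_i = R_i, b = b, f = f, theta = theta,
                 g = if (geometry == "full") 4 * pi^2 else 2 * pi^2,
                 geometry = geometry, mode = mode),
            class = "pulsatile_source")
}

#' Instantaneous PVS inner radius
#'
#' \eqn{r_i(t) = R_i - b \cos(2 \pi f t - \theta)}: minimal at the start of
#' the (unshifted) cycle, time-average `R_i` over a period.
#'
#' @param src a `pulsatile_source`.
#' @param t time (s), vectorized.
#' @return inner radius (m).
#' @export
inner_radius <- function(src, t) {
  src$R_i - src$b * cos(2 * pi * src$f * t - src$theta)
}

#' Volumetric source flow rate
#'
#' Linearized mode evaluates \eqn{g l f b R_i \sin(2 \pi f t - \theta)};
#' exact mode evaluates the analytic time derivative of
#' \eqn{\pi l r_i(t)^2} (scaled by g / (4 pi^2) for half-geometry sources).
#' The relative peak difference between the two is bounded by `b / R_i`.
#'
#' @param src a `pulsatile_source`.
#' @param t time (s), vectorized.
#' @param mode optional override of the source's waveform mode.
#' @return flow rate (m^3/s), positive when the wall moves outward.
#' @export
source_rate <- function(src, t, mode = NULL) {
  mode <- if (is.null(mode)) src$mode else match.arg(mode,
                                                    c("linearized", "exact"))
  ph <- 2 * pi * src$f * t - src$theta
  if (mode == "linearized") {
    src$g * src$l * src$f * src$b * src$R_i * sin(ph)
  } else {
    # d/dt [pi l r_i^2] = 2 pi l r_i * (2 pi f b sin(ph))
    frac <- src$g / (4 * pi^2)  # half-geometry sources emit half the volume
    frac * 4 * pi^2 * src$l * src$f * src$b *
      (src$R_i * sin(ph) - src$b * sin(ph) * cos(ph))
  }
}

#' Pulsatility of a vessel wall waveform
#'
#' Twice the time-integral of the absolute inner-radius excursion over the
#' measurement interval, \eqn{\Pi = 2 \int_0^T |r_i - R_i| \, dt},
#' evaluated by adaptive quadrature.  For a sinusoidal excursion over one
#' full period this equals \eqn{4 b / (\pi f)}; only the ratio of venous to
#' arterial pulsatility (which reduces to the amplitude ratio at shared
#' frequency) is used by the models, so the overall constant is immaterial.
#'
#' @param b pulse amplitude (m).
#' @param f pulse frequency (Hz).
#' @param T measurement interval (s), default one period `1/f`.
#' @return pulsatility (m s).
#' @export
pulsatility <- function(b, f, T = 1 / f) {
  stopifnot(b >= 0, f > 0, T > 0)
  if (b == 0) return(0)
  # integrate over each half-period piece so the kinks of |cos| are on
  # subinterval boundaries
  breaks <- sort(unique(c(seq(0, T, by = 1 / (2 * f)), T)))
  breaks <- breaks[breaks <= T]
  if (breaks[length(breaks)] < T) breaks <- c(breaks, T)
  total <- 0
  for (i in seq_len(length(breaks) - 1L)) {
    total <- total + stats::integrate(
      function(t) abs(-b * cos(2 * pi * f * t)),
      breaks[i], breaks[i + 1L], rel.tol = 1e-10)$value
  }
  2 * total
}

#' Venous pulse amplitude from the pulsatility ratio
#'
#' At shared frequency the venous:arterial pulsatility ratio `xi` equals
#' the amplitude ratio, so `b_venous = xi * b_arterial`.
#'
#' @param b_arterial arterial pulse amplitude (m).
#' @param xi pulsatility ratio in [0, 1].
#' @return venous amplitude (m).
#' @export
venous_amplitude <- function(b_arterial, xi) {
  stopifnot(b_arterial >= 0, xi >= 0, xi <= 1)
  xi * b_arterial
}

#' @export
print.pulsatile_source <- function(x, ...) {
  cat(sprintf(
    "Pulsatile source: l=%g m, R_i=%g m, b=%g m, f=%g Hz, theta=%g rad, %s geometry, %s\n",
    x$l, x$R_i, x$b, x$f, x$theta, x$geometry, x$mode))
  invisible(x)
}
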