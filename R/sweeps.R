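# Parameter sweeps: rebuild the network at each grid point (all other
# parameters at baseline), solve one period, and tabulate per-element
# peaks.  Conductivity grids are typically logarithmic, amplitude/radius/
# phase grids linear, matching the physiological ranges explored.

#' Run a parameter sweep
#'
#' @param parameter one of `"b"` (pulse amplitude, m), `"radii"`
#'   (PVS inner/outer radius pairs), `"K_PVS"` (porous-PVS conductivity,
#'   m^3 s/kg; forces the porous-PVS variant), `"K_PCY"` (parenchyma
#'   conductivity, m^3 s/kg), `"xi"` (pulsatility ratio), `"theta"`
#'   (venous phase shift, rad).
#' @param values numeric vector of grid values; for `"radii"` a
#'   data.frame with columns `R_i`, `R_o` (m).
#' @param params baseline parameters ([pvs_parameters()]).
#' @param model `"one_vessel"` or `"two_vessel"`.
#' @param porous_pvs logical; use the porous-media PVS resistance
#'   (implied by `parameter = "K_PVS"`).
#' @param n_samples time samples per period.
#' @param radii_tol for the radii sweep: resistance-variation tolerance
#'   used to cap the pulse amplitude so narrow gaps keep an effectively
#'   constant free-fluid resistance (amplitude = smaller of the baseline
#'   `b` and [max_amplitude_for_resistance_tolerance()] at the narrowest
#'   grid gap).
#' @return data.frame of class `pvs_sweep`, one row per valid grid point
#'   and element: sweep value column(s), `label`, `kind`,
#'   `peak_velocity` (m/s), `peak_flow` (m^3/s), `peak_pressure` (Pa,
#'   network-wide for that grid point).  Invalid grid points (e.g.
#'   `R_i >= R_o`) are skipped and listed in `attr(, "skipped")`.
#' @export
run_sweep <- function(parameter = c("b", "radii", "K_PVS", "K_PCY",
                                    "xi", "theta"),
                      values, params = pvs_parameters(),
                      model = c("one_vessel", "two_vessel"),
                      porous_pvs = FALSE, n_samples = 256,
                      radii_tol = 0.05) {
  parameter <- match.arg(parameter)
  model <- match.arg(model)
  if (parameter == "K_PVS") porous_pvs <- TRUE
  base <- unclass(params)
  base$E <- NULL; base$model <- NULL

  grid <- if (parameter == "radii") {
    stopifnot(is.data.frame(values), all(c("R_i", "R_o") %in% names(values)))
    values
  } else data.frame(value = values)

  b_radii <- NULL
  if (parameter == "radii") {
    gaps <- grid$R_o - grid$R_i
    ok <- gaps > 0 & grid$R_i > 0
    if (any(ok)) {
      b_cap <- max_amplitude_for_resistance_tolerance(
        grid$R_i[ok][which.min(gaps[ok])],
        grid$R_o[ok][which.min(gaps[ok])], tol = radii_tol)
      b_radii <- min(base$b, b_cap)
    }
  }

  rows <- list(); skipped <- list()
  for (i in seq_len(nrow(grid))) {
    cfg <- base
    if (parameter == "radii") {
      cfg$R_i <- grid$R_i[i]; cfg$R_o <- grid$R_o[i]
      cfg$b <- min(b_radii, cfg$R_i * 0.5)
    } else {
      cfg[[if (parameter == "b") "b" else parameter]] <- grid$value[i]
    }
    pset <- tryCatch(load_parameters(cfg, model = model),
                     error = function(e) e)
    if (inherits(pset, "error")) {
      skipped[[length(skipped) + 1L]] <-
        list(row = i, reason = conditionMessage(pset))
      message("sweep: skipping grid point ", i, ": ",
              conditionMessage(pset))
      next
    }
    net <- build_model(pset, model = model, porous_pvs = porous_pvs)
    sol <- solve_period(net, n_samples = n_samples)
    pk <- sol$peaks
    out <- cbind(grid[rep(i, nrow(pk)), , drop = FALSE], pk,
                 peak_pressure = max(sol$node_peaks$peak_pressure))
    rownames(out) <- NULL
    rows[[length(rows) + 1L]] <- out
  }
  result <- do.call(rbind, rows)
  attr(result, "skipped") <- skipped
  attr(result, "parameter") <- parameter
  class(result) <- c("pvs_sweep", class(result))
  result
}

#' Largest pulse amplitude for a bounded resistance variation
#'
#' The free-fluid PVS resistance depends on the instantaneous inner
#' radius; it is treated as constant over the cycle provided it never
#' deviates from its time-averaged value by more than `tol`.  This solver
#' returns the largest amplitude `b` such that the relative deviation of
#' the annular Poiseuille resistance over
#' `r_i` in `[R_i - b, R_i + b]` stays within `tol`, found by a bracketing
#' root search to 1e-3 relative accuracy.  For a 1 um gap (R_i = 29 um,
#' R_o = 30 um) at `tol = 0.05` this gives ~16.2 nm.
#'
#' @param R_i,R_o time-averaged annulus radii (m).
#' @param tol allowed relative resistance deviation, in (0, 1); `tol = 0`
#'   returns 0.
#' @param mu dynamic viscosity (Pa s); cancels in the ratio but kept for
#'   interface symmetry.
#' @return amplitude b (m).
#' @export
max_amplitude_for_resistance_tolerance <- function(R_i, R_o, tol = 0.05,
                                                   mu = 0.9e-3) {
  stopifnot(R_o > R_i, R_i > 0, tol >= 0, tol < 1)
  if (tol == 0) return(0)
  R0 <- annular_poiseuille_resistance(mu, 1, R_o, R_i / R_o)
  deviation <- function(b) {
    r <- c(R_i - b, R_i + b)
    Rs <- vapply(r, function(ri)
      annular_poiseuille_resistance(mu, 1, R_o, ri / R_o), 0)
    max(abs(Rs - R0) / R0)
  }
  upper <- min(R_o - R_i, R_i) * (1 - 1e-9)
  if (deviation(upper) <= tol) return(upper)
  stats::uniroot(function(b) deviation(b) - tol, c(0, upper),
                 tol = .Machine$double.eps^0.5 * R_i)$root
}

#' Sweep the venous phase shift
#'
#' Solves the two-vessel model across a grid of venous phase shifts and
#' reports signed velocities a quarter period into the arterial waveform
#' (the arterial sources peak at `t = T/4`): the arterial and venous PVS
#' end elements (R1, R4), the central perpendicular parenchyma element
#' (R13), a parallel parenchyma element (R10), and the largest parenchyma
#' speed within 50-150 um of the arterial PVS.
#'
#' @param theta_grid phase shifts (rad) in `[0, 2*pi)`.
#' @param params baseline parameters.
#' @param n_samples time samples per period.
#' @return data.frame with columns `theta`, `v_arterial`, `v_venous`,
#'   `v_pcy_perpendicular`, `v_pcy_parallel` (signed, m/s) and
#'   `pcy_band_max` (m/s).
#' @export
phase_sweep <- function(theta_grid, params = pvs_parameters(),
                        n_samples = 256) {
  stopifnot(all(theta_grid >= 0), all(theta_grid < 2 * pi))
  base <- unclass(params); base$E <- NULL; base$model <- NULL
  rows <- lapply(theta_grid, function(th) {
    cfg <- base; cfg$theta <- th
    pset <- load_parameters(cfg, model = "two_vessel")
    sol <- solve_period(build_two_vessel(pset), n_samples = n_samples)
    k <- which.min(abs(sol$times - sol$period / 4))
    vel_at <- function(label)
      element_velocity(sol, label, peak = FALSE)[k]
    band <- parenchyma_elements(sol$network, 50e-6, 150e-6)
    data.frame(theta = th,
               v_arterial = vel_at("R1"),
               v_venous = vel_at("R4"),
               v_pcy_perpendicular = vel_at("R13"),
               v_pcy_parallel = vel_at("R10"),
               pcy_band_max = max(vapply(band, function(l)
                 abs(vel_at(l)), 0)))
  })
  do.call(rbind, rows)
}
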