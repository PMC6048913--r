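# Canonical internal unit system is SI (m, s, kg, Pa).  Every printed
# micrometre/nanometre/mmHg quantity is converted at the boundary so the
# physics code only ever sees SI numbers.

#' Baseline model parameters
#'
#' Returns the validated set of physical parameters for the one-vessel and
#' two-vessel perivascular flow models, in SI units.  Defaults are the
#' baseline values for rat cortex: a 10 um arteriole with a 30 um
#' perivascular space (PVS) outer boundary over a 300 um segment, a 0.25 um
#' sinusoidal wall pulse at 5 Hz, parenchyma hydraulic conductivity
#' 5.63e-12 m^2/(Pa s), interstitial fluid viscosity 0.9e-3 Pa s and
#' density 993.2 kg/m^3, porosity 0.2, pore size 60 nm, venous:arterial
#' pulsatility ratio 0.80 and zero venous phase shift.
#'
#' @param ... named overrides of any parameter, either SI numerics or
#'   strings of the form `"value unit"` (e.g. `"10 um"`, `"5.63e6 um3.s/kg"`).
#' @param model model variant, `"one_vessel"` or `"two_vessel"`.
#'
#' @return An object of class `pvs_parameters`: a named list of SI values.
#'   Fields: `mu` (Pa s), `rho` (kg/m^3), `R_i`, `R_o`, `L_PVS`, `L_PCY`,
#'   `b`, `h`, `d`, `R_i_PCY`, `R_o_PCY`, `eta` (m), `f` (Hz),
#'   `wave_speed` (m/s), `theta` (rad), `xi`, `phi` (dimensionless),
#'   `K_PCY`, `K_PVS` (m^3 s/kg, identically m^2/(Pa s)), `D_star` (m^2/s),
#'   `T` (s, measurement interval, defaults to one pulse period `1/f`),
#'   `model`.
#' @examples
#' p <- pvs_parameters()
#' p$R_i                     # 1e-05
#' pvs_parameters(b = "0.1 um")$b
#' @export
pvs_parameters <- function(..., model = c("one_vessel", "two_vessel")) {
  model <- match.arg(model)
  load_parameters(list(...), model = model)
}

# parameter -> physical dimension, used to pick the unit table per key
.param_dimensions <- c(
  mu = "viscosity", rho = "density",
  R_i = "length", R_o = "length", L_PVS = "length", L_PCY = "length",
  b = "length", h = "length", d = "length",
  R_i_PCY = "length", R_o_PCY = "length", eta = "length",
  f = "frequency", wave_speed = "speed", theta = "angle",
  xi = "dimensionless", phi = "dimensionless",
  K_PCY = "conductivity", K_PVS = "conductivity",
  D_star = "diffusivity", T = "time"
)

# multiplicative factors to SI per dimension
.unit_tables <- list(
  length      = c(m = 1, mm = 1e-3, um = 1e-6, nm = 1e-9),
  time        = c(s = 1, ms = 1e-3),
  frequency   = c(Hz = 1),
  speed       = c("m/s" = 1, "mm/s" = 1e-3, "um/s" = 1e-6),
  viscosity   = c("Pa.s" = 1, "mPa.s" = 1e-3),
  density     = c("kg/m3" = 1),
  pressure    = c(Pa = 1, mPa = 1e-3, mmHg = 133.322387415),
  conductivity = c("m3.s/kg" = 1, "m2/(Pa.s)" = 1, "um3.s/kg" = 1e-18),
  diffusivity = c("m2/s" = 1, "um2/s" = 1e-12),
  angle       = c(rad = 1),
  dimensionless = c("1" = 1)
)

.normalize_unit <- function(unit) {
  u <- gsub("µ|μ", "u", unit)       # micro sign / Greek mu -> u
  u <- gsub("³", "3", u)
  u <- gsub("²", "2", u)
  u <- gsub("·|\\*| ", ".", u)
  u <- gsub("\\.+", ".", u)
  u
}

.parse_quantity <- function(value, dimension, key = "?") {
  if (is.numeric(value)) return(as.numeric(value))
  if (!is.character(value) || length(value) != 1L)
    stop("parameter '", key, "': expected a number or 'value unit' string",
         call. = FALSE)
  parts <- strsplit(trimws(value), "\\s+")[[1]]
  num <- suppressWarnings(as.numeric(parts[1]))
  if (is.na(num))
    stop("parameter '", key, "': cannot parse numeric value from '", value,
         "'", call. = FALSE)
  if (length(parts) == 1L) return(num)
  unit <- .normalize_unit(paste(parts[-1], collapse = ""))
  tab <- .unit_tables[[dimension]]
  if (!unit %in% names(tab))
    stop("parameter '", key, "': unrecognized ", dimension, " unit '",
         paste(parts[-1], collapse = " "), "'", call. = FALSE)
  num * tab[[unit]]
}

#' Convert a hydraulic conductivity to SI
#'
#' The SI unit m^3 s/kg and the equivalent m^2/(Pa s) are treated as
#' identical (Pa = kg m^-1 s^-2); values in um^3 s/kg are scaled by 1e-18.
#'
#' @param value numeric conductivity value.
#' @param unit one of `"um3.s/kg"`, `"m3.s/kg"`, `"m2/(Pa.s)"` (Unicode
#'   spellings such as `"μm³·s/kg"` are accepted).
#' @return conductivity in m^3 s/kg.
#' @examples
#' convert_conductivity(5.63e6, "um3.s/kg")   # 5.63e-12, the baseline K
#' @export
convert_conductivity <- function(value, unit) {
  stopifnot(is.numeric(value))
  u <- .normalize_unit(unit)
  tab <- .unit_tables$conductivity
  if (!u %in% names(tab))
    stop("unrecognized conductivity unit '", unit, "'", call. = FALSE)
  value * tab[[u]]
}

.baseline_defaults <- function() {
  list(
    mu = 0.9e-3, rho = 993.2,
    R_i = 10e-6, R_o = 30e-6, L_PVS = 300e-6, L_PCY = 200e-6,
    b = 0.25e-6, f = 5, wave_speed = 1,
    K_PCY = 5.63e-12, K_PVS = NA_real_,   # NA -> free-fluid-equivalent, see below
    phi = 0.2, D_star = 100e-12, eta = 60e-9,
    h = 100e-6, d = 200e-6,
    R_i_PCY = 10e-6, R_o_PCY = 300e-6,
    theta = 0, xi = 0.80,
    T = NA_real_                          # NA -> one pulse period 1/f
  )
}

#' Load and validate model parameters from a configuration
#'
#' Accepts either a named list or the path of a flat YAML file whose keys
#' are parameter names (see [pvs_parameters()]).  Values may be SI numbers
#' or `"value unit"` strings.  Unspecified keys take the baseline defaults.
#' All validation failures are collected and reported together.
#'
#' @param config named list or path to a YAML file; `NULL` or an empty list
#'   yields the baseline parameter set.
#' @param model model variant tag.
#' @return A `pvs_parameters` object (all values SI).
#' @export
load_parameters <- function(config = NULL,
                            model = c("one_vessel", "two_vessel")) {
  model <- match.arg(model)
  if (is.null(config)) config <- list()
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  if (!is.list(config)) stop("config must be a named list or a file path")
  defaults <- .baseline_defaults()
  if (!is.null(config$model)) {
    model <- match.arg(config$model, c("one_vessel", "two_vessel"))
    config$model <- NULL
  }
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  p <- defaults
  for (key in names(config))
    p[[key]] <- .parse_quantity(config[[key]], .param_dimensions[[key]], key)
  if (is.na(p$T)) p$T <- 1 / p$f
  if (is.na(p$K_PVS)) {
    # free-fluid-equivalent default; deferred to validation if the
    # annulus geometry itself is invalid
    p$K_PVS <- if (isTRUE(p$mu > 0 && p$R_i > 0 && p$R_i < p$R_o))
      free_fluid_equivalent_conductivity(p$mu, p$R_i, p$R_o) else 1
  }
  p$E <- p$R_i / p$R_o
  p$model <- model
  validate_parameters(p)
  structure(p, class = "pvs_parameters")
}

#' Validate a parameter set
#'
#' Checks every physical invariant (positivity, radius ordering,
#' porosity and pulsatility-ratio ranges, pulse amplitude smaller than the
#' inner radius, phase in [0, 2*pi)).  All violations are reported in a
#' single error.
#'
#' @param p named list of SI parameter values.
#' @return `p`, invisibly, if valid.
#' @export
validate_parameters <- function(p) {
  bad <- character()
  chk <- function(ok, msg) if (!isTRUE(ok)) bad <<- c(bad, msg)
  pos <- function(key) chk(is.numeric(p[[key]]) && is.finite(p[[key]]) &&
                             p[[key]] > 0, paste0(key, " must be > 0"))
  for (key in c("mu", "rho", "R_i", "R_o", "L_PVS", "L_PCY", "f",
                "wave_speed", "K_PCY", "K_PVS", "D_star", "eta", "h", "d",
                "R_i_PCY", "R_o_PCY", "T"))
    pos(key)
  chk(p$b >= 0, "b must be >= 0")
  chk(p$R_i < p$R_o, "R_i < R_o violated (annulus must have positive gap)")
  chk(p$b < p$R_i, "b < R_i violated (wall excursion exceeds inner radius)")
  chk(p$R_i_PCY < p$R_o_PCY, "R_i_PCY < R_o_PCY violated")
  chk(p$phi > 0 && p$phi < 1, "phi must lie in (0, 1)")
  chk(p$xi >= 0 && p$xi <= 1, "xi must lie in [0, 1]")
  chk(p$theta >= 0 && p$theta < 2 * pi, "theta must lie in [0, 2*pi)")
  if (length(bad))
    stop("invalid parameters:\n  - ", paste(bad, collapse = "\n  - "),
         call. = FALSE)
  invisible(p)
}

#' PVS hydraulic conductivity equivalent to a free fluid annulus
#'
#' Solves the porous-annulus resistance expression for the conductivity at
#' which it equals the free-fluid annular Poiseuille resistance of the same
#' geometry, i.e. the conductivity of "a free fluid cavity".
#'
#' @param mu dynamic viscosity (Pa s).
#' @param R_i,R_o annulus inner and outer radii (m).
#' @return conductivity (m^3 s/kg).
#' @export
free_fluid_equivalent_conductivity <- function(mu, R_i, R_o) {
  l <- 1
  R_free <- annular_poiseuille_resistance(mu, l, R_o, R_i / R_o)
  l / (pi * (R_o^2 - R_i^2) * R_free)
}

#' @export
print.pvs_parameters <- function(x, ...) {
  cat("Perivascular flow model parameters (", x$model, ", SI units)\n",
      sep = "")
  keys <- setdiff(names(x), "model")
  for (k in keys)
    cat(sprintf("  %-10s %g\n", k, x[[k]]))
  invisible(x)
}

#' Serialize parameters to a flat YAML configuration
#'
#' Writes all SI values; [load_parameters()] on the result reproduces the
#' parameter set exactly.
#'
#' @param p a `pvs_parameters` object.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(p, path) {
  stopifnot(inherits(p, "pvs_parameters"))
  out <- unclass(p)
  out$E <- NULL  # derived
  yaml::write_yaml(out, path, precision = 17)
  invisible(path)
}
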