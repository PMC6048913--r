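# Stable plain-text persistence: CSV time series and sweep tables, JSON
# run summaries.  Values are serialized at 9 significant digits; identical
# configurations reproduce byte-identical files.

.sig9 <- function(x) {
  if (is.list(x)) return(lapply(x, .sig9))
  if (is.numeric(x)) return(signif(x, 9))
  x
}

#' Validity diagnostics for a parameter set
#'
#' Collects the quantities that justify the modeling assumptions: the
#' Womersley number of the PVS gap (quasi-steady profile), the
#' wavelength:segment ratio (uniform wall motion), the linearization ratio
#' `b / R_i` (source waveform), and the maximal relative variation of the
#' free-fluid PVS resistance over the wall excursion (constant-resistance
#' solve).
#'
#' @param p a `pvs_parameters` object.
#' @return named list of diagnostics.
#' @export
run_diagnostics <- function(p) {
  R0 <- annular_poiseuille_resistance(p$mu, 1, p$R_o, p$R_i / p$R_o)
  dev <- if (p$b > 0) {
    max(vapply(c(p$R_i - p$b, p$R_i + p$b), function(ri)
      abs(annular_poiseuille_resistance(p$mu, 1, p$R_o, ri / p$R_o) - R0) /
        R0, 0))
  } else 0
  wl <- wavelength(p$wave_speed, p$f, p$L_PVS)
  list(
    womersley = womersley_number(p$R_i, p$R_o, p$f, p$rho, p$mu),
    wavelength = wl$wavelength,
    wavelength_ratio = wl$ratio,
    linearization_ratio = p$b / p$R_i,
    resistance_variation = dev)
}

#' Write a run report
#'
#' Persists a solved network as a deterministic JSON summary
#' (`summary.json`: parameter echo, topology digest, peak metrics, net
#' volumes, Peclet table, validity diagnostics) plus a CSV time series
#' (`timeseries.csv`: `t`, nodal pressures `p_*`, resistor flows `q_*`
#' and velocities `v_*`) and a human-readable topology file
#' (`topology.txt`).
#'
#' @param solution a solved network from [solve_period()].
#' @param dir output directory (created if missing).
#' @return named character vector of the files written, invisibly.
#' @export
write_report <- function(solution, dir) {
  stopifnot(inherits(solution, "pvs_solution"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  net <- solution$network
  p <- net$layout$params

  params <- unclass(p); params$E <- NULL
  topo <- lapply(net$resistors, function(r) list(
    label = r$label, from = r$from, to = r$to, kind = r$element$kind,
    length = r$element$l, resistance = r$element$R,
    half_annulus = r$element$half_annulus))
  srcs <- lapply(net$sources, function(s) list(
    label = s$label, node = s$node, l = s$source$l, b = s$source$b,
    f = s$source$f, theta = s$source$theta, geometry = s$source$geometry))

  summary <- list(
    model = net$layout$model,
    porous_pvs = net$layout$porous_pvs,
    n_samples = solution$n_samples,
    period = solution$period,
    parameters = params,
    resistors = topo,
    sources = srcs,
    peaks = list(
      pressure = max(solution$node_peaks$peak_pressure),
      node_pressures = stats::setNames(
        as.list(solution$node_peaks$peak_pressure),
        solution$node_peaks$node),
      element_velocities = stats::setNames(
        as.list(solution$peaks$peak_velocity), solution$peaks$label),
      element_flows = stats::setNames(
        as.list(solution$peaks$peak_flow), solution$peaks$label)),
    net_volumes = as.list(solution$net_volume),
    peclet = {
      pt <- peclet_table(solution)
      .sig9(unname(split(pt, seq_len(nrow(pt)))))
    },
    diagnostics = run_diagnostics(p))
  summary <- .sig9(summary)
  json_path <- file.path(dir, "summary.json")
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  ts <- data.frame(t = signif(solution$times, 9))
  for (id in rownames(solution$pressures))
    ts[[paste0("p_", id)]] <- signif(solution$pressures[id, ], 9)
  for (lb in rownames(solution$flows)) {
    ts[[paste0("q_", lb)]] <- signif(solution$flows[lb, ], 9)
    ts[[paste0("v_", lb)]] <- signif(solution$velocities[lb, ], 9)
  }
  csv_path <- file.path(dir, "timeseries.csv")
  utils::write.csv(ts, csv_path, row.names = FALSE)

  topo_path <- file.path(dir, "topology.txt")
  write_topology(net, topo_path)

  invisible(c(summary = json_path, timeseries = csv_path,
              topology = topo_path))
}

#' Write a human-readable network topology file
#'
#' One line per node, resistor and source, so alternative reconstructions
#' of the printed network figures can be reviewed or swapped without code
#' changes.
#'
#' @param network a [hydraulic_network()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_topology <- function(network, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# model: %s", network$layout$model %||% "custom"), con)
  writeLines("# nodes: id grounded", con)
  for (i in seq_len(nrow(network$nodes)))
    writeLines(sprintf("node %s %s", network$nodes$id[i],
                       network$nodes$grounded[i]), con)
  writeLines("# resistors: label from to kind length_m resistance_Pa.s.m-3",
             con)
  for (r in network$resistors)
    writeLines(sprintf("resistor %s %s %s %s %s %s", r$label, r$from, r$to,
                       r$element$kind, format(r$element$l),
                       format(signif(r$element$R, 9))), con)
  writeLines("# sources: label node l_m b_m f_Hz theta_rad geometry", con)
  for (s in network$sources)
    writeLines(sprintf("source %s %s %s %s %s %s %s", s$label, s$node,
                       format(s$source$l), format(s$source$b),
                       format(s$source$f), format(s$source$theta),
                       s$source$geometry), con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rebuild parameters from a written report
#'
#' Reads `summary.json` back into a `pvs_parameters` object so a run can
#' be reproduced from its own report.
#'
#' @param dir directory holding a report written by [write_report()].
#' @return a `pvs_parameters` object.
#' @export
parameters_from_report <- function(dir) {
  s <- jsonlite::read_json(file.path(dir, "summary.json"),
                           simplifyVector = TRUE)
  cfg <- as.list(s$parameters)
  cfg$T <- NULL  # re-derived from f
  load_parameters(cfg, model = s$model)
}

#' Write a sweep table to CSV
#'
#' @param sweep a `pvs_sweep` data.frame from [run_sweep()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(sweep, path) {
  out <- as.data.frame(lapply(sweep, function(col)
    if (is.numeric(col)) signif(col, 9) else col))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
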