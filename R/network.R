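# Linear hydraulic network: nodes, resistors obeying dp = R q, and
# pulsatile volumetric sources.  Grounded nodes are pressure references
# (p = 0) where fluid exits the modeled domain; the reduced nodal
# conductance system over the remaining nodes is symmetric positive
# definite and is solved quasi-statically at each time sample (no inertia:
# the small Womersley number justifies the steady profile per instant).

#' Construct a hydraulic network
#'
#' @param nodes data.frame with columns `id` (character) and `grounded`
#'   (logical).  At least one node per connected component must be
#'   grounded.
#' @param resistors list of entries `list(label, from, to, element)` where
#'   `element` is a [resistance_element()] and `from`/`to` are node ids
#'   (positive flow runs from `from` to `to`).
#' @param sources list of entries `list(label, node, source)` where
#'   `source` is a [pulsatile_source()].
#' @param layout optional free-form annotation (kept in reports).
#' @return object of class `hydraulic_network`.
#' @export
hydraulic_network <- function(nodes, resistors, sources, layout = NULL) {
  stopifnot(is.data.frame(nodes), all(c("id", "grounded") %in% names(nodes)))
  nodes$id <- as.character(nodes$id)
  if (anyDuplicated(nodes$id)) stop("duplicate node ids")
  if (!any(nodes$grounded)) stop("network has no grounded node")
  for (r in resistors) {
    if (!all(c(r$from, r$to) %in% nodes$id))
      stop("resistor ", r$label, " references unknown node")
    if (identical(r$from, r$to))
      stop("resistor ", r$label, " has identical endpoints")
    if (!inherits(r$element, "resistance_element"))
      stop("resistor ", r$label, " lacks a resistance element")
    if (r$element$R <= 0)
      stop("resistor ", r$label, " has non-positive resistance")
  }
  for (s in sources) {
    if (!s$node %in% nodes$id)
      stop("source ", s$label, " attached to unknown node ", s$node)
    if (!inherits(s$source, "pulsatile_source"))
      stop("source ", s$label, " is not a pulsatile_source")
  }
  net <- structure(list(nodes = nodes, resistors = resistors,
                        sources = sources, layout = layout),
                   class = "hydraulic_network")
  .check_grounded_connectivity(net)
  net
}

.check_grounded_connectivity <- function(net) {
  ids <- net$nodes$id
  reached <- stats::setNames(net$nodes$grounded, ids)
  adj <- lapply(stats::setNames(vector("list", length(ids)), ids), identity)
  for (r in net$resistors) {
    adj[[r$from]] <- c(adj[[r$from]], r$to)
    adj[[r$to]] <- c(adj[[r$to]], r$from)
  }
  frontier <- ids[reached]
  while (length(frontier)) {
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[!reached[nxt]]
    reached[nxt] <- TRUE
    frontier <- nxt
  }
  if (!all(reached))
    stop("floating node(s) not connected to any grounded boundary: ",
         paste(ids[!reached], collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' Assemble the reduced nodal conductance system
#'
#' Standard nodal analysis of `dp = R q`: grounded nodes are eliminated at
#' p = 0 and each resistor contributes its conductance `1/R` to the
#' remaining symmetric positive-definite matrix.
#'
#' @param network a [hydraulic_network()].
#' @return list with `G` (conductance matrix, free nodes), `free`
#'   (free node ids) and `chol` (Cholesky factor used by the solver).
#' @export
assemble_conductance <- function(network) {
  free <- network$nodes$id[!network$nodes$grounded]
  n <- length(free)
  idx <- stats::setNames(seq_len(n), free)
  G <- matrix(0, n, n, dimnames = list(free, free))
  for (r in network$resistors) {
    g <- 1 / r$element$R
    fi <- idx[r$from]; ti <- idx[r$to]
    if (!is.na(fi)) G[fi, fi] <- G[fi, fi] + g
    if (!is.na(ti)) G[ti, ti] <- G[ti, ti] + g
    if (!is.na(fi) && !is.na(ti)) {
      G[fi, ti] <- G[fi, ti] - g
      G[ti, fi] <- G[ti, fi] - g
    }
  }
  ch <- tryCatch(chol(G), error = function(e)
    stop("singular conductance matrix (floating nodes?): ",
         conditionMessage(e), call. = FALSE))
  list(G = G, free = free, chol = ch)
}

#' Solve a network over one pulse period
#'
#' Samples one period of the shared source frequency on `n_samples + 1`
#' equispaced instants (both endpoints included so period integrals
#' close), solves the quasi-static nodal system at each instant, and
#' derives resistor flows, superficial velocities, per-element peak
#' metrics and net displaced volumes.
#'
#' @param network a [hydraulic_network()].
#' @param n_samples samples per period (default 256; peaks change by
#'   < 0.1% on doubling).
#' @return object of class `pvs_solution`: `times` (s), `pressures`
#'   (node x time matrix, Pa; grounded rows identically 0), `flows` and
#'   `velocities` (resistor x time matrices, m^3/s and m/s), `peaks`
#'   (data.frame of per-element peak |v|, |q|, and per-node peak |p|),
#'   `net_volume` (named vector, m^3 over the period), `period` (s).
#' @export
solve_period <- function(network, n_samples = 256) {
  stopifnot(inherits(network, "hydraulic_network"), n_samples >= 16)
  if (!length(network$sources)) stop("network has no sources")
  f <- unique(vapply(network$sources, function(s) s$source$f, 0))
  if (length(f) != 1L)
    stop("sources must share one pulse frequency for a period solve")
  period <- 1 / f
  times <- seq(0, period, length.out = n_samples + 1L)

  sys <- assemble_conductance(network)
  free <- sys$free
  nt <- length(times)

  S <- matrix(0, length(free), nt, dimnames = list(free, NULL))
  for (s in network$sources) {
    if (!s$node %in% free)
      next  # source into a grounded node leaves the free system unchanged
    S[s$node, ] <- S[s$node, ] + source_rate(s$source, times)
  }
  # p = G^-1 S via the Cholesky factor
  P_free <- backsolve(sys$chol, forwardsolve(t(sys$chol), S))
  dimnames(P_free) <- list(free, NULL)

  ids <- network$nodes$id
  P <- matrix(0, length(ids), nt, dimnames = list(ids, NULL))
  P[free, ] <- P_free

  labels <- vapply(network$resistors, function(r) r$label, "")
  Q <- matrix(0, length(labels), nt, dimnames = list(labels, NULL))
  V <- Q
  for (k in seq_along(network$resistors)) {
    r <- network$resistors[[k]]
    Q[k, ] <- (P[r$from, ] - P[r$to, ]) / r$element$R
    V[k, ] <- Q[k, ] / r$element$velocity_area
  }

  dt <- diff(times)
  trapz <- function(y) sum(dt * (y[-length(y)] + y[-1]) / 2)
  net_volume <- apply(Q, 1, trapz)

  peaks <- data.frame(
    label = labels,
    kind = vapply(network$resistors, function(r) r$element$kind, ""),
    peak_flow = apply(abs(Q), 1, max),
    peak_velocity = apply(abs(V), 1, max),
    row.names = NULL, stringsAsFactors = FALSE)
  node_peaks <- data.frame(
    node = ids,
    grounded = network$nodes$grounded,
    peak_pressure = apply(abs(P), 1, max),
    row.names = NULL, stringsAsFactors = FALSE)

  structure(list(times = times, pressures = P, flows = Q, velocities = V,
                 peaks = peaks, node_peaks = node_peaks,
                 net_volume = net_volume, period = period,
                 n_samples = n_samples, network = network),
            class = "pvs_solution")
}

#' Superficial velocity through an element
#'
#' Converts a resistor's volumetric flow to superficial (Darcy) velocity.
#' For radial-shell parenchyma elements the conversion section
#' \eqn{2 \pi r h} depends on the evaluation radius, so the velocity can be
#' reported at any radial distance from the PVS outer boundary; for all
#' other kinds the element's fixed conversion section applies.
#'
#' @param solution a solved network from [solve_period()].
#' @param label resistor label.
#' @param radius optional evaluation radius (m) for radial shells; must
#'   lie in `[R_i_PCY, R_o_PCY]`.
#' @param distance alternative to `radius`: distance (m) beyond the PVS
#'   outer boundary (the element's default evaluation radius).
#' @param peak logical; return the peak of |v| over the period (default)
#'   instead of the full time series.
#' @return velocity in m/s (scalar peak or vector over `solution$times`).
#' @export
element_velocity <- function(solution, label, radius = NULL,
                             distance = NULL, peak = TRUE) {
  stopifnot(inherits(solution, "pvs_solution"))
  k <- match(label, rownames(solution$flows))
  if (is.na(k)) stop("unknown resistor label ", label)
  el <- solution$network$resistors[[k]]$element
  area <- el$velocity_area
  if (el$kind == "radial_shell" && (!is.null(radius) || !is.null(distance))) {
    r <- if (!is.null(radius)) radius else el$eval_radius + distance
    if (r < el$R_i_PCY || r > el$R_o_PCY)
      stop("evaluation radius outside the parenchyma shell [",
           el$R_i_PCY, ", ", el$R_o_PCY, "] m")
    area <- 2 * pi * r * el$h
  } else if (!is.null(radius) || !is.null(distance)) {
    stop("radius/distance apply only to radial_shell elements")
  }
  v <- solution$flows[k, ] / area
  if (peak) max(abs(v)) else v
}

#' Net displaced volume through a resistor over one period
#'
#' Trapezoidal time integral of the flow over the solved period.  For the
#' sinusoidal sources of these models the net volume vanishes (oscillatory
#' motion, no net flow).
#'
#' @param solution a solved network.
#' @param label resistor label.
#' @return net volume (m^3).
#' @export
net_flow <- function(solution, label) {
  stopifnot(inherits(solution, "pvs_solution"))
  if (!label %in% names(solution$net_volume))
    stop("unknown resistor label ", label)
  solution$net_volume[[label]]
}

#' Mass-conservation residual of a solved network
#'
#' Maximum over free nodes and time samples of the absolute Kirchhoff
#' residual (sum of resistor flows minus source inflow), normalized by the
#' peak source magnitude.
#'
#' @param solution a solved network.
#' @return dimensionless relative residual.
#' @export
kirchhoff_residual <- function(solution) {
  net <- solution$network
  times <- solution$times
  free <- net$nodes$id[!net$nodes$grounded]
  resid <- matrix(0, length(free), length(times),
                  dimnames = list(free, NULL))
  for (k in seq_along(net$resistors)) {
    r <- net$resistors[[k]]
    if (r$from %in% free)
      resid[r$from, ] <- resid[r$from, ] + solution$flows[k, ]
    if (r$to %in% free)
      resid[r$to, ] <- resid[r$to, ] - solution$flows[k, ]
  }
  smax <- 0
  for (s in net$sources) {
    q <- source_rate(s$source, times)
    smax <- max(smax, max(abs(q)))
    if (s$node %in% free) resid[s$node, ] <- resid[s$node, ] - q
  }
  if (smax == 0) return(max(abs(resid)))
  max(abs(resid)) / smax
}

#' @export
print.hydraulic_network <- function(x, ...) {
  cat("Hydraulic network: ", nrow(x$nodes), " nodes (",
      sum(x$nodes$grounded), " grounded), ", length(x$resistors),
      " resistors, ", length(x$sources), " sources\n", sep = "")
  invisible(x)
}

#' @export
print.pvs_solution <- function(x, ...) {
  cat("Solved hydraulic network over one period (", x$period, " s, ",
      x$n_samples, " samples)\n", sep = "")
  cat(sprintf("  peak |pressure|: %.4g Pa\n", max(x$node_peaks$peak_pressure)))
  cat(sprintf("  peak |velocity|: %.4g m/s (%s)\n",
              max(x$peaks$peak_velocity),
              x$peaks$label[which.max(x$peaks$peak_velocity)]))
  cat(sprintf("  max |net volume|: %.3g m^3\n", max(abs(x$net_volume))))
  invisible(x)
}
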