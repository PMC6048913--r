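# Builders for the two model networks.
#
# One-vessel model: a 300 um arteriole segment.  Axial PVS chain
# R1(50 um) - R2(100) - R3(100) - R4(50) with both ends grounded (fluid
# leaves axially); three interior nodes n1..n3 each carry a volumetric
# source IA1..IA3 (l = 100 um) and a radial parenchyma shell resistor
# R5..R7 to ground (fluid leaves radially).
#
# Two-vessel model: a planar cortical slice holding an arteriole and a
# vein 200 um apart, 25 resistors.  Four grounded-top-and-bottom columns
# (arterial half-PVS, parenchyma at 50 um, parenchyma at 150 um, venous
# half-PVS) of lengths 50/100/100/50 um, bridged by three horizontal
# parenchyma rows (50 + 100 + 50 um) at the source nodes.  Numbered
# row-wise this reproduces the published element-length inventory exactly:
# R6, R8-R11, R13, R15-R18 and R20 are the eleven 100 um elements, all
# others are 50 um.  PVS elements model half the annulus (doubled
# resistance); arterial sources emit half the displaced volume, venous
# sources additionally carry amplitude xi*b and phase theta.

#' Build the one-vessel hydraulic network
#'
#' @param params a `pvs_parameters` object (see [pvs_parameters()]).
#' @param porous_pvs logical; model the PVS as rigid porous media
#'   (axial Darcy annulus with conductivity `K_PVS`) instead of a free
#'   fluid annulus.
#' @param mode source waveform mode, `"linearized"` (default) or
#'   `"exact"`.
#' @return a [hydraulic_network()] with 7 resistors (R1-R7) and 3 sources
#'   (IA1-IA3).
#' @export
build_one_vessel <- function(params, porous_pvs = FALSE,
                             mode = "linearized") {
  p <- validate_parameters(params)
  pvs_kind <- if (porous_pvs) "annular_porous" else "annular_free"
  pvs <- function(l) resistance_element(pvs_kind, p, l = l)
  shell <- function() resistance_element("radial_shell", p)

  nodes <- data.frame(id = c("GND", "n1", "n2", "n3"),
                      grounded = c(TRUE, FALSE, FALSE, FALSE))
  res <- list(
    list(label = "R1", from = "n1", to = "GND", element = pvs(50e-6),
         meta = list(orientation = "axial")),
    list(label = "R2", from = "n2", to = "n1", element = pvs(100e-6),
         meta = list(orientation = "axial")),
    list(label = "R3", from = "n2", to = "n3", element = pvs(100e-6),
         meta = list(orientation = "axial")),
    list(label = "R4", from = "n3", to = "GND", element = pvs(50e-6),
         meta = list(orientation = "axial")),
    list(label = "R5", from = "n1", to = "GND", element = shell(),
         meta = list(orientation = "radial")),
    list(label = "R6", from = "n2", to = "GND", element = shell(),
         meta = list(orientation = "radial")),
    list(label = "R7", from = "n3", to = "GND", element = shell(),
         meta = list(orientation = "radial")))
  src <- function(label, node) list(
    label = label, node = node,
    source = pulsatile_source(100e-6, p$R_i, p$b, p$f, theta = 0,
                              geometry = "full", mode = mode))
  sources <- list(src("IA1", "n1"), src("IA2", "n2"), src("IA3", "n3"))
  hydraulic_network(nodes, res, sources,
                    layout = list(model = "one_vessel",
                                  porous_pvs = porous_pvs, params = p))
}

#' Build the two-vessel hydraulic network
#'
#' @inheritParams build_one_vessel
#' @return a [hydraulic_network()] with 25 resistors (R1-R25), arterial
#'   sources IA1-IA3 and venous sources IV1-IV3 (amplitude `xi * b`, phase
#'   `theta`).
#' @export
build_two_vessel <- function(params, porous_pvs = FALSE,
                             mode = "linearized") {
  p <- validate_parameters(params)
  pvs_kind <- if (porous_pvs) "annular_porous" else "annular_free"
  pvs <- function(l) resistance_element(pvs_kind, p, l = l,
                                        half_annulus = TRUE)
  slab <- function(l) resistance_element("darcy_slab", p, l = l)

  ids <- c("a1", "a2", "a3", "p1", "p2", "p3", "q1", "q2", "q3",
           "v1", "v2", "v3")
  nodes <- data.frame(id = c("GND", ids),
                      grounded = c(TRUE, rep(FALSE, length(ids))))

  # x: distance of a column from the arterial vessel axis (vein at L_PCY)
  xa <- 0; xp <- 50e-6; xq <- 150e-6; xv <- p$L_PCY
  R <- function(label, from, to, element, x_mid, orientation)
    list(label = label, from = from, to = to, element = element,
         meta = list(x_mid = x_mid, orientation = orientation))
  res <- list(
    # top boundary column elements
    R("R1",  "a1", "GND", pvs(50e-6),  xa, "axial"),
    R("R2",  "p1", "GND", slab(50e-6), xp, "parallel"),
    R("R3",  "q1", "GND", slab(50e-6), xq, "parallel"),
    R("R4",  "v1", "GND", pvs(50e-6),  xv, "axial"),
    # row 1 (horizontal, perpendicular to the vessels)
    R("R5",  "a1", "p1", slab(50e-6),  (xa + xp) / 2, "perpendicular"),
    R("R6",  "p1", "q1", slab(100e-6), (xp + xq) / 2, "perpendicular"),
    R("R7",  "q1", "v1", slab(50e-6),  (xq + xv) / 2, "perpendicular"),
    # verticals between rows 1 and 2
    R("R8",  "a2", "a1", pvs(100e-6),  xa, "axial"),
    R("R9",  "p2", "p1", slab(100e-6), xp, "parallel"),
    R("R10", "q2", "q1", slab(100e-6), xq, "parallel"),
    R("R11", "v2", "v1", pvs(100e-6),  xv, "axial"),
    # row 2 (center)
    R("R12", "a2", "p2", slab(50e-6),  (xa + xp) / 2, "perpendicular"),
    R("R13", "p2", "q2", slab(100e-6), (xp + xq) / 2, "perpendicular"),
    R("R14", "q2", "v2", slab(50e-6),  (xq + xv) / 2, "perpendicular"),
    # verticals between rows 2 and 3
    R("R15", "a2", "a3", pvs(100e-6),  xa, "axial"),
    R("R16", "p2", "p3", slab(100e-6), xp, "parallel"),
    R("R17", "q2", "q3", slab(100e-6), xq, "parallel"),
    R("R18", "v2", "v3", pvs(100e-6),  xv, "axial"),
    # row 3
    R("R19", "a3", "p3", slab(50e-6),  (xa + xp) / 2, "perpendicular"),
    R("R20", "p3", "q3", slab(100e-6), (xp + xq) / 2, "perpendicular"),
    R("R21", "q3", "v3", slab(50e-6),  (xq + xv) / 2, "perpendicular"),
    # bottom boundary column elements
    R("R22", "a3", "GND", pvs(50e-6),  xa, "axial"),
    R("R23", "p3", "GND", slab(50e-6), xp, "parallel"),
    R("R24", "q3", "GND", slab(50e-6), xq, "parallel"),
    R("R25", "v3", "GND", pvs(50e-6),  xv, "axial"))

  b_ven <- venous_amplitude(p$b, p$xi)
  art <- function(label, node) list(
    label = label, node = node,
    source = pulsatile_source(100e-6, p$R_i, p$b, p$f, theta = 0,
                              geometry = "half", mode = mode))
  ven <- function(label, node) list(
    label = label, node = node,
    source = pulsatile_source(100e-6, p$R_i, b_ven, p$f,
                              theta = p$theta, geometry = "half",
                              mode = mode))
  sources <- list(art("IA1", "a1"), art("IA2", "a2"), art("IA3", "a3"),
                  ven("IV1", "v1"), ven("IV2", "v2"), ven("IV3", "v3"))
  hydraulic_network(nodes, res, sources,
                    layout = list(model = "two_vessel",
                                  porous_pvs = porous_pvs, params = p))
}

#' Select parenchyma elements by distance from the arterial PVS
#'
#' Returns the labels of two-vessel parenchyma slab elements whose
#' midpoint lies within a band of distances from the arterial PVS outer
#' boundary, optionally filtered by orientation relative to the vessels.
#'
#' @param network a two-vessel [hydraulic_network()].
#' @param min_dist,max_dist band limits (m), measured from the arterial
#'   PVS outer radius.
#' @param orientation `"perpendicular"`, `"parallel"`, or `"both"`.
#' @return character vector of resistor labels.
#' @export
parenchyma_elements <- function(network, min_dist = 50e-6,
                                max_dist = 150e-6,
                                orientation = c("both", "perpendicular",
                                                "parallel")) {
  orientation <- match.arg(orientation)
  R_o <- network$layout$params$R_o
  keep <- vapply(network$resistors, function(r) {
    if (r$element$kind != "darcy_slab") return(FALSE)
    if (orientation != "both" && r$meta$orientation != orientation)
      return(FALSE)
    d <- r$meta$x_mid - R_o
    d >= min_dist && d <= max_dist
  }, TRUE)
  vapply(network$resistors[keep], function(r) r$label, "")
}

#' Build a model network by name
#'
#' @param params a `pvs_parameters` object.
#' @param model `"one_vessel"` or `"two_vessel"` (defaults to the tag in
#'   `params`).
#' @param ... passed to the underlying builder.
#' @return a [hydraulic_network()].
#' @export
build_model <- function(params, model = params$model, ...) {
  switch(match.arg(model, c("one_vessel", "two_vessel")),
         one_vessel = build_one_vessel(params, ...),
         two_vessel = build_two_vessel(params, ...))
}
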