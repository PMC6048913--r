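make_element <- function(R, area = 1e-9) {
  structure(list(R = R, area = area, velocity_area = area,
                 kind = "annular_free", l = NA_real_,
                 half_annulus = FALSE),
            class = "resistance_element")
}

make_source <- function(...) pulsatile_source(...)

test_that("nodal assembly reproduces hand-eliminated small systems", {
  # single resistor between one free node and ground: 1x1 system [1/R]
  nodes <- data.frame(id = c("GND", "x"), grounded = c(TRUE, FALSE))
  net <- hydraulic_network(
    nodes,
    list(list(label = "Ra", from = "x", to = "GND",
              element = make_element(2e12))),
    list(list(label = "S", node = "x",
              source = make_source(1e-4, 1e-5, 1e-7, 5))))
  sys <- assemble_conductance(net)
  expect_equal(dim(sys$G), c(1L, 1L))
  expect_equal(sys$G[1, 1], 1 / 2e12)

  # two equal resistors in series to ground: p_y = 2 R q, p_x = R q
  nodes <- data.frame(id = c("GND", "x", "y"),
                      grounded = c(TRUE, FALSE, FALSE))
  R <- 3e12
  net2 <- hydraulic_network(
    nodes,
    list(list(label = "Ra", from = "y", to = "x", element = make_element(R)),
         list(label = "Rb", from = "x", to = "GND",
              element = make_element(R))),
    list(list(label = "S", node = "y",
              source = make_source(1e-4, 1e-5, 1e-7, 5))))
  sol <- solve_period(net2, n_samples = 64)
  qpk <- 4 * pi^2 * 1e-4 * 5 * 1e-7 * 1e-5
  k <- which.max(sol$pressures["y", ])
  q_at_peak <- unname(sol$flows["Ra", k])
  expect_equal(unname(sol$pressures["y", k]), 2 * R * q_at_peak,
               tolerance = 1e-12)
  expect_equal(unname(sol$pressures["x", k]), R * q_at_peak,
               tolerance = 1e-12)
  expect_equal(max(abs(sol$flows["Ra", ])), qpk, tolerance = 1e-3)
})

test_that("one-vessel solve matches the hand-derived symmetric chain", {
  p <- baseline_params()
  sol <- solve_period(build_one_vessel(p), n_samples = 256)
  g_end <- 1 / annular_poiseuille_resistance(p$mu, 50e-6, p$R_o, p$E)
  g_mid <- 1 / annular_poiseuille_resistance(p$mu, 100e-6, p$R_o, p$E)
  g_sh <- 1 / radial_shell_resistance(p$K_PCY, p$h, p$R_i_PCY, p$R_o_PCY)
  qpk <- 4 * pi^2 * 100e-6 * p$f * p$b * p$R_i
  expected <- oracle_chain_pressures(g_end, g_mid, g_sh, qpk)
  k <- which.max(sol$pressures["n2", ])  # sources in phase: common peak
  expect_equal(unname(sol$pressures[c("n1", "n2", "n3"), k]),
               unname(expected), tolerance = 1e-6)
})

test_that("mass is conserved at every free node and every sample", {
  for (build in list(build_one_vessel, build_two_vessel)) {
    sol <- solve_period(build(baseline_params()), n_samples = 64)
    expect_lt(kirchhoff_residual(sol), 1e-10)
  }
})

test_that("the resistive network responds linearly to its sources", {
  p1 <- baseline_params()
  p2 <- baseline_params(b = 2 * p1$b)
  s1 <- solve_period(build_one_vessel(p1), n_samples = 64)
  s2 <- solve_period(build_one_vessel(p2), n_samples = 64)
  expect_equal(s2$pressures, 2 * s1$pressures, tolerance = 1e-12)
  expect_equal(s2$velocities, 2 * s1$velocities, tolerance = 1e-12)

  # superposition: arterial-only + venous-only = both (two-vessel)
  full <- build_two_vessel(baseline_params(model = "two_vessel"))
  zero_sources <- function(net, labels) {
    net$sources <- lapply(net$sources, function(s) {
      if (s$label %in% labels) {
        s$source <- pulsatile_source(s$source$l, s$source$R_i, 0,
                                     s$source$f, theta = s$source$theta,
                                     geometry = s$source$geometry)
      }
      s
    })
    net
  }
  art <- zero_sources(full, c("IV1", "IV2", "IV3"))
  ven <- zero_sources(full, c("IA1", "IA2", "IA3"))
  sf <- solve_period(full, n_samples = 64)
  sa <- solve_period(art, n_samples = 64)
  sv <- solve_period(ven, n_samples = 64)
  expect_equal(sf$pressures, sa$pressures + sv$pressures, tolerance = 1e-10)
})

test_that("quiescent sources produce a quiescent network", {
  sol <- solve_period(build_one_vessel(baseline_params(b = 0)),
                      n_samples = 64)
  expect_true(all(sol$pressures == 0))
  expect_true(all(sol$flows == 0))
  expect_true(all(sol$peaks$peak_velocity == 0))
})

test_that("one-vessel baseline is mirror-symmetric about the center node", {
  sol <- solve_period(build_one_vessel(baseline_params()), n_samples = 128)
  expect_equal(sol$pressures["n1", ], sol$pressures["n3", ],
               tolerance = 1e-12)
  expect_equal(abs(sol$velocities["R1", ]), abs(sol$velocities["R4", ]),
               tolerance = 1e-12)
})

test_that("oscillatory flow carries no net volume over a full period", {
  sol <- solve_period(build_one_vessel(baseline_params()), n_samples = 256)
  bound <- 1e-9 * max(sol$peaks$peak_flow) * sol$period
  for (lb in sol$peaks$label)
    expect_lt(abs(net_flow(sol, lb)), bound)
  # ... but the half-period integral is decidedly non-zero (oscillation)
  half <- seq_len(length(sol$times) %/% 2)
  q <- sol$flows["R1", half]
  dt <- diff(sol$times[half])
  half_vol <- sum(dt * (q[-length(q)] + q[-1]) / 2)
  expect_gt(abs(half_vol), 1e3 * bound)
})

test_that("radial-shell velocities can be evaluated at any shell radius", {
  p <- baseline_params()
  sol <- solve_period(build_one_vessel(p), n_samples = 64)
  v_inner <- element_velocity(sol, "R6", radius = p$R_o)
  v_default <- element_velocity(sol, "R6")
  expect_identical(v_inner, v_default)
  # superficial velocity falls off as 1/r through the cylindrical shell
  v_out <- element_velocity(sol, "R6", distance = 50e-6)
  expect_equal(v_out, v_inner * p$R_o / (p$R_o + 50e-6), tolerance = 1e-12)
  expect_error(element_velocity(sol, "R6", radius = 1e-6), "outside")
  expect_error(element_velocity(sol, "R1", radius = 1e-5), "radial_shell")
})

test_that("floating nodes are rejected by name", {
  nodes <- data.frame(id = c("GND", "x", "orphan"),
                      grounded = c(TRUE, FALSE, FALSE))
  expect_error(hydraulic_network(
    nodes,
    list(list(label = "Ra", from = "x", to = "GND",
              element = make_element(1e12))),
    list()), "orphan")
})

test_that("peak metrics are insensitive to time resolution", {
  s256 <- solve_period(build_two_vessel(baseline_params()), n_samples = 256)
  s512 <- solve_period(build_two_vessel(baseline_params()), n_samples = 512)
  expect_equal(s512$peaks$peak_velocity, s256$peaks$peak_velocity,
               tolerance = 1e-3)
  rel <- abs(max(s512$node_peaks$peak_pressure) -
               max(s256$node_peaks$peak_pressure)) /
    max(s512$node_peaks$peak_pressure)
  expect_lt(rel, 1e-3)
})
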