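# Independent numerical oracles used to check the closed-form physics.

# Annular Poiseuille resistance by quadrature of the velocity profile.
# For axial pressure gradient G the profile is
#   u(r) = G/(4 mu) * [Ro^2 - r^2 - (Ro^2 - Ri^2) * ln(Ro/r) / ln(Ro/Ri)]
# and R = dp / q = G l / integral(2 pi r u).
oracle_annulus_resistance <- function(mu, l, R_o, R_i) {
  u <- function(r)
    (1 / (4 * mu)) * (R_o^2 - r^2 -
                        (R_o^2 - R_i^2) * log(R_o / r) / log(R_o / R_i))
  q <- stats::integrate(function(r) 2 * pi * r * u(r), R_i, R_o,
                        rel.tol = 1e-12, abs.tol = 0)$value
  l / q
}

# Radial Darcy shell resistance by a 1-D finite-volume discretization:
# n concentric shells in series, each approximated by dr / (2 pi r_mid h K).
oracle_radial_shell_resistance <- function(K, h, R_i, R_o, n = 1e4) {
  r <- seq(R_i, R_o, length.out = n + 1)
  rm <- (r[-1] + r[-(n + 1)]) / 2
  sum(diff(r) / (2 * pi * rm * h * K))
}

# Hand nodal analysis of the symmetric one-vessel chain: interior nodes
# n1, n2, n3 with end conductance g_end (n1, n3 to ground), axial g_mid
# (n1-n2, n2-n3) and radial shunt g_sh per node; equal source q at each
# node.  Symmetry gives p1 = p3; two equations eliminated by hand.
oracle_chain_pressures <- function(g_end, g_mid, g_sh, q) {
  a <- g_end + g_mid + g_sh
  b <- g_mid
  cc <- 2 * g_mid + g_sh
  p1 <- q * (1 + b / cc) / (a - 2 * b^2 / cc)
  p2 <- (q + 2 * b * p1) / cc
  c(n1 = p1, n2 = p2, n3 = p1)
}

# Peak displaced-volume rate by centered finite differences of
# V(t) = pi l r_i(t)^2 on a fine grid.
oracle_source_peak <- function(l, R_i, b, f, n = 2e5) {
  t <- seq(0, 1 / f, length.out = n)
  ri <- R_i - b * cos(2 * pi * f * t)
  V <- pi * l * ri^2
  dt <- t[2] - t[1]
  max(abs((V[-(1:2)] - V[1:(n - 2)]) / (2 * dt)))
}

baseline_params <- function(...) pvs_parameters(...)

arterial_pvs_labels <- c("R1", "R8", "R15", "R22")
venous_pvs_labels <- c("R4", "R11", "R18", "R25")
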