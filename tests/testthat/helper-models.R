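# Shared fixtures, built in code.

# reference operating point: mild steady inspiration
Q0_REF <- 2.67e-4   # m^3/s (about 16 l/min)
DP0_REF <- 24.45    # Pa
P0_REF <- Q0_REF * DP0_REF  # 6.528e-3 W

# degenerate single-duct networks with closed-form steady states
net_linear <- function(R0 = DP0_REF / Q0_REF) airway_network_single(R0, 0)
net_quadratic <- function(b = DP0_REF / Q0_REF^2) airway_network_single(0, b)

# a small straight-channel duct configuration with Q_exact = 1 under CPG 1.2
duct_straight <- function(ny = 32, nx = 16) {
  duct_geometry(L = 2, H = 1, nx = nx, ny = ny)
}
duct_cfg <- function(...) {
  args <- utils::modifyList(
    list(rho = 1, nu = 0.05, window = 60, discard_fraction = 0.3,
         steady_tol = 1e-7, max_steps = 200000L),
    list(...))
  do.call(solver_config, args)
}
poiseuille_Q <- function(dp, H = 1, rho = 1, nu = 0.05, L = 2) {
  dp * H^3 / (12 * rho * nu * L)
}
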