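test_that("build_grid represents the constriction to within one cell", {
  g0 <- build_grid(duct_geometry(L = 2, H = 1, nx = 16, ny = 16))
  expect_true(all(g0$open_height == 1))
  expect_equal(grid_throat_height(g0), 1)

  g <- build_grid(duct_geometry(L = 2, H = 1, nx = 32, ny = 32, depth = 0.5))
  expect_lte(abs(grid_throat_height(g) - 0.5), g$dy)
  expect_identical(g$metadata$constriction_representation,
                   "blocked-cell stairstep mask")

  # stairstep mask converges at first order: with the bump peak aligned to a
  # cell centre (removing the x-sampling offset), the throat error is the
  # cell-centre rounding, bounded by half a cell at every resolution
  for (ny in c(16, 32, 64)) {
    dx <- 2 / ny
    gi <- build_grid(duct_geometry(L = 2, H = 1, nx = ny, ny = ny,
                                   centre = 1 + dx / 2, depth = 0.37))
    expect_lte(abs(grid_throat_height(gi) - 0.63), gi$dy / 2 + 1e-12)
  }

  expect_error(build_grid(duct_geometry(L = 2, H = 1, nx = 16, ny = 12,
                                        depth = 0.5)),
               "fewer than 8 cells")
  expect_error(duct_geometry(L = 2, H = 1, nx = 16, ny = 16, depth = 1),
               "depth")
})

test_that("flow_rate is a face quadrature across the open section", {
  geom <- duct_straight(ny = 16, nx = 8)
  sim <- rhinocomp:::duct_simulation(geom, forcing_spec("CFR", 1),
                                     duct_cfg())
  # uniform inflow u0 across open height H
  sim$u[3, ] <- 2.5
  expect_equal(duct_flow_rate(sim, 3), 2.5 * 1)
  # Poiseuille parabola with peak u_max: flux = (2/3) u_max H (midpoint
  # quadrature of a quadratic is second-order accurate)
  yc <- sim$grid$yc
  umax <- 1.8
  sim$u[4, ] <- umax * 4 * yc * (1 - yc)
  expect_equal(duct_flow_rate(sim, 4), (2 / 3) * umax, tolerance = 1e-2)
  expect_error(duct_flow_rate(sim, 99), "outside")
})

test_that("CFR enforces the instantaneous inlet flux exactly at every step", {
  geom <- duct_straight(ny = 16, nx = 8)
  sim <- rhinocomp:::duct_simulation(geom, forcing_spec("CFR", 0.7),
                                     duct_cfg())
  for (k in 1:25) {
    duct_step(sim)
    expect_equal(duct_flow_rate(sim, 1), 0.7, tolerance = 1e-14)
  }
  # the projected field conserves mass: flux is station-independent
  fluxes <- sapply(seq_len(nrow(sim$u)), function(i) duct_flow_rate(sim, i))
  expect_lt(max(abs(fluxes - 0.7)), 1e-10)
})

test_that("CPG converges to plane Poiseuille flow", {
  run <- duct_run_case(duct_straight(ny = 32), forcing_spec("CPG", 1.2),
                       duct_cfg())
  expect_equal(run$globals$Q_mean, poiseuille_Q(1.2), tolerance = 2e-2)
  expect_equal(run$globals$R, 1.2 / poiseuille_Q(1.2), tolerance = 2e-2)
  expect_lt(run$metadata$divergence_residual, 1e-10)
  # velocity profile approaches the parabola
  g <- run$mean_fields$grid
  uprof <- run$mean_fields$u_final[g$nx %/% 2, ]
  upar <- 1.5 * poiseuille_Q(1.2) * 4 * g$yc * (1 - g$yc)
  expect_lt(max(abs(uprof - upar)) / max(upar), 5e-2)
})

test_that("the scheme is second-order accurate under grid refinement", {
  errs <- sapply(c(8, 16, 32), function(ny) {
    run <- duct_run_case(duct_straight(ny = ny), forcing_spec("CPG", 1.2),
                         duct_cfg(steady_tol = 1e-8))
    abs(run$globals$Q_mean / poiseuille_Q(1.2) - 1)
  })
  ratios <- errs[-3] / errs[-1]
  expect_true(all(ratios > 3 & ratios < 5))
})

test_that("duct runs are deterministic for a fixed seed", {
  geom <- duct_geometry(L = 2, H = 1, nx = 16, ny = 16, depth = 0.3)
  cfg <- duct_cfg(ic_noise = 0.05, seed = 99L, steady_tol = 0, window = 0.7)
  r1 <- duct_run_case(geom, forcing_spec("CPG", 1.2), cfg)
  r2 <- duct_run_case(geom, forcing_spec("CPG", 1.2), cfg)
  expect_identical(r1$globals, r2$globals)
  expect_identical(r1$series, r2$series)
  expect_identical(r1$metadata$seed, 99L)
})

test_that("pre/post duct pair moves global quantities in the expected direction", {
  pre <- duct_geometry(L = 2, H = 1, nx = 24, ny = 24, depth = 0.5)
  post <- duct_geometry(L = 2, H = 1, nx = 24, ny = 24, depth = 0.25)
  cfg <- duct_cfg(steady_tol = 1e-6)
  p_cpg <- duct_run_case(pre, forcing_spec("CPG", 1.2), cfg)
  q_cpg <- duct_run_case(post, forcing_spec("CPG", 1.2), cfg)
  expect_gt(q_cpg$globals$Q_mean, p_cpg$globals$Q_mean)

  Qr <- p_cpg$globals$Q_mean
  p_cfr <- duct_run_case(pre, forcing_spec("CFR", Qr), cfg)
  q_cfr <- duct_run_case(post, forcing_spec("CFR", Qr), cfg)
  expect_lt(q_cfr$globals$dp_mean, p_cfr$globals$dp_mean)
  # and resistance falls under both forcings
  expect_lt(q_cpg$globals$R, p_cpg$globals$R)
  expect_lt(q_cfr$globals$R, p_cfr$globals$R)
})

test_that("the CPI controller enforces the one-step-lag relation and closes power", {
  geom <- duct_straight(ny = 24, nx = 12)
  cfg0 <- duct_cfg(steady_tol = 1e-6)
  ref <- duct_run_case(geom, forcing_spec("CFR", 1.0), cfg0)
  P0 <- ref$globals$P_mean
  cfg <- duct_cfg(steady_tol = 1e-6, cpi_warm_Q = 1.0)
  run <- duct_run_case(geom, forcing_spec("CPI", P0), cfg)
  # time-averaged power closes on the target within 1%
  expect_equal(run$globals$P_mean, P0, tolerance = 1e-2)
  # flow rate matches the generating CFR run within 1%
  expect_equal(run$globals$Q_mean, 1.0, tolerance = 1e-2)
  # the recorded series satisfies p_th(t) = -P0/Q(t - dt) exactly: power
  # computed from the lagged flow rate equals the target
  s <- run$series
  lagged <- s$Q[-nrow(s)] * (-s$p_th[-1])
  expect_lt(max(abs(lagged - P0)) / P0, 1e-12)
})

test_that("run artifacts serialize: series CSV and legacy VTK", {
  run <- duct_run_case(duct_geometry(L = 2, H = 1, nx = 12, ny = 12,
                                     depth = 0.2),
                       forcing_spec("CPG", 1.2),
                       duct_cfg(window = 1, steady_tol = 1e-5))
  fcsv <- withr::local_tempfile(fileext = ".csv")
  write_flow_series(run$series, fcsv)
  back <- read_flow_series(fcsv)
  expect_equal(nrow(back), nrow(run$series))

  fvtk <- withr::local_tempfile(fileext = ".vtk")
  write_vtk(run, fvtk)
  lines <- readLines(fvtk)
  expect_identical(lines[1], "# vtk DataFile Version 2.0")
  expect_true(any(grepl("^DIMENSIONS 12 12 1$", lines)))
  expect_true(any(grepl("^VECTORS velocity double$", lines)))
})
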