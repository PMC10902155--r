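test_that("dp_of_Q reduces to resistor algebra on linear networks", {
  a_c <- 3; a_br <- 8
  net <- airway_network(segment_law(a_br, 0), segment_law(a_br, 0),
                        segment_law(a_c, 0))
  # series common + two equal parallel linear branches
  expect_equal(dp_of_Q(net, 1), a_c + a_br / 2, tolerance = 1e-12)
  expect_identical(dp_of_Q(net, 0), 0)
  # unequal linear branches: 1/R_par = 1/a_L + 1/a_R
  net2 <- airway_network(segment_law(6, 0), segment_law(3, 0),
                         segment_law(1, 0))
  expect_equal(dp_of_Q(net2, 2), 2 * (1 + 2), tolerance = 1e-10)
})

test_that("a pure quadratic single passage reproduces the reference point", {
  b <- DP0_REF / Q0_REF^2  # 3.43e8 Pa s^2/m^6
  expect_equal(b, 3.4297e8, tolerance = 1e-4)
  net <- net_quadratic(b)
  expect_equal(dp_of_Q(net, Q0_REF), DP0_REF, tolerance = 1e-12)
})

test_that("calibrate_airway hits the reference point for every parameterization", {
  for (blend in c(0, 0.25, 0.5, 1)) {
    for (split in c(0.3, 0.5, 0.62)) {
      for (cf in c(0, 0.2, 0.45)) {
        net <- calibrate_airway(Q0 = Q0_REF, dp0 = DP0_REF, blend = blend,
                                split = split, common_fraction = cf)
        expect_equal(dp_of_Q(net, Q0_REF), DP0_REF, tolerance = 1e-10)
      }
    }
  }
  # fully linear degenerate check at half flow on a single segment
  lam <- 0.5
  net <- airway_network_single(lam * DP0_REF / Q0_REF,
                               (1 - lam) * DP0_REF / Q0_REF^2)
  expect_equal(dp_of_Q(net, Q0_REF / 2),
               lam * DP0_REF / 2 + (1 - lam) * DP0_REF / 4,
               tolerance = 1e-10)
})

test_that("apply_virtual_surgery scales one side only", {
  net <- calibrate_airway()
  same <- apply_virtual_surgery(net, "right", 1)
  expect_equal(same$right$a, net$right$a)
  expect_equal(same$right$b, net$right$b)

  post <- apply_virtual_surgery(net, "right", 0.5)
  expect_equal(post$left$a, net$left$a)
  expect_equal(post$common$a, net$common$a)
  expect_equal(post$right$a, net$right$a * 0.5)
  expect_lt(dp_of_Q(post, Q0_REF), dp_of_Q(net, Q0_REF))
  expect_error(apply_virtual_surgery(net, "right", 0), "factor")
  expect_error(apply_virtual_surgery(net, "right", 1.2), "factor")

  # pure quadratic passage: dp is proportional to b at fixed Q, so a factor
  # 0.754 applied to the whole passage cuts the constant-flow drop by 24.6%
  b <- DP0_REF / Q0_REF^2
  pre <- net_quadratic(b)
  post <- net_quadratic(b * 0.754)
  expect_equal(percent_change(dp_of_Q(pre, Q0_REF), dp_of_Q(post, Q0_REF)),
               -24.6, tolerance = 1e-10)
})

test_that("solve_steady matches single-segment closed forms to 1e-10", {
  R0 <- DP0_REF / Q0_REF
  lin <- net_linear(R0)
  # CPI on a linear law: Q = sqrt(P/R)
  gq <- solve_steady(lin, forcing_spec("CPI", P0_REF))
  expect_equal(gq$Q_mean, sqrt(P0_REF / R0), tolerance = 1e-10)
  # CPG on a linear law: Q = dp/R
  gq <- solve_steady(lin, forcing_spec("CPG", DP0_REF))
  expect_equal(gq$Q_mean, DP0_REF / R0, tolerance = 1e-10)

  b <- DP0_REF / Q0_REF^2
  quad <- net_quadratic(b)
  # CPG on a quadratic law: Q = sqrt(dp/b)
  gq <- solve_steady(quad, forcing_spec("CPG", DP0_REF))
  expect_equal(gq$Q_mean, sqrt(DP0_REF / b), tolerance = 1e-10)
  # CPI on a quadratic law: Q = (P/b)^(1/3)
  gq <- solve_steady(quad, forcing_spec("CPI", P0_REF))
  expect_equal(gq$Q_mean, (P0_REF / b)^(1 / 3), tolerance = 1e-10)
  # CFR is polynomial evaluation
  gq <- solve_steady(quad, forcing_spec("CFR", Q0_REF))
  expect_equal(gq$dp_mean, DP0_REF, tolerance = 1e-12)
  expect_equal(gq$R, DP0_REF / Q0_REF, tolerance = 1e-12)
})

test_that("the three forcings are equivalent on a single anatomy", {
  set.seed(11)
  for (k in 1:6) {
    net <- calibrate_airway(blend = runif(1), split = runif(1, 0.25, 0.75),
                            common_fraction = runif(1, 0, 0.4))
    ref <- solve_steady(net, forcing_spec("CFR", Q0_REF))
    cpg <- solve_steady(net, forcing_spec("CPG", ref$dp_mean))
    cpi <- solve_steady(net, forcing_spec("CPI", ref$P_mean))
    for (gq in list(cpg, cpi)) {
      expect_equal(gq$Q_mean, ref$Q_mean, tolerance = 1e-8)
      expect_equal(gq$dp_mean, ref$dp_mean, tolerance = 1e-8)
      expect_equal(gq$P_mean, ref$P_mean, tolerance = 1e-8)
    }
  }
})

test_that("resistance-change magnitudes order CFR >= CPI >= CPG analytically", {
  # pure quadratic: R ratios are f, f^(2/3), f^(1/2) under CFR, CPI, CPG
  b <- DP0_REF / Q0_REF^2
  f <- 0.754
  pre <- net_quadratic(b); post <- net_quadratic(b * f)
  ref <- solve_steady(pre, forcing_spec("CFR", Q0_REF))
  r_cfr <- solve_steady(post, forcing_spec("CFR", ref$Q_mean))$R / ref$R
  r_cpg <- solve_steady(post, forcing_spec("CPG", ref$dp_mean))$R / ref$R
  r_cpi <- solve_steady(post, forcing_spec("CPI", ref$P_mean))$R / ref$R
  expect_equal(r_cfr, f, tolerance = 1e-10)
  expect_equal(r_cpi, f^(2 / 3), tolerance = 1e-8)
  expect_equal(r_cpg, f^(1 / 2), tolerance = 1e-8)
  expect_true(r_cfr < r_cpi && r_cpi < r_cpg)
})

test_that("lateral resistances respect symmetry and surgery", {
  net <- calibrate_airway(split = 0.5)
  st <- solve_steady(net, forcing_spec("CFR", Q0_REF))
  lr <- lateral_resistances(net, st)
  expect_equal(lr[["left"]], lr[["right"]], tolerance = 1e-10)

  post <- apply_virtual_surgery(net, "right", 0.5)
  stp <- solve_steady(post, forcing_spec("CFR", Q0_REF))
  lrp <- lateral_resistances(post, stp)
  expect_lt(lrp[["right"]], lrp[["left"]])

  # linear branches: lateral resistances equal the branch coefficients
  netl <- airway_network(segment_law(6, 0), segment_law(3, 0),
                         segment_law(1, 0))
  stl <- solve_steady(netl, forcing_spec("CFR", 1))
  lrl <- lateral_resistances(netl, stl)
  expect_equal(lrl[["left"]], 6, tolerance = 1e-9)
  expect_equal(lrl[["right"]], 3, tolerance = 1e-9)
})

test_that("the under-relaxed CPI iteration converges to the root-found state", {
  for (blend in c(0, 0.5, 1)) {
    net <- calibrate_airway(blend = blend)
    direct <- solve_steady(net, forcing_spec("CPI", P0_REF))
    fp <- cpi_fixed_point(net, P0_REF, dp_init = 2 * DP0_REF, relax = 0.5)
    expect_true(fp$converged)
    expect_equal(fp$Q, direct$Q_mean, tolerance = 1e-8)
    expect_equal(fp$dp, direct$dp_mean, tolerance = 1e-8)
    # fixed point closes the power constraint
    expect_equal(fp$Q * fp$dp, P0_REF, tolerance = 1e-8)
  }
})

test_that("airway networks round-trip through the key = value dialect", {
  net <- calibrate_airway(blend = 0.37, split = 0.61)
  f <- withr::local_tempfile(fileext = ".txt")
  write_airway_network(net, f)
  back <- read_airway_network(f)
  for (nm in c("left", "right", "common")) {
    expect_identical(back[[nm]]$a, net[[nm]]$a)
    expect_identical(back[[nm]]$b, net[[nm]]$b)
  }
  writeLines(c("left.a = 1", "oops = 2"), f)
  expect_error(read_airway_network(f), "must define exactly")
})

test_that("segment and network validation catches bad inputs", {
  expect_error(segment_law(-1, 0), ">= 0")
  expect_error(segment_law(0, 0), "nonzero")
  expect_error(dp_of_Q(calibrate_airway(), -1), "Q >= 0")
})
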