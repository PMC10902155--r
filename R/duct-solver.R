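#' 2D incompressible duct solver
#'
#' An unsteady incompressible Navier--Stokes solver on the staggered grid of
#' [build_grid()], used as the desk-scale dynamical stand-in for anatomical
#' airflow simulations. Time advancement is an explicit variable-step
#' Adams--Bashforth-2 scheme for advection and diffusion, followed by a
#' projection (pressure-Poisson) step that enforces a divergence-free field;
#' spatial operators are second-order central differences. The time step is
#' limited by a Courant--Friedrichs--Lewy number (default 0.3) and, because
#' diffusion is explicit, by the viscous stability bound.
#'
#' The three global forcings are realized as boundary conditions:
#' * CFR: the inlet velocity profile is scaled so the instantaneous flux
#'   equals the target exactly; the outlet holds a pressure reference.
#' * CPG: pressure Dirichlet values at inlet (0) and outlet (-dp0).
#' * CPI: as CPG, but the outlet pressure is set every step by the
#'   constant-power controller [cpi_throat_pressure()] from the flow rate at
#'   the previous step.
#'
#' @name duct-solver
NULL

#' Solver configuration
#'
#' @param rho fluid density (kg/m^3); default 1.2 (air at 20 C).
#' @param nu kinematic viscosity (m^2/s); default 1.5e-5 (air at 20 C).
#' @param cfl Courant number in (0, 1); default 0.3.
#' @param max_steps hard cap on time steps.
#' @param window statistical averaging window (s).
#' @param discard_fraction initial fraction of the run discarded as
#'   transient; default 0.3. The planned run length is
#'   `window / (1 - discard_fraction)`.
#' @param div_tol admissible post-projection divergence, normalized by the
#'   maximum face velocity over the smallest cell size; default 1e-8.
#' @param steady_tol relative change of (Q, dp) per check interval below
#'   which the run is declared steady and stopped early; default 1e-7,
#'   set to 0 to disable.
#' @param seed integer seed for the perturbed initial condition.
#' @param ic_noise relative amplitude of the random initial velocity
#'   perturbation; default 0 (quiescent or warm start).
#' @param Q_floor flow-rate floor passed to the CPI controller (m^3/s in 3D
#'   use, m^2/s for the per-unit-depth duct).
#' @param warm_time duration of the constant-flow warm start used before
#'   switching on the CPI controller; default `NULL` (one quarter of the
#'   planned run length).
#' @param cpi_warm_Q optional flow-rate estimate for the CPI warm start; if
#'   `NULL` a lubrication (Poiseuille-integral) estimate is used.
#' @return an object of class `solver_config`.
#' @export
solver_config <- function(rho = 1.2, nu = 1.5e-5, cfl = 0.3,
                          max_steps = 200000L, window = 1.0,
                          discard_fraction = 0.3, div_tol = 1e-8,
                          steady_tol = 1e-7, seed = 1L, ic_noise = 0,
                          Q_floor = 1e-9, warm_time = NULL,
                          cpi_warm_Q = NULL) {
  stopifnot(rho > 0, nu > 0, cfl > 0, cfl < 1, window > 0,
            discard_fraction >= 0, discard_fraction < 1,
            div_tol > 0, ic_noise >= 0, Q_floor > 0)
  structure(list(rho = rho, nu = nu, cfl = cfl,
                 max_steps = as.integer(max_steps), window = window,
                 discard_fraction = discard_fraction, div_tol = div_tol,
                 steady_tol = steady_tol, seed = as.integer(seed),
                 ic_noise = ic_noise, Q_floor = Q_floor,
                 warm_time = warm_time, cpi_warm_Q = cpi_warm_Q),
            class = "solver_config")
}

# ---- pressure-Poisson operator --------------------------------------------
# Assembles the 5-point Laplacian over fluid cells with Neumann conditions at
# walls and solid cells and Dirichlet ghosts at the inlet/outlet according to
# the forcing mode; returns a cached Cholesky factorization of -A (SPD as
# soon as one Dirichlet face is present, which is always the case here).
build_poisson <- function(grid, mode) {
  nx <- grid$nx; ny <- grid$ny
  dx2 <- grid$dx^2; dy2 <- grid$dy^2
  fluidP <- grid$fluidP
  idx <- matrix(0L, nx, ny)
  idx[fluidP] <- seq_len(sum(fluidP))
  n <- sum(fluidP)

  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  diag_acc <- numeric(n)

  pairE <- fluidP[-nx, , drop = FALSE] & fluidP[-1L, , drop = FALSE]
  a <- idx[-nx, ][pairE]; b <- idx[-1L, ][pairE]
  ii <- c(ii, a, b); jj <- c(jj, b, a); xx <- c(xx, rep(1 / dx2, 2 * length(a)))
  tab <- tabulate(c(a, b), nbins = n)
  diag_acc <- diag_acc - tab / dx2

  pairN <- fluidP[, -ny, drop = FALSE] & fluidP[, -1L, drop = FALSE]
  a <- idx[, -ny][pairN]; b <- idx[, -1L][pairN]
  ii <- c(ii, a, b); jj <- c(jj, b, a); xx <- c(xx, rep(1 / dy2, 2 * length(a)))
  tab <- tabulate(c(a, b), nbins = n)
  diag_acc <- diag_acc - tab / dy2

  # Dirichlet ghost faces: outlet for every mode, inlet for CPG/CPI
  out_cells <- idx[nx, fluidP[nx, ]]
  diag_acc[out_cells] <- diag_acc[out_cells] - 2 / dx2
  in_cells <- integer(0)
  if (mode %in% c("CPG", "CPI")) {
    in_cells <- idx[1L, fluidP[1L, ]]
    diag_acc[in_cells] <- diag_acc[in_cells] - 2 / dx2
  }

  ii <- c(ii, seq_len(n)); jj <- c(jj, seq_len(n)); xx <- c(xx, diag_acc)
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  fac <- Matrix::Cholesky(Matrix::forceSymmetric(-A), LDL = FALSE, perm = TRUE)
  list(fac = fac, idx = idx, n = n, out_cells = out_cells, in_cells = in_cells)
}

# ---- simulation context ----------------------------------------------------

# Precomputes masks, ghost bookkeeping and the Poisson factorization for one
# (grid, forcing-mode) pair and initializes the field state.
duct_simulation <- function(geom, forcing, cfg, init = NULL) {
  stopifnot(inherits(geom, "duct_geometry"), inherits(forcing, "forcing_spec"),
            inherits(cfg, "solver_config"))
  grid <- if (inherits(geom, "duct_geometry")) build_grid(geom) else geom
  nx <- grid$nx; ny <- grid$ny
  mode <- forcing$mode

  fluidU <- grid$fluidU; fluidV <- grid$fluidV

  # u faces advanced by the momentum equation (strictly interior in x)
  advU <- fluidU
  advU[c(1L, nx + 1L), ] <- FALSE
  # tangential-wall mirror masks for u (horizontal walls above/below)
  wallN_u <- fluidU & !cbind(fluidU[, -1L, drop = FALSE], rep(FALSE, nx + 1L))
  wallS_u <- fluidU & !cbind(rep(FALSE, nx + 1L), fluidU[, -ny, drop = FALSE])

  advV <- fluidV
  # tangential ghost bookkeeping for v (vertical stair walls, inlet, outlet)
  mirE_v <- fluidV & !rbind(fluidV[-1L, , drop = FALSE], rep(TRUE, ny + 1L))
  mirW_v <- fluidV & !rbind(rep(TRUE, ny + 1L), fluidV[-nx, , drop = FALSE])
  zgE_v <- matrix(FALSE, nx, ny + 1L); zgE_v[nx, ] <- fluidV[nx, ]
  inW_v <- matrix(FALSE, nx, ny + 1L); inW_v[1L, ] <- fluidV[1L, ]
  # inlet tangential ghost: Dirichlet plane (v = 0) under CFR, zero gradient
  # under pressure-driven modes
  w_in_sign <- if (mode == "CFR") -1 else 1

  pois <- build_poisson(grid, mode)

  # CFR inlet profile: parabola over the open inlet span, scaled to the
  # instantaneous target flux
  uin_shape <- numeric(ny)
  open_in <- grid$fluidP[1L, ]
  ys <- grid$yc[open_in]
  y0 <- min(ys) - grid$dy / 2; y1 <- max(ys) + grid$dy / 2
  uin_shape[open_in] <- (ys - y0) * (y1 - ys)
  uin_shape <- uin_shape / sum(uin_shape * grid$dy)

  u <- matrix(0, nx + 1L, ny)
  v <- matrix(0, nx, ny + 1L)
  p <- matrix(0, nx, ny)
  if (!is.null(init)) {
    stopifnot(all(dim(init$u) == dim(u)), all(dim(init$v) == dim(v)))
    u <- init$u; v <- init$v
    u[!fluidU] <- 0; v[!fluidV] <- 0
    if (!is.null(init$p)) p <- init$p
  } else if (cfg$ic_noise > 0) {
    set.seed(cfg$seed)
    scale <- cfg$ic_noise * velocity_scale(grid, forcing, cfg)
    u[advU] <- scale * stats::rnorm(sum(advU))
    v[advV] <- scale * stats::rnorm(sum(advV))
  }

  sim <- new.env(parent = emptyenv())
  sim$grid <- grid; sim$cfg <- cfg; sim$forcing <- forcing; sim$mode <- mode
  sim$u <- u; sim$v <- v; sim$p <- p
  sim$t <- 0; sim$nstep <- 0L
  sim$dt_prev <- NA_real_
  sim$Fu_prev <- NULL; sim$Fv_prev <- NULL
  sim$advU <- advU; sim$advV <- advV
  sim$wallN_u <- wallN_u; sim$wallS_u <- wallS_u
  sim$mirE_v <- mirE_v; sim$mirW_v <- mirW_v
  sim$zgE_v <- zgE_v; sim$inW_v <- inW_v; sim$w_in_sign <- w_in_sign
  sim$pois <- pois
  sim$uin_shape <- uin_shape
  sim$Q_last <- duct_flow_rate(sim)
  sim$dp_last <- NA_real_
  class(sim) <- "duct_simulation"
  sim
}

# crude velocity scale used only for initial noise and divergence
# normalization
velocity_scale <- function(grid, forcing, cfg) {
  area <- grid$throat_height
  switch(forcing$mode,
         CFR = forcing$target / area,
         CPG = sqrt(forcing$target / cfg$rho),
         CPI = (forcing$target / (cfg$rho * area))^(1 / 3))
}

# lubrication (local-Poiseuille) estimate of the duct resistance,
# R = integral of 12 rho nu / h(x)^3 dx, used for the CPI warm start
lubrication_resistance <- function(grid, cfg) {
  h <- grid$open_height
  sum(12 * cfg$rho * cfg$nu / h^3) * grid$dx
}

#' Instantaneous flux through a streamwise station
#'
#' Face-velocity quadrature across the open section. After each projection
#' the discrete field is divergence-free, so the flux is
#' station-independent up to the divergence tolerance.
#'
#' @param sim a duct simulation object (see [duct_run_case()]).
#' @param i face index of the station (1 = inlet, `nx + 1` = outlet);
#'   default the inlet.
#' @return flux per unit depth (m^2/s).
#' @export
duct_flow_rate <- function(sim, i = 1L) {
  u <- sim$u
  if (i < 1L || i > nrow(u)) stop("station outside the domain", call. = FALSE)
  sum(u[i, ]) * sim$grid$dy
}

# effective neighbor fields with mirror/zero-gradient ghosts
u_neighbors <- function(sim) {
  u <- sim$u; nx <- sim$grid$nx; ny <- sim$grid$ny
  uE <- u[c(2:(nx + 1L), nx + 1L), , drop = FALSE]
  uW <- u[c(1L, 1:nx), , drop = FALSE]
  uN <- u[, c(2:ny, ny), drop = FALSE]
  uS <- u[, c(1L, 1:(ny - 1L)), drop = FALSE]
  uN[sim$wallN_u] <- -u[sim$wallN_u]
  uS[sim$wallS_u] <- -u[sim$wallS_u]
  list(E = uE, W = uW, N = uN, S = uS)
}

v_neighbors <- function(sim) {
  v <- sim$v; nx <- sim$grid$nx; ny <- sim$grid$ny
  vE <- v[c(2:nx, nx), , drop = FALSE]
  vW <- v[c(1L, 1:(nx - 1L)), , drop = FALSE]
  vN <- v[, c(2:(ny + 1L), ny + 1L), drop = FALSE]
  vS <- v[, c(1L, 1:ny), drop = FALSE]
  vE[sim$mirE_v] <- -v[sim$mirE_v]
  vW[sim$mirW_v] <- -v[sim$mirW_v]
  vE[sim$zgE_v] <- v[sim$zgE_v]
  vW[sim$inW_v] <- sim$w_in_sign * v[sim$inW_v]
  list(E = vE, W = vW, N = vN, S = vS)
}

# advection + diffusion right-hand sides on the staggered grid
momentum_rhs <- function(sim) {
  g <- sim$grid; nx <- g$nx; ny <- g$ny
  dx <- g$dx; dy <- g$dy; nu <- sim$cfg$nu
  u <- sim$u; v <- sim$v

  un <- u_neighbors(sim)
  vsum <- v[, 1:ny, drop = FALSE] + v[, 2:(ny + 1L), drop = FALSE]
  vbar <- matrix(0, nx + 1L, ny)
  vbar[2:nx, ] <- 0.25 * (vsum[1:(nx - 1L), , drop = FALSE] +
                          vsum[2:nx, , drop = FALSE])
  Fu <- -u * (un$E - un$W) / (2 * dx) -
        vbar * (un$N - un$S) / (2 * dy) +
        nu * ((un$E - 2 * u + un$W) / dx^2 + (un$N - 2 * u + un$S) / dy^2)
  Fu[!sim$advU] <- 0

  vn <- v_neighbors(sim)
  usum <- u[1:nx, , drop = FALSE] + u[2:(nx + 1L), , drop = FALSE]
  ubar <- matrix(0, nx, ny + 1L)
  ubar[, 2:ny] <- 0.25 * (usum[, 1:(ny - 1L), drop = FALSE] +
                          usum[, 2:ny, drop = FALSE])
  Fv <- -ubar * (vn$E - vn$W) / (2 * dx) -
        v * (vn$N - vn$S) / (2 * dy) +
        nu * ((vn$E - 2 * v + vn$W) / dx^2 + (vn$N - 2 * v + vn$S) / dy^2)
  Fv[!sim$advV] <- 0

  list(Fu = Fu, Fv = Fv)
}

# CFL- and viscosity-limited time step
compute_dt <- function(sim) {
  g <- sim$grid; cfg <- sim$cfg
  umax <- max(abs(sim$u)); vmax <- max(abs(sim$v))
  dt_adv <- cfg$cfl * min(if (umax > 0) g$dx / umax else Inf,
                          if (vmax > 0) g$dy / vmax else Inf)
  dt_visc <- 0.5 / (2 * cfg$nu * (1 / g$dx^2 + 1 / g$dy^2))
  dt <- min(dt_adv, dt_visc)
  if (!is.finite(dt) || dt <= 0) stop("CFL collapse: dt = ", dt, call. = FALSE)
  dt
}

#' Advance the duct simulation by one time step
#'
#' Explicit Adams--Bashforth-2 advection--diffusion predictor followed by a
#' pressure projection. The forcing is enforced exactly at every step: under
#' CFR the instantaneous inlet flux equals the target, under CPG the outlet
#' pressure is the target, and under CPI the outlet pressure follows the
#' one-step-lagged constant-power controller.
#'
#' @param sim a duct simulation object (see [duct_run_case()]).
#' @return the simulation object, invisibly; its fields are updated in
#'   place.
#' @export
duct_step <- function(sim) {
  g <- sim$grid; cfg <- sim$cfg; nx <- g$nx; ny <- g$ny
  mode <- sim$mode; rho <- cfg$rho

  # boundary pressures for this step
  p_in <- 0
  p_out <- switch(mode,
    CFR = 0,
    CPG = -sim$forcing$target,
    CPI = cpi_throat_pressure(sim$forcing$target, sim$Q_last,
                              Q_floor = cfg$Q_floor))

  # velocity boundary values entering the predictor
  if (mode == "CFR") {
    sim$u[1L, ] <- sim$forcing$target * sim$uin_shape
  } else {
    sim$u[1L, ] <- sim$u[2L, ] * g$fluidU[1L, ]
  }
  sim$u[nx + 1L, ] <- sim$u[nx, ] * g$fluidU[nx + 1L, ]

  dt <- compute_dt(sim)
  rhs <- momentum_rhs(sim)
  if (is.null(sim$Fu_prev)) {
    du <- dt * rhs$Fu
    dv <- dt * rhs$Fv
  } else {
    r <- dt / sim$dt_prev
    du <- dt * ((1 + r / 2) * rhs$Fu - (r / 2) * sim$Fu_prev)
    dv <- dt * ((1 + r / 2) * rhs$Fv - (r / 2) * sim$Fv_prev)
  }
  sim$u <- sim$u + du
  sim$v <- sim$v + dv
  sim$Fu_prev <- rhs$Fu; sim$Fv_prev <- rhs$Fv; sim$dt_prev <- dt

  # re-impose predictor boundary values
  if (mode == "CFR") {
    sim$u[1L, ] <- sim$forcing$target * sim$uin_shape
  } else {
    sim$u[1L, ] <- sim$u[2L, ] * g$fluidU[1L, ]
  }
  sim$u[nx + 1L, ] <- sim$u[nx, ] * g$fluidU[nx + 1L, ]

  # pressure Poisson: div of the predicted field
  divP <- (sim$u[2:(nx + 1L), , drop = FALSE] - sim$u[1:nx, , drop = FALSE]) / g$dx +
          (sim$v[, 2:(ny + 1L), drop = FALSE] - sim$v[, 1:ny, drop = FALSE]) / g$dy
  b <- (rho / dt) * divP[g$fluidP]
  if (length(sim$pois$out_cells)) {
    b[sim$pois$out_cells] <- b[sim$pois$out_cells] - 2 * p_out / g$dx^2
  }
  if (length(sim$pois$in_cells) && p_in != 0) {
    b[sim$pois$in_cells] <- b[sim$pois$in_cells] - 2 * p_in / g$dx^2
  }
  phi_vec <- -as.numeric(Matrix::solve(sim$pois$fac, b))
  phi <- matrix(0, nx, ny)
  phi[g$fluidP] <- phi_vec

  # velocity correction (ghost-consistent at Dirichlet ends)
  gx <- (phi[2:nx, , drop = FALSE] - phi[1:(nx - 1L), , drop = FALSE]) / g$dx
  corr <- matrix(0, nx + 1L, ny)
  corr[2:nx, ] <- gx
  corr[nx + 1L, ] <- 2 * (p_out - phi[nx, ]) / g$dx
  if (mode != "CFR") corr[1L, ] <- 2 * (phi[1L, ] - p_in) / g$dx
  corr[1L, !g$fluidU[1L, ]] <- 0
  corr[nx + 1L, !g$fluidU[nx + 1L, ]] <- 0
  sel <- sim$advU
  sim$u[sel] <- sim$u[sel] - (dt / rho) * corr[sel]
  sim$u[nx + 1L, ] <- sim$u[nx + 1L, ] - (dt / rho) * corr[nx + 1L, ]
  if (mode != "CFR") sim$u[1L, ] <- sim$u[1L, ] - (dt / rho) * corr[1L, ]

  gy <- (phi[, 2:ny, drop = FALSE] - phi[, 1:(ny - 1L), drop = FALSE]) / g$dy
  corrv <- matrix(0, nx, ny + 1L)
  corrv[, 2:ny] <- gy
  sim$v[sim$advV] <- sim$v[sim$advV] - (dt / rho) * corrv[sim$advV]

  sim$p <- phi
  sim$t <- sim$t + dt
  sim$nstep <- sim$nstep + 1L

  # instantaneous global state
  Q <- duct_flow_rate(sim, 1L)
  dp <- switch(mode,
    CFR = {
      # extrapolate the open-inlet pressure to the x = 0 face; outlet is 0
      open1 <- g$fluidP[1L, ]
      mean(1.5 * phi[1L, open1] - 0.5 * phi[2L, open1])
    },
    CPG = sim$forcing$target,
    CPI = -p_out)
  sim$Q_last <- Q
  sim$dp_last <- dp
  invisible(sim)
}

check_divergence <- function(sim) {
  g <- sim$grid; nx <- g$nx; ny <- g$ny
  divP <- (sim$u[2:(nx + 1L), , drop = FALSE] - sim$u[1:nx, , drop = FALSE]) / g$dx +
          (sim$v[, 2:(ny + 1L), drop = FALSE] - sim$v[, 1:ny, drop = FALSE]) / g$dy
  umax <- max(abs(sim$u), abs(sim$v), 1e-300)
  max(abs(divP[g$fluidP])) * min(g$dx, g$dy) / umax
}

#' Run a duct case to statistical convergence
#'
#' Integrates the duct solver under one forcing until the statistical window
#' is filled (or a steady state is detected), then time-averages the global
#' signals with [time_average()]. A CPI run is warm-started: the flow is
#' first driven at a constant estimated flow rate, and the power controller
#' is switched on from that developed state, because the controller relation
#' is singular at rest.
#'
#' @param geom a [duct_geometry()].
#' @param forcing a [forcing_spec()]. For the 2D duct the flow-rate and
#'   power targets are per unit depth (m^2/s and W/m).
#' @param cfg a [solver_config()].
#' @param init optional initial fields (list with `u`, `v`, optionally `p`).
#' @return a list of class `duct_run` with elements `globals`
#'   ([global_quantities()]), `series` (data.frame `t`, `Q`, `p_th`, `P`),
#'   `mean_fields` (time-averaged `u`, `v`, `p` plus the final snapshot),
#'   and `metadata` (including the enforced-constraint residual, divergence
#'   residual, steps and seed).
#' @export
duct_run_case <- function(geom, forcing, cfg = solver_config(), init = NULL) {
  stopifnot(inherits(forcing, "forcing_spec"))
  t_end <- cfg$window / (1 - cfg$discard_fraction)

  warm <- NULL
  if (forcing$mode == "CPI" && is.null(init)) {
    Q_warm <- cfg$cpi_warm_Q
    if (is.null(Q_warm)) {
      gtmp <- build_grid(geom)
      Q_warm <- sqrt(forcing$target / lubrication_resistance(gtmp, cfg))
    }
    t_warm <- if (is.null(cfg$warm_time)) 0.25 * t_end else cfg$warm_time
    warm_cfg <- cfg
    warm_cfg$window <- t_warm * (1 - cfg$discard_fraction)
    warm_cfg$steady_tol <- 0  # run the full warm window
    warm <- duct_run_case(geom, forcing_spec("CFR", Q_warm), warm_cfg)
    init <- warm$mean_fields[c("u_final", "v_final", "p_final")]
    names(init) <- c("u", "v", "p")
  }

  sim <- duct_simulation(geom, forcing, cfg, init = init)
  g <- sim$grid
  nmax <- cfg$max_steps
  ts <- numeric(0); Qs <- numeric(0); dps <- numeric(0)
  meanU <- matrix(0, g$nx + 1L, g$ny)
  meanV <- matrix(0, g$nx, g$ny + 1L)
  meanP <- matrix(0, g$nx, g$ny)
  t_acc0 <- cfg$discard_fraction * t_end
  acc_t <- 0

  check_every <- 50L
  Q_chk <- NA_real_; dp_chk <- NA_real_
  steady <- FALSE

  while (sim$t < t_end && sim$nstep < nmax) {
    duct_step(sim)
    ts <- c(ts, sim$t); Qs <- c(Qs, sim$Q_last); dps <- c(dps, sim$dp_last)
    if (sim$t >= t_acc0) {
      dt <- sim$dt_prev
      meanU <- meanU + sim$u * dt
      meanV <- meanV + sim$v * dt
      meanP <- meanP + sim$p * dt
      acc_t <- acc_t + dt
    }
    if (cfg$steady_tol > 0 && sim$nstep %% check_every == 0L) {
      if (!is.na(Q_chk)) {
        rel <- max(abs(sim$Q_last - Q_chk) / max(abs(sim$Q_last), 1e-300),
                   abs(sim$dp_last - dp_chk) / max(abs(sim$dp_last), 1e-300))
        if (rel < cfg$steady_tol) { steady <- TRUE; break }
      }
      Q_chk <- sim$Q_last; dp_chk <- sim$dp_last
    }
  }

  div_res <- check_divergence(sim)
  if (div_res > cfg$div_tol) {
    stop("divergence not converged: normalized residual ", format(div_res),
         call. = FALSE)
  }

  series <- data.frame(t = ts, Q = Qs, p_th = -dps, P = Qs * dps)
  if (steady) {
    Q_mean <- sim$Q_last; dp_mean <- sim$dp_last
    P_mean <- Q_mean * dp_mean
  } else {
    Q_mean <- time_average(ts, Qs, cfg$discard_fraction)
    dp_mean <- time_average(ts, dps, cfg$discard_fraction)
    P_mean <- time_average(ts, Qs * dps, cfg$discard_fraction)
  }
  globals <- global_quantities(Q_mean, dp_mean, P_mean)

  if (acc_t > 0 && !steady) {
    meanU <- meanU / acc_t; meanV <- meanV / acc_t; meanP <- meanP / acc_t
  } else {
    meanU <- sim$u; meanV <- sim$v; meanP <- sim$p
  }

  residual <- switch(forcing$mode,
    CFR = abs(Q_mean - forcing$target) / forcing$target,
    CPG = abs(dp_mean - forcing$target) / forcing$target,
    CPI = abs(P_mean - forcing$target) / forcing$target)

  structure(list(
    globals = globals,
    series = series,
    mean_fields = list(u = meanU, v = meanV, p = meanP,
                       u_final = sim$u, v_final = sim$v, p_final = sim$p,
                       grid = g),
    metadata = list(mode = forcing$mode, target = forcing$target,
                    steps = sim$nstep, t_final = sim$t,
                    steady_state = steady,
                    constraint_residual = residual,
                    divergence_residual = div_res,
                    rho = cfg$rho, nu = cfg$nu, cfl = cfg$cfl,
                    seed = cfg$seed,
                    constriction_representation =
                      g$metadata$constriction_representation,
                    warm_start = if (!is.null(warm)) warm$metadata else NULL)),
    class = "duct_run")
}

#' @export
print.duct_run <- function(x, ...) {
  cat(sprintf("<duct_run> %s, %d steps to t = %.4g s%s\n",
              x$metadata$mode, x$metadata$steps, x$metadata$t_final,
              if (x$metadata$steady_state) " (steady)" else ""))
  print(x$globals)
  invisible(x)
}

#' Write mean fields as a legacy VTK structured-points file
#'
#' Cell-centred pressure and centre-interpolated velocity are written as
#' point data on the cell-centre lattice (ASCII, legacy VTK 2.0).
#'
#' @param run a `duct_run` from [duct_run_case()].
#' @param path output `.vtk` path.
#' @export
write_vtk <- function(run, path) {
  g <- run$mean_fields$grid
  nx <- g$nx; ny <- g$ny
  uc <- 0.5 * (run$mean_fields$u[1:nx, , drop = FALSE] +
               run$mean_fields$u[2:(nx + 1L), , drop = FALSE])
  vc <- 0.5 * (run$mean_fields$v[, 1:ny, drop = FALSE] +
               run$mean_fields$v[, 2:(ny + 1L), drop = FALSE])
  p <- run$mean_fields$p
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 2.0",
               "duct mean fields", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d 1", nx, ny),
               sprintf("ORIGIN %.9g %.9g 0", g$dx / 2, g$dy / 2),
               sprintf("SPACING %.9g %.9g 1", g$dx, g$dy),
               sprintf("POINT_DATA %d", nx * ny),
               "SCALARS pressure double 1",
               "LOOKUP_TABLE default"), con)
  writeLines(format(as.numeric(p), digits = 9), con)
  writeLines("VECTORS velocity double", con)
  writeLines(sprintf("%.9g %.9g 0", as.numeric(uc), as.numeric(vc)), con)
  invisible(path)
}
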