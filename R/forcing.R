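#' Global flow quantities and forcing controllers
#'
#' The functions in this file define the global bookkeeping shared by every
#' flow model in the package: the sign conventions for flow rate and throat
#' pressure, the mechanical power identity, the constant-power-input (CPI)
#' controller, nasal resistance, percentage changes, and time averaging of
#' sampled signals.
#'
#' Sign conventions: the ambient is the pressure reference (p = 0), the flow
#' rate Q is positive during inspiration (ambient towards throat) and the
#' throat pressure p_th is then negative. The pressure *drop* dp = -p_th is
#' reported as a positive magnitude, as is the nasal resistance R = dp/Q.
#'
#' @name forcing-core
NULL

#' Mechanical power driving the flow
#'
#' Power input entering the airway, `P = Q * dp = -Q * p_th`: positive during
#' inspiration (Q > 0, p_th < 0).
#'
#' @param Q volumetric flow rate (m^3/s), positive for inspiration.
#' @param p_th throat pressure relative to the ambient reference (Pa),
#'   negative for inspiration.
#' @return power input (W).
#' @examples
#' compute_power(2.67e-4, -24.45)  # ~6.53e-3 W, i.e. 6.53 mW
#' @export
compute_power <- function(Q, p_th) {
  stopifnot(is.numeric(Q), is.numeric(p_th))
  -Q * p_th
}

#' CPI controller: throat pressure from the power target
#'
#' One step of the constant-power-input controller: the throat pressure that,
#' applied to the flow rate observed at the previous step, injects exactly the
#' target power, `p_th = -P0 / Q_prev`. The relation is singular at rest, so a
#' positive floor on `Q_prev` guards the start-up: the controller must be
#' warm-started from a flowing state (see [duct_run_case()]).
#'
#' @param P0 power target (W), > 0.
#' @param Q_prev flow rate at the previous step (m^3/s).
#' @param Q_floor smallest admissible `Q_prev` (m^3/s); default 1e-6.
#' @return throat pressure (Pa), strictly negative.
#' @export
cpi_throat_pressure <- function(P0, Q_prev, Q_floor = 1e-6) {
  stopifnot(is.numeric(P0), length(P0) == 1L, P0 > 0,
            is.numeric(Q_floor), length(Q_floor) == 1L, Q_floor > 0)
  if (!is.numeric(Q_prev) || length(Q_prev) != 1L || !is.finite(Q_prev) ||
      Q_prev <= Q_floor) {
    stop("CPI controller cannot operate at Q_prev <= Q_floor (",
         format(Q_floor), " m^3/s): got Q_prev = ", format(Q_prev),
         ". Warm-start the run from a flowing state.", call. = FALSE)
  }
  -P0 / Q_prev
}

#' Nasal resistance
#'
#' The clinical summary of airway patency, `R = dp / Q`, with the pressure
#' drop taken ambient-to-throat as a positive magnitude.
#'
#' @param dp pressure drop (Pa), >= 0.
#' @param Q flow rate (m^3/s), > 0.
#' @return resistance (Pa s/m^3).
#' @export
nasal_resistance <- function(dp, Q) {
  stopifnot(is.numeric(dp), is.numeric(Q))
  if (any(Q <= 0)) stop("nasal_resistance requires Q > 0", call. = FALSE)
  if (any(dp < 0)) stop("nasal_resistance requires dp >= 0", call. = FALSE)
  dp / Q
}

#' Signed percentage change
#'
#' `100 * (post - pre) / abs(pre)`; applied throughout to positive magnitudes
#' of Q, dp, P and R, so a positive value means an increase.
#'
#' @param pre reference value, non-zero.
#' @param post new value.
#' @return signed percentage.
#' @export
percent_change <- function(pre, post) {
  stopifnot(is.numeric(pre), is.numeric(post))
  if (any(pre == 0)) stop("percent_change undefined for pre = 0", call. = FALSE)
  100 * (post - pre) / abs(pre)
}

#' Time-weighted mean of a sampled signal
#'
#' Trapezoidal time average over the retained window after discarding an
#' initial fraction of the sampled time span (the start-up transient).
#' Trapezoidal weighting matters because adaptive CFL stepping produces
#' non-uniformly spaced samples.
#'
#' @param t sample times (s), strictly increasing.
#' @param x sampled values, same length as `t`.
#' @param discard_fraction fraction of the initial time span to drop,
#'   in `[0, 1)`; default 0.3.
#' @return time-weighted mean over the retained window.
#' @export
time_average <- function(t, x, discard_fraction = 0.3) {
  stopifnot(is.numeric(t), is.numeric(x), length(t) == length(x),
            length(discard_fraction) == 1L,
            discard_fraction >= 0, discard_fraction < 1)
  if (length(t) == 0L) stop("empty series", call. = FALSE)
  if (length(t) > 1L && any(diff(t) <= 0)) {
    stop("sample times must be strictly increasing", call. = FALSE)
  }
  t0 <- t[1L] + discard_fraction * (t[length(t)] - t[1L])
  keep <- t >= t0
  if (!any(keep)) stop("retained averaging window is empty", call. = FALSE)
  tk <- t[keep]
  xk <- x[keep]
  if (tk[1L] > t0 && !keep[1L]) {
    # interpolate the window edge so the discard is exact in time
    i <- max(which(!keep))
    w <- (t0 - t[i]) / (t[i + 1L] - t[i])
    tk <- c(t0, tk)
    xk <- c((1 - w) * x[i] + w * x[i + 1L], xk)
  }
  n <- length(tk)
  if (n == 1L) return(xk)
  dt <- diff(tk)
  sum(dt * (xk[-1L] + xk[-n]) / 2) / (tk[n] - tk[1L])
}

#' Forcing specification
#'
#' Which of the three global constraints is enforced for a run and its
#' constant target value: CFR fixes the volumetric flow rate Q0, CPG fixes
#' the ambient-to-throat pressure drop dp0 (stored positive), CPI fixes the
#' power input P0.
#'
#' @param mode one of `"CFR"`, `"CPG"`, `"CPI"`.
#' @param target positive scalar: Q0 (m^3/s), dp0 (Pa) or P0 (W) according
#'   to `mode`.
#' @return an object of class `forcing_spec`.
#' @export
forcing_spec <- function(mode = c("CFR", "CPG", "CPI"), target) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(target), length(target) == 1L, is.finite(target))
  if (target <= 0) stop("forcing target must be > 0", call. = FALSE)
  structure(list(mode = mode, target = target), class = "forcing_spec")
}

#' @export
print.forcing_spec <- function(x, ...) {
  units <- switch(x$mode, CFR = "m^3/s", CPG = "Pa", CPI = "W")
  cat(sprintf("<forcing_spec> %s at %s %s\n", x$mode, format(x$target), units))
  invisible(x)
}

#' Time-averaged global quantities of one run
#'
#' Container for the mean flow rate, pressure drop, power and the derived
#' nasal resistance `R = dp_mean / Q_mean`. `P_mean` defaults to the product
#' `Q_mean * dp_mean`; a solver that averages the instantaneous power can
#' supply it explicitly.
#'
#' @param Q_mean mean flow rate (m^3/s), > 0.
#' @param dp_mean mean pressure drop (Pa), > 0.
#' @param P_mean mean power (W); default `Q_mean * dp_mean`.
#' @return an object of class `global_quantities`.
#' @export
global_quantities <- function(Q_mean, dp_mean, P_mean = Q_mean * dp_mean) {
  stopifnot(is.numeric(Q_mean), is.numeric(dp_mean), is.numeric(P_mean),
            length(Q_mean) == 1L, length(dp_mean) == 1L, length(P_mean) == 1L)
  if (Q_mean <= 0 || dp_mean <= 0 || P_mean <= 0) {
    stop("global quantities of a converged inspiration run must be positive",
         call. = FALSE)
  }
  structure(list(Q_mean = Q_mean, dp_mean = dp_mean, P_mean = P_mean,
                 R = dp_mean / Q_mean),
            class = "global_quantities")
}

#' @export
print.global_quantities <- function(x, ...) {
  cat("<global_quantities>\n")
  cat(sprintf("  Q  = %.4g m^3/s  (%.2f l/min)\n", x$Q_mean, x$Q_mean * 6e4))
  cat(sprintf("  dp = %.4g Pa\n", x$dp_mean))
  cat(sprintf("  P  = %.4g W  (%.2f mW)\n", x$P_mean, x$P_mean * 1e3))
  cat(sprintf("  R  = %.4g Pa s/m^3  (%.2f x 10^4)\n", x$R, x$R / 1e4))
  invisible(x)
}

#' Serialize global quantities to JSON
#'
#' Writes keys `Q_mean`, `dp_mean`, `P_mean`, `R` plus a `units` block.
#'
#' @param gq a [global_quantities()] object.
#' @param path output file; if `NULL`, the JSON string is returned.
#' @export
write_global_quantities <- function(gq, path = NULL) {
  stopifnot(inherits(gq, "global_quantities"))
  obj <- list(Q_mean = gq$Q_mean, dp_mean = gq$dp_mean,
              P_mean = gq$P_mean, R = gq$R,
              units = list(Q_mean = "m^3/s", dp_mean = "Pa",
                           P_mean = "W", R = "Pa*s/m^3"))
  if (is.null(path)) {
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}

#' Read global quantities from JSON
#'
#' @param path file written by [write_global_quantities()].
#' @return a [global_quantities()] object.
#' @export
read_global_quantities <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  global_quantities(obj$Q_mean, obj$dp_mean, obj$P_mean)
}

#' Write a time series of global flow state
#'
#' CSV schema shared by all solvers: columns `t`, `Q`, `p_th`, `P` in SI
#' units (s, m^3/s, Pa, W).
#'
#' @param series data.frame with columns `t`, `Q`, `p_th`, `P`.
#' @param path output CSV path.
#' @export
write_flow_series <- function(series, path) {
  stopifnot(is.data.frame(series),
            all(c("t", "Q", "p_th", "P") %in% names(series)))
  utils::write.csv(series[, c("t", "Q", "p_th", "P")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_flow_series
#' @export
read_flow_series <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("t", "Q", "p_th", "P") %in% names(df)))
  df
}
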