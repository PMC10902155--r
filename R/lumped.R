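#' Quasi-steady lumped-parameter airway models
#'
#' A nasal airway reduced to three resistive elements: two parallel nasal
#' passages (left and right) in series with a common pharyngeal segment.
#' Each element follows a pressure--flow law `dp(Q) = a*Q + b*Q^2`, blending
#' a viscous (linear) and an inertial (quadratic) contribution: nasal flow is
#' transitional, with coexisting laminar and subcritical turbulent regions,
#' so neither limit alone is realistic. The network provides fast,
#' analytically checkable steady states under each forcing.
#'
#' @name lumped-airway
NULL

#' Pressure--flow law of one airway segment
#'
#' @param a linear coefficient (Pa s/m^3), >= 0.
#' @param b quadratic coefficient (Pa s^2/m^6), >= 0.
#' @param label free-text description.
#' @return an object of class `segment_law`.
#' @export
segment_law <- function(a, b, label = "") {
  stopifnot(is.numeric(a), is.numeric(b), length(a) == 1L, length(b) == 1L,
            is.finite(a), is.finite(b))
  if (a < 0 || b < 0) stop("segment coefficients must be >= 0", call. = FALSE)
  if (a + b <= 0) stop("segment must have nonzero resistance", call. = FALSE)
  structure(list(a = a, b = b, label = as.character(label)),
            class = "segment_law")
}

segment_dp <- function(seg, Q) seg$a * Q + seg$b * Q^2

#' Lumped airway network
#'
#' Two parallel nasal branches in series with a common (pharynx/throat)
#' segment. For a degenerate single-duct model see
#' [airway_network_single()].
#'
#' @param left,right,common [segment_law()] objects.
#' @return an object of class `airway_network`.
#' @export
airway_network <- function(left, right, common) {
  stopifnot(inherits(left, "segment_law"), inherits(right, "segment_law"),
            inherits(common, "segment_law"))
  structure(list(left = left, right = right, common = common),
            class = "airway_network")
}

#' Degenerate single-segment network
#'
#' Convenience constructor for a network whose total law equals a single
#' segment `dp(Q) = a*Q + b*Q^2`: two identical branches each carrying half
#' the flow plus a zero-resistance-free common segment is impossible with
#' strictly positive laws, so the branch coefficients are doubled/quadrupled
#' to compensate for the parallel split.
#'
#' @param a,b total linear and quadratic coefficients.
#' @return an `airway_network` with `dp_of_Q(net, Q) == a*Q + b*Q^2`.
#' @export
airway_network_single <- function(a, b) {
  # two identical branches at Q/2 each: dp_branch = (2a)(Q/2) + (4b)(Q/2)^2
  eps <- .Machine$double.xmin
  airway_network(left = segment_law(2 * a + eps, 4 * b, "half"),
                 right = segment_law(2 * a + eps, 4 * b, "half"),
                 common = segment_law(eps, 0, "null"))
}

#' @export
print.airway_network <- function(x, ...) {
  cat("<airway_network>\n")
  for (nm in c("left", "right", "common")) {
    s <- x[[nm]]
    cat(sprintf("  %-6s a = %.6g Pa s/m^3, b = %.6g Pa s^2/m^6  %s\n",
                nm, s$a, s$b, s$label))
  }
  invisible(x)
}

# Equilibrium split of total flow Q between the two parallel branches:
# Q_left + Q_right = Q with equal branch pressure drops. The difference of
# branch drops is strictly increasing in Q_left, so bisection via uniroot on
# [0, Q] is unconditionally safe.
branch_split <- function(model, Q) {
  if (Q == 0) return(c(left = 0, right = 0))
  f <- function(qL) segment_dp(model$left, qL) - segment_dp(model$right, Q - qL)
  if (f(0) >= 0) return(c(left = 0, right = Q))
  if (f(Q) <= 0) return(c(left = Q, right = 0))
  r <- stats::uniroot(f, c(0, Q), tol = .Machine$double.eps * max(1, Q))
  qL <- r$root
  c(left = qL, right = Q - qL)
}

#' Total pressure drop of the network at a given flow rate
#'
#' Common-segment drop plus the unique parallel-branch drop such that branch
#' flows are nonnegative, sum to `Q` and give equal branch drops.
#'
#' @param model an [airway_network()].
#' @param Q total flow rate (m^3/s), >= 0.
#' @return pressure drop (Pa); `dp_of_Q(model, 0) == 0`.
#' @export
dp_of_Q <- function(model, Q) {
  stopifnot(inherits(model, "airway_network"), is.numeric(Q))
  vapply(Q, function(q) {
    if (q < 0) stop("dp_of_Q requires Q >= 0", call. = FALSE)
    if (q == 0) return(0)
    sp <- branch_split(model, q)
    dpb <- if (sp[["left"]] > 0) segment_dp(model$left, sp[["left"]])
           else segment_dp(model$right, sp[["right"]])
    segment_dp(model$common, q) + dpb
  }, numeric(1))
}

#' Calibrate a network to a reference operating point
#'
#' Builds a network whose total drop at the reference flow rate `Q0` equals
#' `dp0` exactly, for any blend between linear and quadratic behaviour, any
#' left/right flow split at reference, and any share of the drop assigned to
#' the common segment.
#'
#' @param Q0 reference flow rate (m^3/s); default 2.67e-4 (about 16 l/min,
#'   mild steady inspiration).
#' @param dp0 reference pressure drop (Pa); default 24.45.
#' @param blend lambda in `[0, 1]`: fraction of each element's reference drop
#'   carried by the linear term (1 = fully linear, 0 = fully quadratic).
#' @param split fraction of `Q0` through the left branch at reference;
#'   default 0.5.
#' @param common_fraction fraction of `dp0` across the common segment;
#'   default 0.2.
#' @return an [airway_network()] with `dp_of_Q(net, Q0) == dp0` to
#'   1e-10 relative.
#' @export
calibrate_airway <- function(Q0 = 2.67e-4, dp0 = 24.45, blend = 0.5,
                             split = 0.5, common_fraction = 0.2) {
  stopifnot(Q0 > 0, dp0 > 0, blend >= 0, blend <= 1,
            split > 0, split < 1, common_fraction >= 0, common_fraction < 1)
  seg_for <- function(dp_ref, Q_ref, label) {
    segment_law(a = blend * dp_ref / Q_ref,
                b = (1 - blend) * dp_ref / Q_ref^2,
                label = label)
  }
  dp_c <- common_fraction * dp0
  dp_b <- dp0 - dp_c
  common <- if (dp_c > 0) seg_for(dp_c, Q0, "pharynx") else
    segment_law(.Machine$double.xmin, 0, "pharynx")
  airway_network(left = seg_for(dp_b, split * Q0, "left passage"),
                 right = seg_for(dp_b, (1 - split) * Q0, "right passage"),
                 common = common)
}

#' Apply a virtual surgery to one nasal side
#'
#' A resistance-lowering operation (for example a medial maxillectomy, which
#' enlarges the operated meatus) is represented by scaling both coefficients
#' of one branch by a common factor in `(0, 1]`; the contralateral branch and
#' the common segment are untouched.
#'
#' @param model an [airway_network()].
#' @param side `"left"` or `"right"`.
#' @param factor coefficient multiplier in `(0, 1]`; 1 is the identity.
#' @return the modified network.
#' @export
apply_virtual_surgery <- function(model, side = c("right", "left"), factor) {
  stopifnot(inherits(model, "airway_network"),
            is.numeric(factor), length(factor) == 1L)
  side <- match.arg(side)
  if (factor <= 0 || factor > 1) {
    stop("surgery factor must lie in (0, 1]", call. = FALSE)
  }
  seg <- model[[side]]
  model[[side]] <- segment_law(seg$a * factor, seg$b * factor,
                               label = paste(seg$label, "(operated)"))
  model
}

# grow a bracket [lo, hi] until fn changes sign; fn(lo) < 0 expected
grow_bracket <- function(fn, lo, hi) {
  flo <- fn(lo)
  if (flo > 0) stop("root bracketing failed: fn(", format(lo), ") = ",
                    format(flo), " > 0", call. = FALSE)
  for (i in 1:200) {
    if (fn(hi) >= 0) return(c(lo, hi))
    hi <- hi * 2
  }
  stop("root bracketing failed: no sign change up to Q = ", format(hi),
       call. = FALSE)
}

#' Steady state of a lumped network under a global forcing
#'
#' CFR returns `Q = Q0` directly; CPG and CPI solve the monotone relations
#' `dp_of_Q(Q) = dp0` and `Q * dp_of_Q(Q) = P0` by bracketed root-finding.
#' The residual of the active constraint is driven below 1e-12 relative.
#'
#' @param model an [airway_network()].
#' @param forcing a [forcing_spec()].
#' @return a [global_quantities()] object.
#' @export
solve_steady <- function(model, forcing) {
  stopifnot(inherits(model, "airway_network"), inherits(forcing, "forcing_spec"))
  Q <- switch(forcing$mode,
    CFR = forcing$target,
    CPG = {
      fn <- function(q) dp_of_Q(model, q) - forcing$target
      br <- grow_bracket(fn, 0, 1e-4)
      stats::uniroot(fn, br, tol = 1e-15 * max(1, br[2]))$root
    },
    CPI = {
      fn <- function(q) q * dp_of_Q(model, q) - forcing$target
      br <- grow_bracket(fn, 0, 1e-4)
      stats::uniroot(fn, br, tol = 1e-15 * max(1, br[2]))$root
    })
  # polish the root on the monotone map (uniroot tol is on x, not residual)
  if (forcing$mode != "CFR") {
    target <- forcing$target
    g <- switch(forcing$mode,
                CPG = function(q) dp_of_Q(model, q),
                CPI = function(q) q * dp_of_Q(model, q))
    for (i in 1:50) {
      res <- g(Q) - target
      if (abs(res) <= 1e-13 * target) break
      h <- Q * 1e-7
      dg <- (g(Q + h) - g(Q - h)) / (2 * h)
      Q <- Q - res / dg
    }
  }
  dp <- dp_of_Q(model, Q)
  global_quantities(Q_mean = Q, dp_mean = dp)
}

#' Per-side (lateral) resistances at a converged state
#'
#' The per-branch `dp_branch / Q_branch` at the equilibrium branch split
#' corresponding to the state's total flow rate. Clinically these are the
#' per-nostril resistances; their relative change under surgery is even
#' larger than that of the total resistance.
#'
#' @param model an [airway_network()].
#' @param state a [global_quantities()] object from [solve_steady()].
#' @return named numeric vector `c(left = , right = )` (Pa s/m^3).
#' @export
lateral_resistances <- function(model, state) {
  stopifnot(inherits(model, "airway_network"),
            inherits(state, "global_quantities"))
  sp <- branch_split(model, state$Q_mean)
  if (any(sp <= 0)) stop("a branch carries no flow; lateral resistance undefined",
                         call. = FALSE)
  dpb <- segment_dp(model$left, sp[["left"]])
  c(left = dpb / sp[["left"]], right = dpb / sp[["right"]])
}

#' Under-relaxed quasi-steady CPI iteration
#'
#' Mimics the time-stepping CPI controller on a quasi-steady model: given a
#' pressure drop, the model answers with the flow rate `Q = g(dp)` (a CPG
#' solve); the controller then proposes `P0 / Q` as the next drop. The raw
#' map is neutrally stable (it 2-cycles on a linear model), so the update is
#' under-relaxed, `dp <- (1 - relax) * dp + relax * P0 / Q`. Converges to the
#' same fixed point as the direct root-find in [solve_steady()], at which
#' `Q * dp = P0` exactly.
#'
#' @param model an [airway_network()].
#' @param P0 power target (W).
#' @param dp_init initial pressure-drop guess (Pa).
#' @param relax relaxation factor in `(0, 1]`; default 0.5.
#' @param tol relative convergence tolerance on dp; default 1e-12.
#' @param max_iter iteration cap.
#' @return list with `Q`, `dp`, `iterations`, `converged`.
#' @export
cpi_fixed_point <- function(model, P0, dp_init, relax = 0.5,
                            tol = 1e-12, max_iter = 1000L) {
  stopifnot(P0 > 0, dp_init > 0, relax > 0, relax <= 1)
  dp <- dp_init
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Q <- solve_steady(model, forcing_spec("CPG", dp))$Q_mean
    dp_new <- (1 - relax) * dp + relax * P0 / Q
    if (abs(dp_new - dp) <= tol * dp) {
      dp <- dp_new
      converged <- TRUE
      break
    }
    dp <- dp_new
  }
  Q <- solve_steady(model, forcing_spec("CPG", dp))$Q_mean
  list(Q = Q, dp = dp, iterations = it, converged = converged)
}

#' Serialize an airway network to the key = value text dialect
#'
#' Keys `left.a`, `left.b`, `right.a`, `right.b`, `common.a`, `common.b`
#' (SI units), one per line.
#'
#' @param model an [airway_network()].
#' @param path output file; if `NULL` the text is returned as a character
#'   vector.
#' @export
write_airway_network <- function(model, path = NULL) {
  stopifnot(inherits(model, "airway_network"))
  lines <- unlist(lapply(c("left", "right", "common"), function(nm) {
    s <- model[[nm]]
    c(sprintf("%s.a = %.17g", nm, s$a), sprintf("%s.b = %.17g", nm, s$b))
  }))
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_airway_network
#' @param text alternatively, the serialized lines themselves.
#' @export
read_airway_network <- function(path = NULL, text = NULL) {
  lines <- if (is.null(text)) readLines(path) else text
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, character(1), 1L)
  vals <- as.numeric(vapply(kv, `[`, character(1), 2L))
  need <- c("left.a", "left.b", "right.a", "right.b", "common.a", "common.b")
  if (!setequal(keys, need)) {
    stop("airway network file must define exactly: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  names(vals) <- keys
  airway_network(
    left = segment_law(vals[["left.a"]], vals[["left.b"]], "left passage"),
    right = segment_law(vals[["right.a"]], vals[["right.b"]], "right passage"),
    common = segment_law(vals[["common.a"]], vals[["common.b"]], "pharynx"))
}
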