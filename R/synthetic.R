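#' Synthetic pre/post case generation
#'
#' Generates matched pre/post model pairs emulating a unilateral,
#' resistance-lowering nasal surgery, for either backend, with controllable
#' severity and seeded nuisance-parameter jitter. Jitter touches only the
#' nuisance parameters (left/right asymmetry and the linear/quadratic blend),
#' never the calibration point, so the pre-operative model always reproduces
#' the reference operating point exactly.
#'
#' @name synthetic-case
NULL

#' Recipe for one synthetic pre/post pair
#'
#' @param backend `"lumped"` or `"duct"`.
#' @param severity coefficient-reduction factor of the operated side, in
#'   `(0, 1]`; 1 is the identity surgery. Default 0.754, which on a pure
#'   quadratic single-passage model lowers the constant-flow pressure drop
#'   by 24.6 percent.
#' @param asymmetry pre-operative left/right imbalance in `(-1, 1)`: the
#'   left passage carries a fraction `(1 + asymmetry) / 2` of the reference
#'   flow. Default 0.
#' @param blend linear/quadratic blend of the lumped elements in `[0, 1]`;
#'   default 0.5.
#' @param seed integer seed controlling the jitter.
#' @param noise relative jitter amplitude on the nuisance parameters;
#'   default 0.
#' @param Q0,dp0 calibration point of the pre-operative model; defaults
#'   2.67e-4 m^3/s and 24.45 Pa (mild steady inspiration).
#' @param duct list of duct-backend settings: `L`, `H`, `nx`, `ny`,
#'   `depth_pre` (pre-operative constriction depth).
#' @return an object of class `case_recipe`.
#' @export
case_recipe <- function(backend = c("lumped", "duct"), severity = 0.754,
                        asymmetry = 0, blend = 0.5, seed = 1L, noise = 0,
                        Q0 = 2.67e-4, dp0 = 24.45,
                        duct = list(L = 2, H = 1, nx = 32, ny = 32,
                                    depth_pre = 0.5)) {
  backend <- match.arg(backend)
  stopifnot(severity > 0, severity <= 1, noise >= 0,
            asymmetry > -1, asymmetry < 1, blend >= 0, blend <= 1,
            Q0 > 0, dp0 > 0)
  structure(list(backend = backend, severity = severity,
                 asymmetry = asymmetry, blend = blend,
                 seed = as.integer(seed), noise = noise,
                 Q0 = Q0, dp0 = dp0, duct = duct),
            class = "case_recipe")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate a matched pre/post model pair
#'
#' Deterministic given the recipe (including its seed). The lumped
#' pre-operative network is calibrated to the reference point `(Q0, dp0)`;
#' the post-operative network applies the surgery factor to the right
#' passage. The duct pair shares one channel; the surgery lowers the
#' constriction depth by the severity factor.
#'
#' @param recipe a [case_recipe()].
#' @return a list of class `synthetic_case` with `pre`, `post`, `recipe`
#'   and `metadata` (including the achieved resistance factor).
#' @export
make_case <- function(recipe) {
  stopifnot(inherits(recipe, "case_recipe"))
  set.seed(recipe$seed)
  blend <- recipe$blend
  asym <- recipe$asymmetry
  if (recipe$noise > 0) {
    blend <- clamp(blend * (1 + recipe$noise * stats::rnorm(1)), 0, 1)
    asym <- clamp(asym + recipe$noise * stats::rnorm(1), -0.9, 0.9)
  }
  split <- (1 + asym) / 2

  if (recipe$backend == "lumped") {
    pre <- calibrate_airway(Q0 = recipe$Q0, dp0 = recipe$dp0, blend = blend,
                            split = split)
    post <- apply_virtual_surgery(pre, "right", recipe$severity)
    achieved <- dp_of_Q(post, recipe$Q0) / dp_of_Q(pre, recipe$Q0)
  } else {
    d <- recipe$duct
    pre <- duct_geometry(L = d$L, H = d$H, nx = d$nx, ny = d$ny,
                         depth = d$depth_pre)
    post <- duct_geometry(L = d$L, H = d$H, nx = d$nx, ny = d$ny,
                          depth = d$depth_pre * recipe$severity)
    # lubrication estimate of the resistance factor; the solver measures the
    # exact value at run time
    cfg0 <- solver_config(rho = 1, nu = 1)
    achieved <- lubrication_resistance(build_grid(post), cfg0) /
      lubrication_resistance(build_grid(pre), cfg0)
  }
  structure(list(pre = pre, post = post, recipe = recipe,
                 metadata = list(blend = blend, split = split,
                                 surgery_factor = recipe$severity,
                                 achieved_resistance_factor = achieved,
                                 seed = recipe$seed)),
            class = "synthetic_case")
}

#' @export
print.synthetic_case <- function(x, ...) {
  cat(sprintf("<synthetic_case> %s backend, severity %.3g, achieved R factor %.3g\n",
              x$recipe$backend, x$recipe$severity,
              x$metadata$achieved_resistance_factor))
  invisible(x)
}

#' Run a comparison for every recipe in a collection
#'
#' Individual failures are caught and recorded; the sweep continues.
#'
#' @param recipes non-empty list of [case_recipe()] objects.
#' @param cfg optional [solver_config()] for duct recipes.
#' @return a list with `reports` (one `comparison_report` or error condition
#'   per recipe) and `summary`, a data.frame of recipe parameters and
#'   percentage resistance changes per forcing.
#' @export
sweep_cases <- function(recipes, cfg = NULL) {
  if (!is.list(recipes) || length(recipes) == 0L) {
    stop("sweep requires a non-empty collection of recipes", call. = FALSE)
  }
  reports <- lapply(recipes, function(rc) {
    tryCatch({
      case <- make_case(rc)
      run_comparison(case$pre, case$post,
                     reference_forcing = forcing_spec("CFR", rc$Q0),
                     backend = rc$backend, cfg = cfg)
    }, error = function(e) e)
  })
  summary <- do.call(rbind, lapply(seq_along(recipes), function(k) {
    rc <- recipes[[k]]
    rep <- reports[[k]]
    ok <- inherits(rep, "comparison_report")
    data.frame(case = k, backend = rc$backend, severity = rc$severity,
               blend = rc$blend, asymmetry = rc$asymmetry, seed = rc$seed,
               ok = ok,
               dR_CFR = if (ok) rep$rows$CFR$pct[["R"]] else NA_real_,
               dR_CPG = if (ok) rep$rows$CPG$pct[["R"]] else NA_real_,
               dR_CPI = if (ok) rep$rows$CPI$pct[["R"]] else NA_real_,
               error = if (ok) "" else conditionMessage(rep))
  }))
  list(reports = reports, summary = summary)
}
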