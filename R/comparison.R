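#' Pre/post comparison engine
#'
#' Orchestrates the six-run protocol for comparing two airway models: the
#' pre-operative model is solved once under a reference forcing, yielding the
#' self-consistent reference triple (Q0, dp0, P0 = Q0*dp0); the pre-operative
#' model is then re-solved under the other two forcings as a consistency
#' check (a single anatomy must give the same answer under all three), and
#' the post-operative model is solved three times, enforcing Q0, dp0 and P0
#' in turn. The report tabulates global quantities and percentage changes
#' per forcing, in the layout used for published nasal-resistance
#' comparisons.
#'
#' @name comparison-engine
NULL

#' Reference triple of a pre-operative run
#'
#' @param Q0 reference flow rate (m^3/s).
#' @param dp0 reference pressure drop (Pa).
#' @param P0 reference power (W); default `Q0 * dp0`, and the triple must be
#'   self-consistent to 1e-8 relative.
#' @return an object of class `reference_triple`.
#' @export
reference_triple <- function(Q0, dp0, P0 = Q0 * dp0) {
  stopifnot(Q0 > 0, dp0 > 0, P0 > 0)
  if (abs(P0 - Q0 * dp0) > 1e-8 * P0) {
    stop("reference triple is not self-consistent: |P0 - Q0*dp0| > 1e-8 rel",
         call. = FALSE)
  }
  structure(list(Q0 = Q0, dp0 = dp0, P0 = P0), class = "reference_triple")
}

# backend dispatch: returns global_quantities for one (model, forcing) run
solve_case <- function(model, forcing, backend, cfg = NULL, warm_Q = NULL) {
  switch(backend,
    lumped = solve_steady(model, forcing),
    duct = {
      if (is.null(cfg)) cfg <- solver_config()
      if (forcing$mode == "CPI" && !is.null(warm_Q) && is.null(cfg$cpi_warm_Q)) {
        cfg$cpi_warm_Q <- warm_Q
      }
      duct_run_case(model, forcing, cfg)$globals
    },
    stop("unknown backend: ", backend, call. = FALSE))
}

comparison_row <- function(pre, post) {
  list(pre = pre, post = post,
       pct = c(Q = percent_change(pre$Q_mean, post$Q_mean),
               dp = percent_change(pre$dp_mean, post$dp_mean),
               P = percent_change(pre$P_mean, post$P_mean),
               R = percent_change(pre$R, post$R)))
}

#' Run a full pre/post comparison under all three forcings
#'
#' @param pre_model,post_model airway models for the chosen backend: an
#'   [airway_network()] (`backend = "lumped"`) or a [duct_geometry()]
#'   (`backend = "duct"`).
#' @param reference_forcing the forcing of the calibration run on the
#'   pre-operative model; default CFR at 2.67e-4 m^3/s (mild inspiration).
#' @param backend `"lumped"` or `"duct"`.
#' @param cfg a [solver_config()] for the duct backend.
#' @param consistency_tol admissible relative spread of the pre-operative
#'   global quantities across the three forcings; default 1e-8 (lumped) or
#'   2e-2 (duct).
#' @return an object of class `comparison_report`.
#' @export
run_comparison <- function(pre_model, post_model,
                           reference_forcing = forcing_spec("CFR", 2.67e-4),
                           backend = c("lumped", "duct"),
                           cfg = NULL, consistency_tol = NULL) {
  backend <- match.arg(backend)
  if (is.null(consistency_tol)) {
    consistency_tol <- if (backend == "lumped") 1e-8 else 2e-2
  }

  # run 1: pre-op under the reference forcing -> reference triple
  pre_ref <- solve_case(pre_model, reference_forcing, backend, cfg)
  triple <- reference_triple(pre_ref$Q_mean, pre_ref$dp_mean)

  targets <- list(CFR = triple$Q0, CPG = triple$dp0, CPI = triple$P0)

  # runs 2-3: pre-op under the other two forcings (consistency check)
  pre_runs <- list()
  pre_runs[[reference_forcing$mode]] <- pre_ref
  for (m in setdiff(names(targets), reference_forcing$mode)) {
    pre_runs[[m]] <- solve_case(pre_model, forcing_spec(m, targets[[m]]),
                                backend, cfg, warm_Q = triple$Q0)
    dev <- max(abs(pre_runs[[m]]$Q_mean / triple$Q0 - 1),
               abs(pre_runs[[m]]$dp_mean / triple$dp0 - 1))
    if (dev > consistency_tol) {
      stop(sprintf(
        "pre-op consistency check failed under %s: relative deviation %.3g > %.3g",
        m, dev, consistency_tol), call. = FALSE)
    }
  }

  # runs 4-6: post-op under the three forcings
  post_runs <- lapply(names(targets), function(m) {
    solve_case(post_model, forcing_spec(m, targets[[m]]), backend, cfg,
               warm_Q = triple$Q0)
  })
  names(post_runs) <- names(targets)

  rows <- lapply(c("CPG", "CFR", "CPI"), function(m) {
    comparison_row(pre_runs[[m]], post_runs[[m]])
  })
  names(rows) <- c("CPG", "CFR", "CPI")

  structure(list(rows = rows, triple = triple,
                 metadata = list(backend = backend,
                                 reference_forcing = reference_forcing$mode,
                                 n_runs = 6L,
                                 consistency_tol = consistency_tol)),
            class = "comparison_report")
}

#' Assemble a comparison report from externally supplied global values
#'
#' Report-only mode: no simulation is performed. Given the pre-operative
#' `(Q, dp)` pair and one `(Q, dp)` pair per forcing for the post-operative
#' case (for instance values transcribed from a published table), the
#' derived power `P = Q * dp`, resistance `R = dp / Q` and percentage
#' changes are computed. A post-operative CPI pair may omit `dp` (`NA`): it
#' is then filled in from the power constraint as `P0 / Q`.
#'
#' @param pre numeric `c(Q = , dp = )` for the pre-operative case.
#' @param post named list with elements `CFR`, `CPG`, `CPI`, each a numeric
#'   `c(Q = , dp = )`.
#' @return an object of class `comparison_report`.
#' @export
report_from_globals <- function(pre, post) {
  stopifnot(is.numeric(pre), length(pre) == 2L,
            is.list(post), setequal(names(post), c("CFR", "CPG", "CPI")))
  if (any(pre <= 0)) stop("pre-op values must be positive", call. = FALSE)
  pre_gq <- global_quantities(pre[[1L]], pre[[2L]])
  triple <- reference_triple(pre_gq$Q_mean, pre_gq$dp_mean)
  rows <- lapply(c("CPG", "CFR", "CPI"), function(m) {
    pp <- post[[m]]
    stopifnot(is.numeric(pp), length(pp) == 2L)
    Q <- pp[[1L]]; dp <- pp[[2L]]
    if (m == "CPI" && is.na(dp)) dp <- triple$P0 / Q
    if (!is.finite(Q) || Q <= 0 || !is.finite(dp) || dp <= 0) {
      stop("post-op values must be positive", call. = FALSE)
    }
    comparison_row(pre_gq, global_quantities(Q, dp))
  })
  names(rows) <- c("CPG", "CFR", "CPI")
  structure(list(rows = rows, triple = triple,
                 metadata = list(backend = "report_only",
                                 reference_forcing = NA_character_,
                                 n_runs = 0L)),
            class = "comparison_report")
}

#' Relative overestimation of the resistance reduction, CFR versus CPG
#'
#' How much larger the apparent post-operative resistance reduction is when
#' the comparison is run at constant flow rate instead of constant pressure
#' drop: `100 * (|%dR_CFR| - |%dR_CPG|) / |%dR_CPG|`. Both reductions must
#' be negative (the surgery lowers resistance).
#'
#' @param x a `comparison_report`, or a named numeric vector
#'   `c(CFR = , CPG = )` of signed resistance percentage changes.
#' @return the relative overestimation, in percent.
#' @export
resistance_reduction_overestimate <- function(x) {
  if (inherits(x, "comparison_report")) {
    x <- c(CFR = unname(x$rows$CFR$pct["R"]), CPG = unname(x$rows$CPG$pct["R"]))
  }
  stopifnot(is.numeric(x), all(c("CFR", "CPG") %in% names(x)))
  if (x[["CFR"]] >= 0 || x[["CPG"]] >= 0) {
    stop("both resistance changes must be reductions (negative)", call. = FALSE)
  }
  100 * (abs(x[["CFR"]]) - abs(x[["CPG"]])) / abs(x[["CPG"]])
}

# presentation rounding used by print/export: published precision (signif
# strips root-finder residuals of order 1e-13 before formatting)
fmt_row <- function(gq) {
  c(p_th = sprintf("%.1f", -signif(gq$dp_mean, 12)),
    Q = sprintf("%.2f", signif(gq$Q_mean, 12) / 1e-4),
    P = sprintf("%.2f", -signif(gq$P_mean, 12) * 1e3),
    R = sprintf("%.2f", signif(gq$R, 12) / 1e4))
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Global quantities under the three flow forcings\n")
  cat(sprintf("(backend: %s)\n\n", x$metadata$backend))
  hdr <- sprintf("%-22s", "")
  for (m in c("CPG", "CFR", "CPI")) hdr <- paste0(hdr, sprintf("%27s", m))
  cat(hdr, "\n")
  sub <- sprintf("%-22s", "")
  for (m in c("CPG", "CFR", "CPI")) {
    sub <- paste0(sub, sprintf("%9s%9s%9s", "pre", "post", "%chg"))
  }
  cat(sub, "\n")
  labels <- c(p_th = "p_th [Pa]", Q = "Q [1e-4 m^3/s]",
              P = "P [1e-3 W]", R = "R [1e4 Pa s/m^3]")
  enforced <- c(CPG = "dp", CFR = "Q", CPI = "P")
  qty_of <- c(p_th = "dp", Q = "Q", P = "P", R = "R")
  for (q in names(labels)) {
    line <- sprintf("%-22s", labels[[q]])
    for (m in c("CPG", "CFR", "CPI")) {
      row <- x$rows[[m]]
      pre_s <- fmt_row(row$pre)[[q]]
      post_s <- fmt_row(row$post)[[q]]
      pct_s <- if (enforced[[m]] == qty_of[[q]]) "-" else
        sprintf("%.1f", row$pct[[qty_of[[q]]]])
      line <- paste0(line, sprintf("%9s%9s%9s", pre_s, post_s, pct_s))
    }
    cat(line, "\n")
  }
  invisible(x)
}

report_data_frame <- function(report) {
  out <- do.call(rbind, lapply(c("CPG", "CFR", "CPI"), function(m) {
    row <- report$rows[[m]]
    data.frame(forcing = m,
               variant = c("pre", "post", "pct_change"),
               Q = c(row$pre$Q_mean, row$post$Q_mean, row$pct[["Q"]]),
               dp = c(row$pre$dp_mean, row$post$dp_mean, row$pct[["dp"]]),
               P = c(row$pre$P_mean, row$post$P_mean, row$pct[["P"]]),
               R = c(row$pre$R, row$post$R, row$pct[["R"]]))
  }))
  rownames(out) <- NULL
  out
}

#' Export a comparison report
#'
#' Writes three renderings: CSV (one row per forcing and variant), JSON, and
#' a plain-text table in the published layout.
#'
#' @param report a `comparison_report`.
#' @param dir output directory (created if missing).
#' @param basename stem of the output files; default `"report"`.
#' @return paths of the written files, invisibly.
#' @export
write_comparison_report <- function(report, dir, basename = "report") {
  stopifnot(inherits(report, "comparison_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(basename, c(".csv", ".json", ".txt")))
  utils::write.csv(report_data_frame(report), paths[1L], row.names = FALSE)
  obj <- list(rows = lapply(report$rows, function(r) list(
    pre = r$pre[c("Q_mean", "dp_mean", "P_mean", "R")],
    post = r$post[c("Q_mean", "dp_mean", "P_mean", "R")],
    pct_change = as.list(r$pct))),
    triple = unclass(report$triple), metadata = report$metadata)
  jsonlite::write_json(obj, paths[2L], auto_unbox = TRUE, digits = NA,
                       null = "null")
  writeLines(utils::capture.output(print(report)), paths[3L])
  invisible(paths)
}
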