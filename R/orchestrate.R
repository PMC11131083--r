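#' Run one steady problem with a chosen solver
#'
#' Thin dispatcher used by the experiment runners: `"analytic"` calls
#' [core_shell_steady()], `"fv"` calls [steady_state_fv()], `"fe"` calls
#' [steady_state_fe()], `"fv_transient"` runs [run_transient_fv()] to its
#' long-time limit.
#'
#' @param prob a [drying_problem()].
#' @param solver one of `"analytic"`, `"fv"`, `"fe"`, `"fv_transient"`.
#' @param ... solver-specific arguments (mesh resolutions, tolerances,
#'   `t_end` for the transient).
#' @return A list with at least `p_gas`, `r_in`, `r_out`; grid solvers also
#'   carry a `profile` data frame.
#' @export
solve_steady <- function(prob, solver = c("analytic", "fv", "fe",
                                          "fv_transient"), ...) {
  solver <- match.arg(solver)
  switch(solver,
         analytic = core_shell_steady(prob, ...),
         fv = steady_state_fv(prob, ...),
         fe = {
           s <- steady_state_fe(prob, ...)
           s$Lambda_in <- s$r_in / prob$geom$R_in
           s
         },
         fv_transient = {
           s <- run_transient_fv(prob, ...)
           s$Lambda_in <- s$r_in / prob$geom$R_in
           s
         })
}

# max relative deviation between two lambda_theta profiles, interpolated on
# the common material-coordinate overlap
profile_deviation <- function(p1, p2, what = "lambda_theta") {
  lo <- max(min(p1$R), min(p2$R)); hi <- min(max(p1$R), max(p2$R))
  Rg <- seq(lo, hi, length.out = 101)
  v1 <- stats::approx(p1$R, p1[[what]], Rg)$y
  v2 <- stats::approx(p2$R, p2[[what]], Rg)$y
  max(abs(v1 - v2) / pmax(abs(v1), 1e-12))
}

#' Cross-solver comparison over a parameter grid
#'
#' Runs the selected steady solvers on every grid point and reports, per
#' point, the pairwise maximal relative deviation of the hoop-stretch profile
#' (interpolated to a common material grid; solvers without radial profiles
#' contribute their boundary stretches `Lambda_in`/`Lambda_out`) and of the
#' gas pressure.
#'
#' @param grid data frame with columns among `G_ratio`, `Pi_ext_over_G`,
#'   `R_in_frac`, `t_skin_frac`, `T`; one row per experiment.
#' @param solvers character vector of solvers, see [solve_steady()].
#' @param solver_args named list: per-solver argument lists.
#' @param lambda_tol,p_gas_tol tolerances used for the `flagged` column.
#' @param ... common [drying_problem()] arguments.
#' @return Data frame: the grid plus per-solver `p_gas_over_p0` and
#'   `Lambda_in` columns, the pairwise deviations `dev_lambda`, `dev_p_gas`,
#'   a `flagged` logical, and an `error` column recording solver failures.
#' @export
compare_solvers <- function(grid, solvers = c("analytic", "fv", "fe"),
                            solver_args = list(), lambda_tol = 0.02,
                            p_gas_tol = 0.05, ...) {
  stopifnot(nrow(grid) >= 1, length(solvers) >= 1)
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    args <- c(as.list(grid[i, , drop = FALSE]), list(...))
    prob <- do.call(drying_problem, args)
    sols <- list(); err <- character(0)
    for (sv in solvers) {
      s <- tryCatch(
        do.call(solve_steady,
                c(list(prob = prob, solver = sv),
                  solver_args[[sv]] %||% list())),
        error = function(e) e)
      if (inherits(s, "error")) err <- c(err, paste0(sv, ": ",
                                                     conditionMessage(s)))
      else sols[[sv]] <- s
    }
    dev_l <- dev_p <- NA_real_
    if (length(sols) >= 2) {
      nm <- names(sols)
      dev_l <- 0; dev_p <- 0
      for (a in seq_along(nm)) for (b in seq_len(a - 1L)) {
        sa <- sols[[nm[a]]]; sb <- sols[[nm[b]]]
        if (!is.null(sa$profile) && !is.null(sb$profile)) {
          dev_l <- max(dev_l, profile_deviation(sa$profile, sb$profile))
        } else {
          dev_l <- max(dev_l, abs(sa$Lambda_in - sb$Lambda_in) /
                         abs(sb$Lambda_in))
        }
        dev_p <- max(dev_p, abs(sa$p_gas - sb$p_gas) / abs(sb$p_gas))
      }
    }
    row <- grid[i, , drop = FALSE]
    for (sv in names(sols)) {
      row[[paste0("p_gas_over_p0_", sv)]] <- sols[[sv]]$p_gas / prob$gel$p0
      row[[paste0("Lambda_in_", sv)]] <- sols[[sv]]$Lambda_in
    }
    row$dev_lambda <- dev_l
    row$dev_p_gas <- dev_p
    row$flagged <- isTRUE(dev_l > lambda_tol) || isTRUE(dev_p > p_gas_tol)
    row$error <- paste(err, collapse = "; ")
    out[[i]] <- row
  }
  do.call(rbind, lapply(out, function(r) {
    miss <- setdiff(unique(unlist(lapply(out, names))), names(r))
    for (m in miss) r[[m]] <- NA
    r
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Critical skin stiffness for pore opening
#'
#' The steady-state pore exceeds its initial size exactly when the cavity gas
#' pressure falls below ambient; this scans/bisects the stiffness ratio
#' `G_skin/G_core` for the condition `-sigma_rr(r_in)/p0 - 1 = 0`
#' (equivalently steady `r_in = R_in`) and returns the threshold ratio.
#'
#' @param Pi_ext_over_G scaled external osmotic pressure (default 20).
#' @param R_in_frac,t_skin_frac geometry fractions (defaults 0.6, 0.05).
#' @param bracket initial bracket on the stiffness ratio.
#' @param tol absolute tolerance on the ratio.
#' @param solver steady solver to use (`"fv"` or `"analytic"`).
#' @param ... further [drying_problem()] or solver arguments (`T`, mesh
#'   sizes).
#' @param solver_args arguments passed to the steady solver.
#' @return List with `ratio` (the threshold), and `scan`, a data frame of the
#'   bisection history (ratio, p_gas/p0, Lambda_in).
#' @export
critical_stiffness_ratio <- function(Pi_ext_over_G = 20, R_in_frac = 0.6,
                                     t_skin_frac = 0.05,
                                     bracket = c(2, 40), tol = 0.1,
                                     solver = "fv", solver_args = list(),
                                     ...) {
  rows <- list()
  f <- function(ratio) {
    prob <- drying_problem(G_ratio = ratio, Pi_ext_over_G = Pi_ext_over_G,
                           R_in_frac = R_in_frac,
                           t_skin_frac = t_skin_frac, ...)
    s <- do.call(solve_steady, c(list(prob = prob, solver = solver),
                                 solver_args))
    rows[[length(rows) + 1L]] <<- data.frame(
      ratio = ratio, p_gas_over_p0 = s$p_gas / prob$gel$p0,
      Lambda_in = s$Lambda_in)
    s$p_gas / prob$gel$p0 - 1
  }
  lo <- bracket[1]; hi <- bracket[2]
  f_lo <- f(lo); f_hi <- f(hi)
  if (f_lo * f_hi > 0)
    stop("no sign change of p_gas - p0 in the stiffness bracket [",
         lo, ", ", hi, "]")
  # p_gas decreases with stiffness ratio: plain bisection
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f_lo * f(mid) <= 0) hi <- mid else lo <- mid
  }
  list(ratio = (lo + hi) / 2, scan = do.call(rbind, rows))
}

#' Steady gas pressure versus initial pore size
#'
#' Scans decreasing initial pore radii at fixed stiffness ratio and external
#' pressure; the steady gas pressure decreases monotonically towards a
#' positive limiting value as the pore shrinks.
#'
#' @param R_in_fracs initial pore radii as fractions of `R_out`.
#' @param Pi_ext_over_G,G_ratio,t_skin_frac experiment parameters (defaults:
#'   20, 20, 0.05).
#' @param solver steady solver (default `"fv"`).
#' @param solver_args passed to the solver.
#' @param ... further [drying_problem()] arguments.
#' @return Data frame: R_in_frac, p_gas_over_p0, Lambda_in, r_in_over_R_out,
#'   error.
#' @export
pore_size_scan <- function(R_in_fracs = c(0.6, 0.4, 0.3, 0.2, 0.1, 0.05),
                           Pi_ext_over_G = 20, G_ratio = 20,
                           t_skin_frac = 0.05, solver = "fv",
                           solver_args = list(), ...) {
  rows <- lapply(R_in_fracs, function(fr) {
    prob <- drying_problem(G_ratio = G_ratio,
                           Pi_ext_over_G = Pi_ext_over_G,
                           R_in_frac = fr, t_skin_frac = t_skin_frac, ...)
    s <- tryCatch(
      do.call(solve_steady, c(list(prob = prob, solver = solver),
                              solver_args)),
      error = function(e) e)
    if (inherits(s, "error"))
      return(data.frame(R_in_frac = fr, p_gas_over_p0 = NA, Lambda_in = NA,
                        r_in_over_R_out = NA, error = conditionMessage(s)))
    data.frame(R_in_frac = fr, p_gas_over_p0 = s$p_gas / prob$gel$p0,
               Lambda_in = s$Lambda_in,
               r_in_over_R_out = s$r_in / prob$geom$R_out, error = "")
  })
  do.call(rbind, rows)
}

#' Transient drying studies over a parameter grid
#'
#' Runs the finite-element transient over the grid and summarises each run
#' (final radii and pressures, presence of an air-pressure minimum and of a
#' temporary pore-radius extremum).
#'
#' @param grid data frame with columns among `G_ratio`, `Pi_ext_over_G`,
#'   `R_in_frac`, `t_skin_frac`, `T`.
#' @param n_core,n_skin FE elements per layer.
#' @param ... further [drying_problem()] or [run_transient_fe()] arguments.
#' @return List with `summary` (one row per run) and `runs` (the time-series
#'   data frames).
#' @export
transient_study <- function(grid, n_core = 16, n_skin = 6, ...) {
  dots <- list(...)
  fe_args <- dots[names(dots) %in% names(formals(run_transient_fe))]
  prob_args <- dots[!names(dots) %in% names(fe_args)]
  runs <- vector("list", nrow(grid))
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    args <- c(as.list(grid[i, , drop = FALSE]), prob_args)
    prob <- do.call(drying_problem, args)
    s <- tryCatch(
      do.call(run_transient_fe,
              c(list(prob = prob, n_core = n_core, n_skin = n_skin),
                fe_args)),
      error = function(e) e)
    if (inherits(s, "error")) {
      rows[[i]] <- cbind(grid[i, , drop = FALSE],
                         data.frame(r_in_over_R_in = NA, r_out_over_R_out = NA,
                                    p_gas_over_p0 = NA, p_air_min_over_p0 = NA,
                                    air_min_interior = NA, r_in_extremum = NA,
                                    error = conditionMessage(s)))
      next
    }
    tt <- s$times
    i_min <- which.min(tt$p_air)
    r_in_path <- tt$r_in / prob$geom$R_in
    interior_ext <- any(diff(sign(diff(r_in_path))) != 0)
    rows[[i]] <- cbind(grid[i, , drop = FALSE], data.frame(
      r_in_over_R_in = s$r_in / prob$geom$R_in,
      r_out_over_R_out = s$r_out / prob$geom$R_out,
      p_gas_over_p0 = s$p_gas / prob$gel$p0,
      p_air_min_over_p0 = tt$p_air[i_min] / prob$gel$p0,
      air_min_interior = i_min > 1 && i_min < nrow(tt),
      r_in_extremum = interior_ext,
      error = ""))
    runs[[i]] <- tt
  }
  list(summary = do.call(rbind, rows), runs = runs)
}
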