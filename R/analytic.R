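#' Pressure drop over a uniformly swollen spherical shell
#'
#' Closed-form integral of the radial momentum balance across a homogeneous
#' Neo-Hookean shell with uniform swelling:
#' `dp = (G/2) * [ (1 + 4*phi*La^3)/(phi*La^4) - (1 + 4*phi*Lb^3)/(phi*Lb^4) ]`.
#' The antiderivative `F(L) = (G/2)(1 + 4*phi*L^3)/(phi*L^4)` satisfies
#' `F'(L) = dsigma_rr/dL`, so the returned value is
#' `sigma_rr` at the surface with hoop stretch `Lambda_a` minus `sigma_rr` at
#' the surface with `Lambda_b`.  Stretches and the swelling measure are taken
#' with respect to the unstretched (elastically relaxed) configuration:
#' `Lambda = lambda0 * lambda` and `phi_hat = phi/phi_ref`, with the shell's
#' uniform volume ratio `J_e = 1/phi_hat`.
#'
#' @param phi_hat uniform swelling measure of the shell (> 0).
#' @param Lambda_a,Lambda_b hoop stretches at the two shell surfaces (> 0).
#' @param G shear modulus (Pa).
#' @return Pressure drop (Pa); antisymmetric under swap of the stretches.
#' @export
shell_pressure_drop <- function(phi_hat, Lambda_a, Lambda_b, G) {
  stopifnot(all(phi_hat > 0), all(Lambda_a > 0), all(Lambda_b > 0))
  f <- function(L) (1 + 4 * phi_hat * L^3) / (phi_hat * L^4)
  G / 2 * (f(Lambda_a) - f(Lambda_b))
}

#' Swelling measure from chemical equilibrium at a layer boundary
#'
#' At a boundary carrying radial traction `-(p0 + p_offset)`, the liquid
#' pressure is `p_liq = G*phi_hat*lambda_r^2 + p0 + p_offset`, and chemical
#' equilibrium with the environment (`mu_w = p0 - Pi_ext`) closes the swelling
#' measure `phi_hat = phi/(phi0*lambda0)`:
#' `G*phi_hat*lambda_r^2 + Pi_ext + p_offset - Pi_mix(phi_hat) = 0`.
#' Under per-layer uniform swelling the radial stretch follows from the hoop
#' stretch, `lambda_e,r = J_e/lambda_e^2` (`stretch = "radial"`, the default,
#' which reproduces the exact grid solvers to a fraction of a percent).  The
#' variant `stretch = "hoop"` uses `Lambda_b` itself in place of the radial
#' stretch (a cruder thin-shell simplification).  The root is unique on the
#' physical branch and found by bracketed root-finding.
#'
#' @param Lambda_b hoop stretch at the boundary (relative to the free-swollen
#'   state).
#' @param env a [drying_environment()] (supplies `Pi_ext`).
#' @param layer a [layer_spec()].
#' @param gel a [gel_params()].
#' @param p_offset additional pressure offset (Pa), default 0.
#' @param stretch `"radial"` (default) or `"hoop"`; see Details.
#' @return The swelling measure `phi_hat` (dimensionless).
#' @export
phi_hat_outer_equilibrium <- function(Lambda_b, env, layer, gel, p_offset = 0,
                                      stretch = c("radial", "hoop")) {
  stopifnot(Lambda_b > 0)
  stretch <- match.arg(stretch)
  G <- layer$G
  l0 <- gel$lambda0
  # Pi_mix(phi_hat) = A * phi_hat^beta in the phi_hat variable
  A <- gel$alpha * G / l0^(2 * gel$beta)
  cc <- env$Pi_ext + p_offset
  ph_max <- (1 - 1e-12) / (layer$phi0 * l0)  # phi < 1
  if (stretch == "radial") {
    # lambda_e,r = (1/phi_tilde)/lambda_e^2: the stress term G*l0^2/(ph*le^4)
    # decreases in ph, so the residual is strictly increasing: unique root
    le4 <- (l0 * Lambda_b)^4
    g <- function(ph) A * ph^gel$beta - G * l0^2 / (ph * le4) - cc
    ph_min <- 1e-10
    if (g(ph_max) < 0)
      stop("no equilibrium swelling below phi = 1 (convergence error)")
    stats::uniroot(g, c(ph_min, ph_max), tol = 1e-15)$root
  } else {
    g <- function(ph) A * ph^gel$beta - G * ph * Lambda_b^2 - cc
    # stationary point of g: below it g decreases, above it increases
    ph_min <- (G * Lambda_b^2 / (gel$beta * A))^(1 / (gel$beta - 1))
    if (g(ph_min) > 0)
      stop("no equilibrium swelling at this stretch (convergence error)")
    if (g(ph_max) < 0)
      stop("no equilibrium swelling below phi = 1 (convergence error)")
    stats::uniroot(g, c(ph_min, ph_max), tol = 1e-14 * ph_min)$root
  }
}

#' Inner radius of a shell from incompressibility
#'
#' `r_a = (r_b^3 - (phi0/phi) * (R_B^3 - R_A^3))^(1/3)` with
#' `r_b = Lambda_b * R_B`: the deformed shell encloses the reference shell
#' volume scaled by the uniform volume ratio `J = phi0/phi`.
#'
#' @param Lambda_b hoop stretch at the outer surface.
#' @param phi_ratio `phi/phi0`, the shell's uniform densification ratio.
#' @param R_A,R_B reference inner and outer radii (m).
#' @return Current inner radius (m).
#' @export
inner_radius_from_incompressibility <- function(Lambda_b, phi_ratio, R_A, R_B) {
  stopifnot(Lambda_b > 0, phi_ratio > 0, R_A > 0, R_B > R_A)
  r_b <- Lambda_b * R_B
  ra3 <- r_b^3 - (R_B^3 - R_A^3) / phi_ratio
  if (ra3 <= 0) stop("shell-collapse: deformed shell volume exceeds enclosure")
  ra3^(1 / 3)
}

# Given the outer stretch, walk the analytic chain; returns the full state or
# NULL when the geometry collapses for this trial stretch.
analytic_chain <- function(Lambda_out, prob, stretch = "radial") {
  gel <- prob$gel; geom <- prob$geom; env <- prob$env
  l0 <- gel$lambda0
  ph_s <- tryCatch(
    phi_hat_outer_equilibrium(Lambda_out, env, prob$skin, gel,
                              stretch = stretch),
    error = function(e) NULL)
  if (is.null(ph_s)) return(NULL)
  J_s <- 1 / (l0 * ph_s)
  r_out <- Lambda_out * geom$R_out
  rm3 <- r_out^3 - J_s * (geom$R_out^3 - geom$R_m^3)
  if (rm3 <= 0) return(NULL)
  r_m <- rm3^(1 / 3)
  Lambda_m <- r_m / geom$R_m
  # elastic variables for the closed-form drop: phi_tilde = phi/phi_ref,
  # lambda_e = lambda0 * lambda; the drop is sigma(outer) - sigma(inner)
  pt_s <- ph_s / l0^2
  dp_skin <- shell_pressure_drop(pt_s, l0 * Lambda_out, l0 * Lambda_m,
                                 prob$skin$G)
  ph_c <- tryCatch(
    phi_hat_outer_equilibrium(Lambda_m, env, prob$core, gel,
                              p_offset = dp_skin, stretch = stretch),
    error = function(e) NULL)
  if (is.null(ph_c)) return(NULL)
  J_c <- 1 / (l0 * ph_c)
  rin3 <- r_m^3 - J_c * (geom$R_m^3 - geom$R_in^3)
  if (rin3 <= 0) return(NULL)
  r_in <- rin3^(1 / 3)
  Lambda_in <- r_in / geom$R_in
  pt_c <- ph_c / l0^2
  dp_core <- shell_pressure_drop(pt_c, l0 * Lambda_m, l0 * Lambda_in,
                                 prob$core$G)
  p_gas <- gel$p0 + dp_skin + dp_core
  list(Lambda_in = Lambda_in, Lambda_m = Lambda_m, Lambda_out = Lambda_out,
       phi_hat_core = ph_c, phi_hat_skin = ph_s,
       dp_core = dp_core, dp_skin = dp_skin, p_gas = p_gas,
       r_in = r_in, r_m = r_m, r_out = r_out)
}

# cavity-side gas pressure for a given pore radius and mechanical p_gas
cavity_closure <- function(r_in, p_gas, prob) {
  gel <- prob$gel
  RT <- gel$R_gas * gel$T
  V_gas <- 4 * pi * r_in^3 / 3
  p_air <- prob$cavity0$N_air * RT / V_gas
  p_vap <- p_sat_tetens(gel$T) *
    exp((prob$env$mu_ext - p_gas) * gel$nu_w / RT)
  list(p_air = p_air, p_vap = p_vap, p_gas = p_air + p_vap)
}

#' Analytical steady state of the core-shell sphere
#'
#' Closed-form approximation assuming uniform swelling within each layer:
#' the swelling of the skin follows chemical equilibrium at the outer surface,
#' the swelling of the core follows equilibrium at the interface using the
#' pressure transmitted through the skin, and the cavity pressure decomposes
#' as `p_gas - p0 = dp_skin + dp_core`.  The outer stretch is iterated
#' (secant, with a bracketed fallback) until the mechanical gas pressure
#' matches the cavity closure `p_gas = N_air*R*T/V_gas +
#' p_sat*exp((mu_ext - p_gas)*nu_w/(R*T))`.
#'
#' @param prob a [drying_problem()].
#' @param tol relative tolerance on the pressure match.
#' @param max_iter maximum secant iterations before falling back to a
#'   bracketed search.
#' @param stretch boundary-equilibrium stretch variant, see
#'   [phi_hat_outer_equilibrium()].
#' @return An object of class `steady_solution`: stretches `Lambda_in`,
#'   `Lambda_m`, `Lambda_out`, per-layer swelling measures, layer pressure
#'   drops, cavity pressures and current radii.
#' @export
core_shell_steady <- function(prob, tol = 1e-10, max_iter = 60,
                              stretch = "radial") {
  gel <- prob$gel
  resid <- function(L) {
    ch <- analytic_chain(L, prob, stretch)
    if (is.null(ch)) return(NA_real_)
    cav <- cavity_closure(ch$r_in, ch$p_gas, prob)
    ch$p_gas - cav$p_gas
  }
  # initial guess: uniform swelling of a skin-only sphere at Pi_ext
  L <- 1
  for (i in 1:25) {
    ph <- phi_hat_outer_equilibrium(L, prob$env, prob$skin, gel,
                                    stretch = stretch)
    L_new <- (1 / (gel$lambda0 * ph))^(1 / 3)
    if (abs(L_new - L) < 1e-12) break
    L <- L_new
  }
  x0 <- L; f0 <- resid(x0)
  root <- NA_real_
  if (is.finite(f0) && abs(f0) < tol * gel$p0) root <- x0
  x1 <- 0.99 * L; f1 <- resid(x1)
  if (!is.finite(f1)) { x1 <- 1.01 * L; f1 <- resid(x1) }
  if (!is.finite(root) && is.finite(f0) && is.finite(f1)) {
    for (i in seq_len(max_iter)) {
      if (abs(f1 - f0) < .Machine$double.xmin) break
      x2 <- x1 - f1 * (x1 - x0) / (f1 - f0)
      if (!is.finite(x2) || x2 <= 0) break
      f2 <- resid(x2)
      if (!is.finite(f2)) break
      x0 <- x1; f0 <- f1; x1 <- x2; f1 <- f2
      if (abs(f1) < tol * gel$p0) { root <- x1; break }
    }
  }
  if (!is.finite(root)) {
    # bracketed fallback: scan outer stretch for a sign change
    grid <- seq(0.2, 1.3, length.out = 111)
    vals <- vapply(grid, resid, 0)
    ok <- which(is.finite(vals))
    sgn <- which(diff(sign(vals[ok])) != 0)
    if (!length(sgn))
      stop("steady-state secant did not converge and no bracket found; ",
           "residual range [", signif(min(vals[ok]), 4), ", ",
           signif(max(vals[ok]), 4), "] Pa")
    i <- ok[sgn[1]]; j <- ok[sgn[1] + 1]
    root <- stats::uniroot(resid, c(grid[i], grid[j]),
                           tol = 1e-13)$root
  }
  ch <- analytic_chain(root, prob, stretch)
  cav <- cavity_closure(ch$r_in, ch$p_gas, prob)
  structure(c(ch, list(p_vap = cav$p_vap, p_air = cav$p_air,
                       residual = ch$p_gas - cav$p_gas, solver = "analytic")),
            class = "steady_solution")
}

#' @export
print.steady_solution <- function(x, ...) {
  cat("<steady_solution> (", x$solver, ")\n", sep = "")
  cat(sprintf("  Lambda_in = %.5g, Lambda_m = %.5g, Lambda_out = %.5g\n",
              x$Lambda_in, x$Lambda_m, x$Lambda_out))
  cat(sprintf("  p_gas = %.6g Pa (p_vap = %.5g, p_air = %.5g)\n",
              x$p_gas, x$p_vap, x$p_air))
  cat(sprintf("  r_in = %.5g m, r_out = %.5g m\n", x$r_in, x$r_out))
  invisible(x)
}

#' Quasi-steady gas pressure at an instantaneous geometry
#'
#' During slow drying the mechanics is equilibrated at all times, so the
#' instantaneous gas pressure follows the analytical layer decomposition
#' `p_gas = p0 + dp_skin + dp_core` evaluated at the instantaneous radii.
#' The per-layer uniform swelling follows from the geometry alone:
#' `phi_tilde = 1/(lambda0^3 * J_layer)` with `J_layer` the layer's current
#' over reference volume ratio.
#'
#' @param prob a [drying_problem()].
#' @param r_in,r_m,r_out instantaneous cavity, interface and outer radii (m);
#'   vectorised.
#' @return Gas pressure(s) (Pa).
#' @export
quasi_steady_gas <- function(prob, r_in, r_m, r_out) {
  gel <- prob$gel; geom <- prob$geom
  l0 <- gel$lambda0
  J_skin <- (r_out^3 - r_m^3) / (geom$R_out^3 - geom$R_m^3)
  J_core <- (r_m^3 - r_in^3) / (geom$R_m^3 - geom$R_in^3)
  pt_s <- 1 / (l0^3 * J_skin)
  pt_c <- 1 / (l0^3 * J_core)
  dp_skin <- shell_pressure_drop(pt_s, l0 * r_out / geom$R_out,
                                 l0 * r_m / geom$R_m, prob$skin$G)
  dp_core <- shell_pressure_drop(pt_c, l0 * r_m / geom$R_m,
                                 l0 * r_in / geom$R_in, prob$core$G)
  gel$p0 + dp_skin + dp_core
}
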