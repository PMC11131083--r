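#' Build the co-moving finite-volume mesh
#'
#' Subdivides the sphere into spherical-shell control volumes whose boundaries
#' align exactly with the cavity wall, the core/skin interface and the outer
#' surface.  Control volumes have uniform thickness within each layer.  The
#' polymer volume per CV is fixed once and for all: the mesh co-moves with the
#' network and only the water volumes evolve.
#'
#' @param prob a [drying_problem()].
#' @param n_core,n_skin number of control volumes per layer (>= 3).
#' @return An object of class `fv_state`.
#' @export
build_mesh <- function(prob, n_core = 30, n_skin = 6) {
  stopifnot(n_core >= 3, n_skin >= 3)
  geom <- prob$geom
  R_face <- c(seq(geom$R_in, geom$R_m, length.out = n_core + 1),
              seq(geom$R_m, geom$R_out, length.out = n_skin + 1)[-1])
  if (any(diff(R_face) <= 0)) stop("degenerate geometry")
  n <- n_core + n_skin
  R_center <- (R_face[-1] + R_face[-(n + 1)]) / 2
  V <- 4 * pi / 3 * diff(R_face^3)
  layer_id <- rep(c(1L, 2L), c(n_core, n_skin))
  phi0 <- ifelse(layer_id == 1L, prob$core$phi0, prob$skin$phi0)
  cav <- prob$cavity0
  structure(list(prob = prob, n_core = n_core, n_skin = n_skin,
                 R_face = R_face, R_center = R_center,
                 layer = layer_id,
                 G = ifelse(layer_id == 1L, prob$core$G, prob$skin$G),
                 phi_ref = ifelse(layer_id == 1L, prob$core$phi_ref,
                                  prob$skin$phi_ref),
                 phi0 = phi0,
                 dV_s = phi0 * V, dV_w = (1 - phi0) * V,
                 V_gas = cav$V_gas, N_air = cav$N_air, N_vap = cav$N_vap,
                 time = 0),
            class = "fv_state")
}

# Current-frame geometry, stretches, momentum balance and chemical potential.
# Faces are rebuilt from the gas volume and the per-CV volumes; the radial
# stress is integrated inward from sigma_rr(r_out) = -p0.
fv_fields <- function(state) {
  prob <- state$prob; gel <- prob$gel
  n <- length(state$dV_s)
  V <- state$dV_s + state$dV_w
  r_face <- (cumsum(c(state$V_gas, V)) * 3 / (4 * pi))^(1 / 3)
  r_c <- (r_face[-1] + r_face[-(n + 1)]) / 2
  dr <- diff(r_face)
  lambda_theta <- r_c / state$R_center
  lambda_r <- dr / diff(state$R_face)
  phi <- state$dV_s / V
  phi_hat <- phi / (state$phi0 * gel$lambda0)
  dsdr <- 2 * state$G * phi_hat * (lambda_theta^2 - lambda_r^2) / r_c
  # march inward: sigma(r - dr/2) = sigma(r + dr/2) - dr * dsigma/dr(center)
  sigma_face <- numeric(n + 1)
  sigma_face[n + 1] <- -gel$p0
  sigma_face[1:n] <- -gel$p0 - rev(cumsum(rev(dr * dsdr)))
  sigma_c <- sigma_face[-1] - (dr / 2) * dsdr
  p_liq <- state$G * phi_hat * lambda_r^2 - sigma_c
  Pi_mix <- gel$alpha * state$G * (phi / state$phi_ref)^gel$beta
  mu <- -Pi_mix + p_liq
  list(r_face = r_face, r_c = r_c, dr = dr,
       lambda_r = lambda_r, lambda_theta = lambda_theta,
       phi = phi, phi_w = 1 - phi, phi_hat = phi_hat,
       sigma_face = sigma_face, sigma_c = sigma_c,
       p_liq = p_liq, mu = mu, Pi_mix = Pi_mix,
       p_gas = -sigma_face[1])
}

#' Radial stress and liquid pressure on the finite-volume mesh
#'
#' Integrates the current-frame momentum balance
#' `dsigma_rr/dr = (2G/r) * phi_hat * (lambda_theta^2 - lambda_r^2)` inward
#' from the outer boundary condition `sigma_rr(r_out) = -p0`, then recovers
#' the liquid pressure `p_liq = G*phi_hat*lambda_r^2 - sigma_rr`.
#'
#' @param state an `fv_state`.
#' @return List with `sigma_face` (per face), `sigma_c`, `p_liq`, `mu`
#'   (per CV), and `p_gas = -sigma_rr(r_in)`.
#' @export
integrate_momentum <- function(state) {
  f <- fv_fields(state)
  f[c("sigma_face", "sigma_c", "p_liq", "mu", "p_gas")]
}

#' Water fluxes across control-volume faces
#'
#' Central differencing of the chemical potential between adjacent CV centres:
#' `J_w(face) = -(D_s*nu_w/(R*T)) * (mu(+) - mu(-))/dr * 4*pi*r^2` (volumetric
#' flux, positive outward).  The outer face carries the Dirichlet condition
#' `mu_w(r_out) = p0 - Pi_ext` through a ghost value at the face (or zero flux
#' in closed mode); the inner face is handled by the cavity update.
#'
#' @param state an `fv_state`.
#' @param fields optional precomputed [fv_fields] result.
#' @param mode `"dirichlet"` (drying) or `"closed"` (no outer exchange).
#' @return Numeric vector of length `n + 1` of volumetric fluxes (m^3/s);
#'   element 1 (cavity face) is zero here.
#' @export
compute_fluxes <- function(state, fields = NULL, mode = c("dirichlet", "closed")) {
  mode <- match.arg(mode)
  if (is.null(fields)) fields <- fv_fields(state)
  gel <- state$prob$gel
  n <- length(state$dV_s)
  mob <- gel$D_s * gel$nu_w / (gel$R_gas * gel$T)
  J <- numeric(n + 1)
  d_cc <- diff(fields$r_c)
  J[2:n] <- -mob * diff(fields$mu) / d_cc * 4 * pi * fields$r_face[2:n]^2
  if (mode == "dirichlet") {
    d_out <- fields$r_face[n + 1] - fields$r_c[n]
    J[n + 1] <- -mob * (state$prob$env$mu_ext - fields$mu[n]) / d_out *
      4 * pi * fields$r_face[n + 1]^2
  }
  J
}

#' Cavity update of the transient finite-volume scheme
#'
#' From the integrated momentum balance, `p_gas = -sigma_rr(r_in)`; the wall
#' activity gives the vapour pressure, the remainder is air, and the air
#' isotherm `p_air*V_gas = p_air,0*V_gas,0` yields the new gas volume.  The
#' change in vapour moles is the evaporative molar flux at the inner boundary,
#' drawn as liquid from the innermost control volume by the caller.
#'
#' @param state an `fv_state`.
#' @param fields optional precomputed [fv_fields] result.
#' @return List with the updated `cavity` (a `cavity_state`) and `dN_vap`
#'   (mol), the vapour created in this update.
#' @export
update_cavity <- function(state, fields = NULL) {
  if (is.null(fields)) fields <- fv_fields(state)
  gel <- state$prob$gel
  cav0 <- list(N_air = state$N_air)
  cav <- cavity_from_pressure(fields$sigma_face[1], fields$mu[1],
                              state$V_gas, cav0, gel, mode = "volume")
  list(cavity = cav, dN_vap = cav$N_vap - state$N_vap)
}

# largest stable explicit step: dt = C * min(d_eff^2) / D_eff with
# D_eff = D_s * (nu_w/(R*T)) * dPi_mix/dphi_w per CV and d_eff the smallest
# distance between the chemical-potential evaluation points bounding the CV
# (half the cell width at the outer Dirichlet ghost).
fv_stable_dt <- function(state, fields, C = 0.2) {
  gel <- state$prob$gel
  n <- length(fields$phi)
  dPi <- gel$beta * fields$Pi_mix / fields$phi
  D_eff <- gel$D_s * gel$nu_w / (gel$R_gas * gel$T) * dPi
  d_cc <- diff(fields$r_c)                       # interior face gaps
  d_out <- fields$r_face[n + 1] - fields$r_c[n]  # ghost gap at outer face
  gap <- pmin(c(d_cc[1], d_cc), c(d_cc, d_out))  # per-CV smallest gap
  C * min(gap^2 / D_eff)
}

# Enforce local equilibrium of the gas bubble at fixed water distribution:
# find V_gas such that the mechanical pressure -sigma_rr(r_in) equals the
# cavity pressure N_air*R*T/V_gas + a_w*p_sat.  The bubble is assumed
# equilibrated at all times; solving the algebraic loop implicitly (rather
# than as a lagged fixed point) keeps the scheme stable for stiff gels.
fv_equilibrate_cavity <- function(state, tol = 1e-12) {
  gel <- state$prob$gel
  RT <- gel$R_gas * gel$T
  psat <- p_sat_tetens(gel$T)
  gas_gap <- function(V) {
    st <- state; st$V_gas <- V
    f <- fv_fields(st)
    a_w <- exp((f$mu[1] - f$p_gas) * gel$nu_w / RT)
    f$p_gas - (state$N_air * RT / V + a_w * psat)
  }
  V0 <- state$V_gas
  g0 <- gas_gap(V0)
  if (abs(g0) < tol * gel$p0) return(state)
  # warm-started secant: between steps the equilibrium volume barely moves
  x0 <- V0; x1 <- V0 * (1 + 1e-6); f0 <- g0; f1 <- gas_gap(x1)
  done <- FALSE
  for (k in 1:40) {
    if (!is.finite(f1) || abs(f1 - f0) < .Machine$double.xmin) break
    x2 <- x1 - f1 * (x1 - x0) / (f1 - f0)
    if (!is.finite(x2) || x2 <= 0) break
    f2 <- gas_gap(x2)
    x0 <- x1; f0 <- f1; x1 <- x2; f1 <- f2
    if (abs(f1) < tol * gel$p0) { done <- TRUE; break }
  }
  if (!done) {  # bracketed fallback
    lo <- V0; hi <- V0; glo <- g0; ghi <- g0
    for (k in 1:60) {
      if (glo > 0) { lo <- lo / 1.2; glo <- gas_gap(lo) }  # p_mech falls with V
      if (ghi < 0) { hi <- hi * 1.2; ghi <- gas_gap(hi) }
      if (glo <= 0 && ghi >= 0) break
    }
    if (!(glo <= 0 && ghi >= 0))
      stop("nonphysical cavity state: no equilibrium gas volume found")
    x1 <- stats::uniroot(gas_gap, c(lo, hi), tol = V0 * 1e-14)$root
  }
  state$V_gas <- x1
  state
}

#' Advance the transient finite-volume state by one explicit Euler step
#'
#' Sequence: equilibrate the gas bubble (the cavity is in local equilibrium
#' with the stress field and the wall activity at all times), harvest the
#' vapour increment as liquid drawn from the innermost control volume, compute
#' face fluxes, then update the per-CV water volumes conservatively,
#' `dV_w/dt = J(r-) - J(r+)`.
#'
#' @param state an `fv_state`.
#' @param dt time step (s); must satisfy the stability bound.
#' @param mode outer boundary mode, see [compute_fluxes()].
#' @return The advanced `fv_state`.
#' @export
fv_step <- function(state, dt, mode = "dirichlet") {
  state <- fv_equilibrate_cavity(state)
  fields <- fv_fields(state)
  gel <- state$prob$gel
  RT <- gel$R_gas * gel$T
  a_w <- exp((fields$mu[1] - fields$p_gas) * gel$nu_w / RT)
  p_vap <- a_w * p_sat_tetens(gel$T)
  if (p_vap >= fields$p_gas)
    stop("nonphysical cavity state: p_vap >= p_gas")
  N_vap_new <- p_vap * state$V_gas / RT
  dN_vap <- N_vap_new - state$N_vap
  J <- compute_fluxes(state, fields, mode = mode)
  n <- length(state$dV_w)
  dV_w <- state$dV_w + dt * (J[1:n] - J[2:(n + 1)])
  dV_w[1] <- dV_w[1] - gel$nu_w * dN_vap
  if (any(dV_w <= 0))
    stop("step-size error: water volume depleted in a control volume")
  state$dV_w <- dV_w
  state$N_vap <- N_vap_new
  state$time <- state$time + dt
  state
}

fv_profile <- function(state, fields = NULL) {
  if (is.null(fields)) fields <- fv_fields(state)
  data.frame(R = state$R_center, r = fields$r_c,
             lambda_r = fields$lambda_r, lambda_theta = fields$lambda_theta,
             sigma_rr = fields$sigma_c, p_liq = fields$p_liq,
             mu_w = fields$mu, phi_w = fields$phi_w,
             layer = ifelse(state$layer == 1L, "core", "skin"))
}

#' Run the transient finite-volume solver
#'
#' Explicit Euler time integration with an adaptive step at a fixed fraction
#' of the diffusive stability bound.  Terminates at `t_end` or earlier when
#' the relative water-content rate (scaled by the diffusion time
#' `R_out^2/D_s`) falls below `steady_tol`.
#'
#' @param prob a [drying_problem()].
#' @param t_end final time (s).
#' @param n_core,n_skin control volumes per layer.
#' @param output_every sampling interval for the time series (s); default
#'   `t_end/200`.
#' @param mode outer boundary mode, see [compute_fluxes()].
#' @param steady_tol steady-state detection: the run stops once the maximal
#'   water-fraction rate has decayed below this fraction of the largest rate
#'   seen during the run.
#' @param C Courant-like safety factor for the explicit step.
#' @param max_steps hard cap on the number of steps.
#' @return List with `times` (data frame: t, p_gas, p_air, p_vap, r_in,
#'   r_out), `profile` (final radial profiles), `state`, `p_gas`, `r_in`,
#'   `r_out`, and `steady` (logical).
#' @export
run_transient_fv <- function(prob, t_end, n_core = 30, n_skin = 6,
                             output_every = NULL, mode = "dirichlet",
                             steady_tol = 1e-8, C = 0.2, max_steps = 2e6) {
  state <- build_mesh(prob, n_core, n_skin)
  gel <- prob$gel
  if (is.null(output_every)) output_every <- t_end / 200
  peak_rate <- 0
  rows <- vector("list", 2048L)
  n_rows <- 0L
  snapshot <- function(state) {
    st <- fv_equilibrate_cavity(state)
    f <- fv_fields(st)
    a_w <- exp((f$mu[1] - f$p_gas) * gel$nu_w / (gel$R_gas * gel$T))
    p_vap <- a_w * p_sat_tetens(gel$T)
    list(state = st, fields = f, p_gas = f$p_gas, p_vap = p_vap,
         p_air = f$p_gas - p_vap)
  }
  record <- function(sn) {
    n_rows <<- n_rows + 1L
    if (n_rows > length(rows)) length(rows) <<- 2L * n_rows
    rows[[n_rows]] <<- data.frame(
      t = sn$state$time, p_gas = sn$p_gas, p_air = sn$p_air,
      p_vap = sn$p_vap, r_in = sn$fields$r_face[1],
      r_m = sn$fields$r_face[sn$state$n_core + 1L],
      r_out = sn$fields$r_face[length(sn$fields$r_face)])
  }
  record(snapshot(state))
  next_out <- output_every
  steady <- FALSE
  steps <- 0L
  while (state$time < t_end && steps < max_steps) {
    fields <- fv_fields(state)
    dt <- min(fv_stable_dt(state, fields, C), t_end - state$time)
    old_w <- state$dV_w
    new_state <- NULL
    for (try in 1:25) {  # halve on depletion/nonphysical overshoot
      new_state <- tryCatch(fv_step(state, dt, mode = mode),
                            error = function(e) e)
      if (!inherits(new_state, "error")) break
      dt <- dt / 2
    }
    if (inherits(new_state, "error")) stop(new_state)
    state <- new_state
    steps <- steps + 1L
    rate <- max(abs(state$dV_w - old_w) / (state$dV_s + state$dV_w)) / dt
    peak_rate <- max(peak_rate, rate)
    if (state$time >= next_out || state$time >= t_end) {
      record(snapshot(state))
      next_out <- next_out + output_every
    }
    if (rate < steady_tol * peak_rate) { steady <- TRUE; break }
  }
  sn <- snapshot(state)
  record(sn)
  times <- do.call(rbind, rows[seq_len(n_rows)])
  list(times = times, profile = fv_profile(sn$state, sn$fields),
       state = sn$state,
       p_gas = sn$p_gas, p_vap = sn$p_vap, p_air = sn$p_air,
       r_in = sn$fields$r_face[1],
       r_out = sn$fields$r_face[length(sn$fields$r_face)],
       steady = steady, steps = steps)
}

# Steady-state march at a trial outer stretch: every CV is in chemical
# equilibrium with the environment (Pi_mix - p_liq + p0 = Pi_ext), the
# momentum balance is integrated inward, and the polymer fraction of each CV
# is the root of the combined relation.  Returns NULL if the trial stretch is
# geometrically infeasible.
fv_steady_march <- function(Lambda_b, mesh) {
  prob <- mesh$prob; gel <- prob$gel
  n <- length(mesh$dV_s)
  r_face <- numeric(n + 1)
  sigma_face <- numeric(n + 1)
  r_face[n + 1] <- Lambda_b * prob$geom$R_out
  sigma_face[n + 1] <- -gel$p0
  phi <- numeric(n); lam_r <- numeric(n); lam_t <- numeric(n)
  sig_c <- numeric(n); p_liq <- numeric(n)
  for (i in n:1) {
    r_plus <- r_face[i + 1]; s_plus <- sigma_face[i + 1]
    dVs <- mesh$dV_s[i]; G <- mesh$G[i]
    phi0 <- mesh$phi0[i]; phiref <- mesh$phi_ref[i]
    dR <- mesh$R_face[i + 1] - mesh$R_face[i]
    Rc <- mesh$R_center[i]
    eval_cv <- function(ph) {
      V <- dVs / ph
      rm3 <- r_plus^3 - 3 * V / (4 * pi)
      if (rm3 <= 0) return(NULL)
      r_minus <- rm3^(1 / 3)
      rc <- (r_plus + r_minus) / 2
      lt <- rc / Rc
      lr <- (r_plus - r_minus) / dR
      ph_hat <- ph / (phi0 * gel$lambda0)
      dsdr <- 2 * G * ph_hat * (lt^2 - lr^2) / rc
      sc <- s_plus - (r_plus - rc) * dsdr
      pl <- G * ph_hat * lr^2 - sc
      Pi <- gel$alpha * G * (ph / phiref)^gel$beta
      list(resid = Pi - pl + gel$p0 - prob$env$Pi_ext,
           r_minus = r_minus, lt = lt, lr = lr, sc = sc, pl = pl,
           s_minus = s_plus - (r_plus - r_minus) * dsdr)
    }
    res_of <- function(ph) {
      e <- eval_cv(ph)
      if (is.null(e)) return(NA_real_)
      e$resid
    }
    lo <- dVs * 3 / (4 * pi * r_plus^3) * (1 + 1e-8)  # r_minus > 0
    hi <- 1 - 1e-12
    if (lo >= hi) return(NULL)
    # the residual can be positive at both bracket ends with the physical
    # root on the rising branch past a minimum: scan, then bracket upward
    grid <- exp(seq(log(lo), log(hi), length.out = 30))
    vals <- vapply(grid, res_of, 0)
    if (!any(is.finite(vals))) return(NULL)
    imin <- which.min(vals)
    if (!is.finite(vals[imin]) || vals[imin] > 0) return(NULL)
    f_hi <- res_of(hi)
    if (!is.finite(f_hi) || f_hi < 0) return(NULL)
    ph <- stats::uniroot(res_of, c(grid[imin], hi), tol = 1e-15)$root
    e <- eval_cv(ph)
    phi[i] <- ph; lam_r[i] <- e$lr; lam_t[i] <- e$lt
    sig_c[i] <- e$sc; p_liq[i] <- e$pl
    r_face[i] <- e$r_minus; sigma_face[i] <- e$s_minus
  }
  list(r_face = r_face, sigma_face = sigma_face, phi = phi,
       lambda_r = lam_r, lambda_theta = lam_t, sigma_c = sig_c,
       p_liq = p_liq, p_gas = -sigma_face[1], r_in = r_face[1])
}

#' Steady-state finite-volume solver (secant closure)
#'
#' For an assumed outer stretch the momentum balance is integrated inward with
#' every control volume in chemical equilibrium with the environment; the
#' vapour pressure from the cavity gas law (`p_vap = p_gas - N_air*R*T/V_gas`)
#' must match the equilibrium expression
#' `p_sat*exp((mu_ext - p_gas)*nu_w/(R*T))`.  The outer stretch is iterated by
#' the secant method with a bracketed fallback.
#'
#' @param prob a [drying_problem()].
#' @param n_core,n_skin control volumes per layer.
#' @param tol relative tolerance on the vapour-pressure mismatch.
#' @param max_iter secant iteration cap.
#' @return An object of class `steady_solution` with an additional `profile`
#'   data frame.
#' @export
steady_state_fv <- function(prob, n_core = 60, n_skin = 12, tol = 1e-8,
                            max_iter = 60) {
  mesh <- build_mesh(prob, n_core, n_skin)
  gel <- prob$gel
  RT <- gel$R_gas * gel$T
  p_scale <- p_sat_tetens(gel$T)
  mismatch <- function(L) {
    m <- fv_steady_march(L, mesh)
    if (is.null(m)) return(NA_real_)
    V_gas <- 4 * pi * m$r_in^3 / 3
    p_air <- mesh$N_air * RT / V_gas
    p_vap_gas <- m$p_gas - p_air
    p_vap_eq <- p_sat_tetens(gel$T) *
      exp((prob$env$mu_ext - m$p_gas) * gel$nu_w / RT)
    p_vap_gas - p_vap_eq
  }
  guess <- tryCatch(core_shell_steady(prob)$Lambda_out,
                    error = function(e) NA_real_)
  if (!is.finite(guess)) guess <- 0.9
  x0 <- guess; f0 <- mismatch(x0)
  root <- if (is.finite(f0) && abs(f0) < tol * p_scale) x0 else NA_real_
  x1 <- 1.01 * guess; f1 <- mismatch(x1)
  if (!is.finite(f1)) { x1 <- 0.99 * guess; f1 <- mismatch(x1) }
  hist <- c()
  if (!is.finite(root) && is.finite(f0) && is.finite(f1)) {
    for (i in seq_len(max_iter)) {
      if (abs(f1 - f0) < .Machine$double.xmin) break
      x2 <- x1 - f1 * (x1 - x0) / (f1 - f0)
      if (!is.finite(x2) || x2 <= 0) break
      f2 <- mismatch(x2)
      hist <- c(hist, f2)
      if (!is.finite(f2)) break
      x0 <- x1; f0 <- f1; x1 <- x2; f1 <- f2
      if (abs(f1) < tol * p_scale) { root <- x1; break }
    }
  }
  if (!is.finite(root)) {
    grid <- seq(0.2, 1.3, length.out = 111)
    vals <- vapply(grid, mismatch, 0)
    ok <- which(is.finite(vals))
    sgn <- which(diff(sign(vals[ok])) != 0)
    if (!length(sgn))
      stop("FV steady secant did not converge; residual history: ",
           paste(signif(hist, 3), collapse = ", "))
    i <- ok[sgn[1]]; j <- ok[sgn[1] + 1]
    root <- stats::uniroot(mismatch, c(grid[i], grid[j]), tol = 1e-13)$root
  }
  m <- fv_steady_march(root, mesh)
  V_gas <- 4 * pi * m$r_in^3 / 3
  p_air <- mesh$N_air * RT / V_gas
  geom <- prob$geom
  i_m <- n_core + 1L  # face index of the core/skin interface
  prof <- data.frame(R = mesh$R_center,
                     r = (m$r_face[-1] + m$r_face[-length(m$r_face)]) / 2,
                     lambda_r = m$lambda_r, lambda_theta = m$lambda_theta,
                     sigma_rr = m$sigma_c, p_liq = m$p_liq,
                     mu_w = -gel$alpha * mesh$G *
                       (m$phi / mesh$phi_ref)^gel$beta + m$p_liq,
                     phi_w = 1 - m$phi,
                     layer = ifelse(mesh$layer == 1L, "core", "skin"))
  structure(list(Lambda_in = m$r_face[1] / geom$R_in,
                 Lambda_m = m$r_face[i_m] / geom$R_m,
                 Lambda_out = root,
                 phi_hat_core = NA_real_, phi_hat_skin = NA_real_,
                 dp_core = -m$sigma_face[1] + m$sigma_face[i_m],
                 dp_skin = -m$sigma_face[i_m] - gel$p0,
                 p_gas = m$p_gas, p_air = p_air, p_vap = m$p_gas - p_air,
                 r_in = m$r_face[1], r_out = m$r_face[length(m$r_face)],
                 profile = prof, solver = "fv_steady"),
            class = "steady_solution")
}
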