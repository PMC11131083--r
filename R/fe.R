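# Mixed finite-element solver of the weak formulation on the fixed initial
# frame: quadratic displacement u(R), linear Lagrange pressure p(R) and linear
# molar water concentration c(R), the latter two with a doubled node at the
# core/skin interface (lambda_r, and with it p, jumps there; the water fields
# live on disjoint subdomains coupled by an interface permeance).  The cavity
# vapour content N_vap is one extra scalar unknown evolved as an ODE.
#
# Unknown vector layout: [u, p_core, p_skin, c_core, c_skin, N_vap].

gauss3 <- list(xi = c(0.5 - sqrt(3 / 20), 0.5, 0.5 + sqrt(3 / 20)),
               w = c(5, 8, 5) / 18)

fe_setup <- function(prob, n_core = 16, n_skin = 6, D_mu_penalty = 100,
                     n_vap_scale = NULL) {
  stopifnot(n_core >= 2, n_skin >= 2)
  geom <- prob$geom; gel <- prob$gel
  n_el <- n_core + n_skin
  Rv <- c(seq(geom$R_in, geom$R_m, length.out = n_core + 1),
          seq(geom$R_m, geom$R_out, length.out = n_skin + 1)[-1])
  n_u <- 2 * n_el + 1
  n_pc <- n_core + 1 + n_skin + 1   # doubled vertex at the interface
  nq <- 3 * n_el
  Bu0 <- matrix(0, nq, n_u); Bu1 <- matrix(0, nq, n_u)
  Bp0 <- matrix(0, nq, n_pc); Bp1 <- matrix(0, nq, n_pc)
  Rq <- numeric(nq); Wq <- numeric(nq); layer_q <- integer(nq)
  for (e in seq_len(n_el)) {
    h <- Rv[e + 1] - Rv[e]
    ud <- c(2 * e - 1, 2 * e, 2 * e + 1)
    pd <- if (e <= n_core) c(e, e + 1) else
      c(n_core + 1 + (e - n_core), n_core + 2 + (e - n_core))
    for (k in 1:3) {
      xi <- gauss3$xi[k]; row <- 3 * (e - 1) + k
      Rq[row] <- Rv[e] + xi * h
      Wq[row] <- gauss3$w[k] * h * 4 * pi * Rq[row]^2
      Bu0[row, ud] <- c((1 - xi) * (1 - 2 * xi), 4 * xi * (1 - xi),
                        xi * (2 * xi - 1))
      Bu1[row, ud] <- c(4 * xi - 3, 4 - 8 * xi, 4 * xi - 1) / h
      Bp0[row, pd] <- c(1 - xi, xi)
      Bp1[row, pd] <- c(-1, 1) / h
    }
    layer_q[3 * (e - 1) + 1:3] <- if (e <= n_core) 1L else 2L
  }
  Gq <- ifelse(layer_q == 1L, prob$core$G, prob$skin$G)
  phi0q <- ifelse(layer_q == 1L, prob$core$phi0, prob$skin$phi0)
  phirefq <- ifelse(layer_q == 1L, prob$core$phi_ref, prob$skin$phi_ref)
  h_min <- min(diff(Rv))
  idx <- list(u = seq_len(n_u),
              p = n_u + seq_len(n_pc),
              c = n_u + n_pc + seq_len(n_pc),
              N = n_u + 2 * n_pc + 1L)
  # interface / boundary dof positions within the p/c blocks
  i_if_core <- n_core + 1L; i_if_skin <- n_core + 2L
  cav0 <- prob$cavity0
  if (is.null(n_vap_scale)) n_vap_scale <- cav0$N_vap
  scales <- c(rep(geom$R_out, n_u),
              rep(max(prob$core$G, prob$env$Pi_ext, gel$p0), n_pc),
              rep(1 / gel$nu_w, n_pc),
              n_vap_scale)
  list(prob = prob, n_core = n_core, n_skin = n_skin, n_el = n_el,
       Rv = Rv, n_u = n_u, n_pc = n_pc, nq = nq, idx = idx,
       Bu0 = Bu0, Bu1 = Bu1, Bp0 = Bp0, Bp1 = Bp1,
       Rq = Rq, Wq = Wq, layer_q = layer_q,
       Gq = Gq, phi0q = phi0q, phirefq = phirefq,
       i_if_core = i_if_core, i_if_skin = i_if_skin,
       D_mu = D_mu_penalty * gel$D_s / (gel$R_gas * gel$T * h_min),
       beta_air = prob$env$beta_air,
       c_sat = p_sat_tetens(gel$T) / (gel$R_gas * gel$T),
       scales = scales, n_dof = n_u + 2 * n_pc + 1L)
}

#' Initial finite-element state
#'
#' Free-swollen configuration: zero displacement, per-layer pressure
#' `p = G/lambda0 + p0`, water concentration `nu_w*c = 1 - phi0`, and a
#' saturated cavity at ambient pressure.
#'
#' @param prob a [drying_problem()].
#' @param n_core,n_skin elements per layer.
#' @param ... further arguments to the internal setup (interface-permeance
#'   penalty).
#' @return List with the discretisation (`fe`) and the initial unknown vector
#'   (`x`).
#' @export
fe_init_state <- function(prob, n_core = 16, n_skin = 6, ...) {
  fe <- fe_setup(prob, n_core, n_skin, ...)
  gel <- prob$gel
  p0v <- c(rep(prob$core$G / gel$lambda0 + gel$p0, fe$n_core + 1),
           rep(prob$skin$G / gel$lambda0 + gel$p0, fe$n_skin + 1))
  c0v <- c(rep((1 - prob$core$phi0) / gel$nu_w, fe$n_core + 1),
           rep((1 - prob$skin$phi0) / gel$nu_w, fe$n_skin + 1))
  x <- c(rep(0, fe$n_u), p0v, c0v, prob$cavity0$N_vap)
  list(fe = fe, x = x)
}

# cavity pressures from the inner displacement and vapour moles
fe_cavity <- function(fe, u_in, N_vap) {
  prob <- fe$prob; gel <- prob$gel
  R_in <- prob$geom$R_in
  r_in <- R_in + u_in
  V_gas <- 4 * pi * r_in^3 / 3
  RT <- gel$R_gas * gel$T
  p_air <- prob$cavity0$p_air * prob$cavity0$V_gas / V_gas
  p_vap <- N_vap * RT / V_gas
  list(r_in = r_in, V_gas = V_gas, p_air = p_air, p_vap = p_vap,
       p_gas = p_air + p_vap,
       RH_cav = p_vap / p_sat_tetens(gel$T))
}

#' Finite-element residual of the coupled weak formulation
#'
#' Stacks the weak momentum balance (divergence-consistent form
#' `dS_RR/dR + (2/R)(S_RR - S_tt) = 0` with traction boundary terms
#' `S_RR = -p0*lambda_t^2` outside and `S_RR = -p_gas*lambda_t^2` at the
#' cavity), the incompressibility constraint `J = phi0 + nu_w*c`, the water
#' mass balances of core and skin with referential flux
#' `h_R = -(lambda_t^2/lambda_r)*(D_s/(R*T))*dmu/dR`, Robin evaporation fluxes
#' at the cavity and outer surfaces, an interface permeance flux proportional
#' to the chemical-potential jump, and the cavity vapour ODE (backward Euler).
#'
#' @param x unknown vector.
#' @param fe discretisation from [fe_init_state()].
#' @param x_old,dt previous state and time step; `dt = Inf` gives the steady
#'   residual.
#' @return Residual vector (same length as `x`).
#' @export
fe_residual <- function(x, fe, x_old = x, dt = Inf) {
  prob <- fe$prob; gel <- prob$gel; env <- prob$env
  RT <- gel$R_gas * gel$T
  idx <- fe$idx
  u <- x[idx$u]; pv <- x[idx$p]; cv <- x[idx$c]; N_vap <- x[idx$N]
  u_q <- drop(fe$Bu0 %*% u); du_q <- drop(fe$Bu1 %*% u)
  p_q <- drop(fe$Bp0 %*% pv)
  c_q <- drop(fe$Bp0 %*% cv); dc_q <- drop(fe$Bp1 %*% cv)
  dp_q <- drop(fe$Bp1 %*% pv)
  lam_r <- 1 + du_q
  lam_t <- 1 + u_q / fe$Rq
  if (any(lam_r <= 0) || any(lam_t <= 0))
    stop("element inversion: non-positive stretch")
  l0 <- gel$lambda0
  S_RR <- fe$Gq * lam_r / l0 - p_q * lam_t^2
  S_tt <- fe$Gq * lam_t / l0 - p_q * lam_t * lam_r
  J_q <- lam_r * lam_t^2
  J_hat <- fe$phi0q + gel$nu_w * c_q
  if (any(J_hat <= fe$phi0q)) stop("non-positive water content")
  phi_q <- fe$phi0q / J_hat
  Pi_q <- gel$alpha * fe$Gq * (phi_q / fe$phirefq)^gel$beta
  # d(mu)/dR with mu = -Pi(phi(c)) + p
  dPi_dc <- gel$beta * Pi_q / phi_q * (-fe$phi0q * gel$nu_w / J_hat^2)
  dmu_q <- -dPi_dc * dc_q + dp_q
  h_q <- -(lam_t^2 / lam_r) * (gel$D_s / RT) * dmu_q
  cdot_q <- drop(fe$Bp0 %*% ((cv - x_old[idx$c]) / dt))

  R_u <- -drop(crossprod(fe$Bu1, fe$Wq * S_RR)) -
    drop(crossprod(fe$Bu0, fe$Wq * 2 / fe$Rq * S_tt))
  R_p <- drop(crossprod(fe$Bp0, fe$Wq * (J_q - J_hat)))
  R_c <- drop(crossprod(fe$Bp0, fe$Wq * cdot_q)) -
    drop(crossprod(fe$Bp1, fe$Wq * h_q))

  # boundary tractions
  geom <- prob$geom
  cav <- fe_cavity(fe, u[1], N_vap)
  lam_t_in <- 1 + u[1] / geom$R_in
  lam_t_out <- 1 + u[fe$n_u] / geom$R_out
  R_u[1] <- R_u[1] + cav$p_gas * lam_t_in^2 * 4 * pi * geom$R_in^2
  R_u[fe$n_u] <- R_u[fe$n_u] - gel$p0 * lam_t_out^2 * 4 * pi * geom$R_out^2

  # Robin fluxes (per reference area, lambda_t^2 maps the current surface)
  mu_node <- -gel$alpha *
    c(prob$core$G * ((fe$prob$core$phi0 /
        (fe$prob$core$phi0 + gel$nu_w * cv[1])) / prob$core$phi_ref)^gel$beta,
      prob$core$G * ((prob$core$phi0 /
        (prob$core$phi0 + gel$nu_w * cv[fe$i_if_core])) /
          prob$core$phi_ref)^gel$beta,
      prob$skin$G * ((prob$skin$phi0 /
        (prob$skin$phi0 + gel$nu_w * cv[fe$i_if_skin])) /
          prob$skin$phi_ref)^gel$beta,
      prob$skin$G * ((prob$skin$phi0 /
        (prob$skin$phi0 + gel$nu_w * cv[fe$n_pc])) /
          prob$skin$phi_ref)^gel$beta) +
    c(pv[1], pv[fe$i_if_core], pv[fe$i_if_skin], pv[fe$n_pc])
  a_w_int <- exp((mu_node[1] - cav$p_gas) * gel$nu_w / RT)
  a_w_ext <- exp((mu_node[4] - gel$p0) * gel$nu_w / RT)
  beta_cav <- env$D_vap / (cav$r_in / 5)
  J_cav <- lam_t_in^2 * beta_cav * (a_w_int - cav$RH_cav) * fe$c_sat
  J_evap <- lam_t_out^2 * fe$beta_air * (a_w_ext - env$RH_ext) * fe$c_sat
  Phi_if <- fe$D_mu * (mu_node[2] - mu_node[3])

  R_c[1] <- R_c[1] + J_cav * 4 * pi * geom$R_in^2
  R_c[fe$i_if_core] <- R_c[fe$i_if_core] + Phi_if * 4 * pi * geom$R_m^2
  R_c[fe$i_if_skin] <- R_c[fe$i_if_skin] - Phi_if * 4 * pi * geom$R_m^2
  R_c[fe$n_pc] <- R_c[fe$n_pc] + J_evap * 4 * pi * geom$R_out^2

  R_N <- (N_vap - x_old[idx$N]) / dt - J_cav * 4 * pi * geom$R_in^2

  c(R_u, R_p, R_c, R_N)
}

# residual scale per equation row, for convergence tests and row
# equilibration; rate rows scale with the step actually taken
fe_res_scale <- function(fe, dt = Inf) {
  prob <- fe$prob; gel <- prob$gel
  p_scale <- max(prob$core$G, prob$env$Pi_ext, gel$p0)
  A <- 4 * pi * prob$geom$R_out^2
  hbar <- mean(diff(fe$Rv))
  t_diff <- prob$geom$R_out^2 / gel$D_s
  tau <- if (is.finite(dt)) min(dt, t_diff) else t_diff
  c(rep(p_scale * A, fe$n_u),                       # momentum: Pa * m^2-ish
    rep(A * hbar, fe$n_pc),                         # incompressibility: volume
    rep(A * hbar / gel$nu_w / tau, fe$n_pc),        # water rate
    fe$prob$cavity0$N_vap / tau)                    # cavity vapour rate
}

fe_fd_jacobian <- function(x, fe, x_old, dt, r0 = NULL) {
  if (is.null(r0)) r0 <- fe_residual(x, fe, x_old, dt)
  n <- fe$n_dof
  Jm <- matrix(0, n, n)
  for (j in seq_len(n)) {
    h <- 1e-6 * fe$scales[j]
    xp <- x; xp[j] <- xp[j] + h
    Jm[, j] <- (fe_residual(xp, fe, x_old, dt) - r0) / h
  }
  Jm
}

fe_newton <- function(x, fe, x_old, dt, tol = 1e-9, max_iter = 14,
                      Jm = NULL) {
  rs <- fe_res_scale(fe, dt)
  r <- tryCatch(fe_residual(x, fe, x_old, dt), error = function(e) NULL)
  if (is.null(r)) return(list(ok = FALSE))
  err <- max(abs(r / rs))
  fresh <- FALSE
  for (it in seq_len(max_iter)) {
    if (err < tol) return(list(ok = TRUE, x = x, iter = it - 1, J = Jm))
    if (is.null(Jm)) {
      Jm <- tryCatch(fe_fd_jacobian(x, fe, x_old, dt, r0 = r),
                     error = function(e) NULL)
      if (is.null(Jm)) return(list(ok = FALSE))
      fresh <- TRUE
    }
    # row/column equilibration: raw units span many orders of magnitude
    Js <- sweep(sweep(Jm, 1, rs, "/"), 2, fe$scales, "*")
    step <- tryCatch(fe$scales * solve(Js, -r / rs), error = function(e) NULL)
    if (is.null(step)) {
      if (!fresh) { Jm <- NULL; next }
      return(list(ok = FALSE))
    }
    # damped update: backtrack until the residual decreases (or accept small)
    lam <- 1; improved <- FALSE
    for (ls in 1:8) {
      x_try <- x + lam * step
      r_try <- tryCatch(fe_residual(x_try, fe, x_old, dt),
                        error = function(e) NULL)
      if (!is.null(r_try)) {
        err_try <- max(abs(r_try / rs))
        if (err_try < err || err_try < tol) {
          x <- x_try; r <- r_try; err <- err_try; improved <- TRUE
          break
        }
      }
      lam <- lam / 2
    }
    if (!improved) {
      if (!fresh) { Jm <- NULL; next }  # retry with a fresh Jacobian
      return(list(ok = FALSE))
    }
    if (!fresh && it >= 3) Jm <- NULL  # stale Jacobian: refresh next round
  }
  if (err < tol) list(ok = TRUE, x = x, iter = max_iter, J = Jm)
  else list(ok = FALSE)
}

#' Advance the finite-element state by one backward-Euler step
#'
#' Monolithic Newton iteration on the full unknown vector (displacement,
#' pressure, concentrations, cavity vapour); the Jacobian is assembled by
#' finite differences and reused while convergence stays fast.
#'
#' @param state list with `fe` and `x` (see [fe_init_state()]).
#' @param dt time step (s).
#' @param tol Newton tolerance on the scaled residual.
#' @return Updated state (with `iter`, the Newton count), or `NULL` on
#'   divergence.
#' @export
fe_time_step <- function(state, dt, tol = 1e-9) {
  res <- fe_newton(state$x, state$fe, state$x, dt, tol = tol,
                   Jm = state$J)
  if (!res$ok) return(NULL)
  list(fe = state$fe, x = res$x, J = res$J, iter = res$iter)
}

fe_snapshot <- function(fe, x) {
  cav <- fe_cavity(fe, x[fe$idx$u][1], x[fe$idx$N])
  u <- x[fe$idx$u]
  r_out <- fe$prob$geom$R_out + u[fe$n_u]
  r_m <- fe$prob$geom$R_m + u[2 * fe$n_core + 1]
  list(p_gas = cav$p_gas, p_air = cav$p_air, p_vap = cav$p_vap,
       r_in = cav$r_in, r_m = r_m, r_out = r_out)
}

fe_profile <- function(fe, x) {
  gel <- fe$prob$gel
  u <- x[fe$idx$u]; pv <- x[fe$idx$p]; cv <- x[fe$idx$c]
  u_q <- drop(fe$Bu0 %*% u); du_q <- drop(fe$Bu1 %*% u)
  p_q <- drop(fe$Bp0 %*% pv); c_q <- drop(fe$Bp0 %*% cv)
  lam_r <- 1 + du_q; lam_t <- 1 + u_q / fe$Rq
  J_hat <- fe$phi0q + gel$nu_w * c_q
  phi_q <- fe$phi0q / J_hat
  Pi_q <- gel$alpha * fe$Gq * (phi_q / fe$phirefq)^gel$beta
  sigma_rr <- (fe$Gq * lam_r / gel$lambda0 - p_q * lam_t^2) / lam_t^2
  data.frame(R = fe$Rq, r = fe$Rq + u_q,
             lambda_r = lam_r, lambda_theta = lam_t,
             sigma_rr = sigma_rr, p_liq = p_q,
             mu_w = -Pi_q + p_q, phi_w = 1 - phi_q,
             layer = ifelse(fe$layer_q == 1L, "core", "skin"))
}

#' Run the transient finite-element solver
#'
#' Backward-Euler time stepping with adaptive step growth (and halving on
#' Newton failure), starting from the free-swollen state.  Terminates at
#' `t_end` or when the scaled state rate has decayed below `steady_tol` times
#' its peak.
#'
#' @param prob a [drying_problem()].
#' @param t_end final time (s); `Inf` runs to steady state.
#' @param n_core,n_skin elements per layer.
#' @param dt0 initial step (s); default `1e-5 * R_out^2/D_s`.
#' @param dt_max step-size cap (s).
#' @param grow step growth factor on fast convergence.
#' @param steady_tol relative steady-detection threshold.
#' @param max_steps step cap.
#' @param tol Newton tolerance.
#' @param ... passed to [fe_init_state()].
#' @return List with `times` (t, p_gas, p_air, p_vap, r_in, r_out), final
#'   `profile`, final scalars, and `steady`.
#' @export
run_transient_fe <- function(prob, t_end = Inf, n_core = 16, n_skin = 6,
                             dt0 = NULL, dt_max = NULL, grow = 1.6,
                             steady_tol = 1e-9, max_steps = 3000,
                             tol = 1e-9, ...) {
  t_diff <- prob$geom$R_out^2 / prob$gel$D_s
  if (is.null(dt0)) dt0 <- 1e-5 * t_diff
  if (is.null(dt_max)) dt_max <- if (is.finite(t_end)) t_end / 8 else t_diff
  state <- fe_init_state(prob, n_core, n_skin, ...)
  state$J <- NULL
  x_scale <- state$fe$scales
  t <- 0; dt <- dt0
  rows <- list(); peak_rate <- 0; steady <- FALSE
  sn <- fe_snapshot(state$fe, state$x)
  rows[[1]] <- data.frame(t = t, p_gas = sn$p_gas, p_air = sn$p_air,
                          p_vap = sn$p_vap, r_in = sn$r_in, r_m = sn$r_m,
                          r_out = sn$r_out)
  steps <- 0
  while (t < t_end && steps < max_steps) {
    dt_eff <- min(dt, t_end - t)
    x_prev <- state$x
    nxt <- fe_time_step(state, dt_eff, tol = tol)
    retry <- 0
    while (is.null(nxt) && retry < 30) {
      dt_eff <- dt_eff / 2; dt <- dt_eff
      state$J <- NULL
      nxt <- fe_time_step(state, dt_eff, tol = tol)
      retry <- retry + 1
    }
    if (is.null(nxt)) stop("FE step failure: Newton divergence at t = ", t)
    state <- nxt
    t <- t + dt_eff
    steps <- steps + 1
    sn <- fe_snapshot(state$fe, state$x)
    rows[[steps + 1]] <- data.frame(t = t, p_gas = sn$p_gas,
                                    p_air = sn$p_air, p_vap = sn$p_vap,
                                    r_in = sn$r_in, r_m = sn$r_m,
                                    r_out = sn$r_out)
    rate <- max(abs(state$x - x_prev) / x_scale) / dt_eff
    peak_rate <- max(peak_rate, rate)
    if (rate < steady_tol * peak_rate) { steady <- TRUE; break }
    if (state$iter <= 4) dt <- min(dt * grow, dt_max)
  }
  times <- do.call(rbind, rows)
  list(times = times, profile = fe_profile(state$fe, state$x),
       state = state, p_gas = sn$p_gas, p_air = sn$p_air, p_vap = sn$p_vap,
       r_in = sn$r_in, r_out = sn$r_out, steady = steady, steps = steps)
}

#' Steady state via the finite-element solver
#'
#' Pseudo-time continuation: the transient solver is run with aggressive step
#' growth until the state stops changing.
#'
#' @inheritParams run_transient_fe
#' @return As [run_transient_fe()].
#' @export
steady_state_fe <- function(prob, n_core = 16, n_skin = 6, ...) {
  run_transient_fe(prob, t_end = Inf, n_core = n_core, n_skin = n_skin,
                   grow = 2.5, steady_tol = 1e-10, ...)
}
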