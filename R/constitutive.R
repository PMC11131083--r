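#' Cloizeaux osmotic mixing pressure
#'
#' `Pi_mix = alpha * G * (phi/phi_ref)^beta`.  Replaces the Flory-Huggins
#' mixing term: by the c*-theorem the osmotic response of food gels collapses
#' onto a single master curve once scaled with the elastic modulus, with
#' exponent `beta = 9/4`.  Strictly increasing in `phi`.
#'
#' @param phi polymer volume fraction in the current frame, in (0, 1).
#' @param layer a [layer_spec()].
#' @param gel a [gel_params()].
#' @return Osmotic pressure (Pa); vectorised over `phi`.
#' @export
osmotic_pressure_mix <- function(phi, layer, gel) {
  stopifnot(all(phi > 0), all(phi < 1))
  gel$alpha * layer$G * (phi / layer$phi_ref)^gel$beta
}

# phi-hat swelling measure: phi / (phi0 * lambda0); enters sigma_i = phi_hat*G*lambda_i^2 - p
phi_hat_of <- function(phi, layer, gel) phi / (layer$phi0 * gel$lambda0)

#' Neo-Hookean Cauchy stress in spherical symmetry
#'
#' With stretches measured from the free-swollen state and
#' incompressibility `phi/phi0 = 1/(lambda_r * lambda_theta^2)`:
#' `sigma_rr = G*lambda_r/(lambda_theta^2*lambda0) - p_liq` and
#' `sigma_tt = G/(lambda_r*lambda0) - p_liq`, equivalently
#' `sigma_i = phi_hat * G * lambda_i^2 - p_liq`.
#'
#' @param lambda_r,lambda_theta radial and hoop stretches (> 0).
#' @param p_liq liquid hydrostatic pressure (Pa).
#' @param layer a [layer_spec()].
#' @param gel a [gel_params()].
#' @return List with components `sigma_rr`, `sigma_tt` (Pa); vectorised.
#' @export
cauchy_stress <- function(lambda_r, lambda_theta, p_liq, layer, gel) {
  stopifnot(all(lambda_r > 0), all(lambda_theta > 0))
  l0 <- gel$lambda0
  list(sigma_rr = layer$G * lambda_r / (lambda_theta^2 * l0) - p_liq,
       sigma_tt = layer$G / (lambda_r * l0) - p_liq)
}

#' First Piola stress in spherical symmetry
#'
#' Reference-frame stress, `S = sigma F*`:
#' `S_RR = G*lambda_r/lambda0 - p*lambda_theta^2`,
#' `S_tt = G*lambda_theta/lambda0 - p*lambda_theta*lambda_r`.
#' Push-forward identities `S_RR = sigma_rr*lambda_theta^2` and
#' `S_tt = sigma_tt*lambda_theta*lambda_r` hold.
#'
#' @inheritParams cauchy_stress
#' @param p Lagrange (liquid) pressure (Pa).
#' @return List with components `S_RR`, `S_tt` (Pa); vectorised.
#' @export
piola_stress <- function(lambda_r, lambda_theta, p, layer, gel) {
  stopifnot(all(lambda_r > 0), all(lambda_theta > 0))
  l0 <- gel$lambda0
  list(S_RR = layer$G * lambda_r / l0 - p * lambda_theta^2,
       S_tt = layer$G * lambda_theta / l0 - p * lambda_theta * lambda_r)
}

#' Water chemical potential
#'
#' `mu_w = -Pi_mix(phi) + p_liq`, in units of J/m^3 = Pa.
#'
#' @inheritParams osmotic_pressure_mix
#' @param p_liq liquid pressure (Pa).
#' @return Chemical potential (Pa); vectorised.
#' @export
chemical_potential <- function(phi, p_liq, layer, gel) {
  -osmotic_pressure_mix(phi, layer, gel) + p_liq
}

#' Saturated vapour pressure (Tetens relation)
#'
#' `p_sat = 610.78 * exp(17.27*(T - 273.15) / ((T - 273.15) + 237.3))`.
#'
#' @param T temperature (K), in `[273.15, 373.15]`.
#' @return Saturation pressure (Pa); vectorised.
#' @export
p_sat_tetens <- function(T) {
  if (any(T < 273.15 | T > 373.15))
    stop("Tetens relation used outside [273.15, 373.15] K")
  Tc <- T - 273.15
  610.78 * exp(17.27 * Tc / (Tc + 237.3))
}

#' Water activity from chemical potential (and back)
#'
#' `a_w = exp(mu_w * nu_w / (R_gas * T))`, the inverse of
#' `mu_w = (R_gas*T/nu_w) * log(a_w)`.  The caller supplies `mu_w` relative to
#' the appropriate pressure offset (ambient `p0` at the outer surface, `p_gas`
#' at the cavity wall), so that the free-swollen state has `a_w = 1`.
#'
#' @param mu_w chemical potential (Pa).
#' @param gel a [gel_params()].
#' @return Dimensionless activity; warns above 1 (supersaturation).
#' @export
water_activity <- function(mu_w, gel) {
  a <- exp(mu_w * gel$nu_w / (gel$R_gas * gel$T))
  if (any(a > 1 + 1e-9))
    warning("supersaturated state: a_w > 1")
  a
}

#' @rdname water_activity
#' @param a_w water activity.
#' @export
activity_to_potential <- function(a_w, gel) {
  stopifnot(all(a_w > 0))
  gel$R_gas * gel$T / gel$nu_w * log(a_w)
}

#' Initial cavity state
#'
#' In the free-swollen initial state the cavity gas is at ambient pressure and
#' the vapour is saturated: `p_gas = p0`, `p_vap = p_sat(T)`,
#' `p_air = p0 - p_sat(T)`.  The moles of (insoluble) air fixed here are
#' conserved throughout drying.
#'
#' @param geom a [sphere_geometry()].
#' @param gel a [gel_params()].
#' @return An object of class `cavity_state` with fields `N_air`, `N_vap`,
#'   `V_gas`, `p_air`, `p_vap`, `p_gas`, `RH_cav`.
#' @export
cavity_init <- function(geom, gel) {
  V0 <- 4 * pi * geom$R_in^3 / 3
  p_vap <- p_sat_tetens(gel$T)
  p_air <- gel$p0 - p_vap
  if (p_air <= 0) stop("ambient pressure below saturation pressure")
  RT <- gel$R_gas * gel$T
  structure(list(N_air = p_air * V0 / RT, N_vap = p_vap * V0 / RT,
                 V_gas = V0, p_air = p_air, p_vap = p_vap, p_gas = gel$p0,
                 RH_cav = 1),
            class = "cavity_state")
}

#' Cavity state from the mechanical pressure and wall chemical potential
#'
#' Local equilibrium of the gas bubble: the total pressure balances the radial
#' traction, `p_gas = -sigma_rr(r_in)`; the vapour is in equilibrium with the
#' gel at the cavity wall, `p_vap = a_w * p_sat(T)` with
#' `a_w = exp((mu_w(r_in) - p_gas) * nu_w / (R_gas*T))`; the remaining partial
#' pressure is air.  Depending on `mode`, either the gas volume is updated from
#' the air isotherm `p_air * V_gas = N_air * R_gas * T` (`"volume"`, the
#' transient finite-volume usage) or `V_gas` is taken as given and `N_vap`
#' recomputed (`"moles"`).
#'
#' @param sigma_rr_inner radial Cauchy stress at the cavity wall (Pa).
#' @param mu_w_inner water chemical potential at the cavity wall (Pa).
#' @param V_gas current gas volume (m^3); used directly in `"moles"` mode and
#'   as a fallback diagnostic in `"volume"` mode.
#' @param cavity a `cavity_state` (supplies the conserved `N_air`).
#' @param gel a [gel_params()].
#' @param mode `"volume"` or `"moles"`; see Details.
#' @return Updated `cavity_state`.
#' @export
cavity_from_pressure <- function(sigma_rr_inner, mu_w_inner, V_gas, cavity,
                                 gel, mode = c("volume", "moles")) {
  mode <- match.arg(mode)
  RT <- gel$R_gas * gel$T
  p_gas <- -sigma_rr_inner
  a_w <- exp((mu_w_inner - p_gas) * gel$nu_w / RT)
  p_vap <- a_w * p_sat_tetens(gel$T)
  p_air <- p_gas - p_vap
  if (p_air <= 0)
    stop("nonphysical cavity state: p_vap >= p_gas (negative air pressure)")
  if (mode == "volume") V_gas <- cavity$N_air * RT / p_air
  N_vap <- p_vap * V_gas / RT
  structure(list(N_air = cavity$N_air, N_vap = N_vap, V_gas = V_gas,
                 p_air = p_air, p_vap = p_vap, p_gas = p_gas,
                 RH_cav = p_vap / p_sat_tetens(gel$T)),
            class = "cavity_state")
}
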