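#' Global gel-physics constants
#'
#' Bundles the material and thermodynamic constants shared by all solvers.
#' The free-swelling stretch satisfies `lambda0^3 = 3/2`, a value found to be
#' universal for food biopolymer gels independent of crosslink density.  The
#' osmotic prefactor defaults to `alpha = lambda0^(23/4)`, the unique value for
#' which the free-swollen state (water activity 1) is a stationary state of the
#' constitutive laws themselves, so that a sphere left in pure water does not
#' drift.
#'
#' @param T temperature (K).
#' @param p0 ambient pressure (Pa).
#' @param alpha dimensionless osmotic prefactor (> 1); default `lambda0^(23/4)`.
#' @param beta Cloizeaux scaling exponent; 9/4 by the c*-theorem.
#' @param lambda0_cubed cube of the free-swelling stretch; default 3/2.
#' @param nu_w water molar volume (m^3/mol).
#' @param D_s water self-diffusivity in the gel (m^2/s).
#' @param R_gas gas constant (J/mol/K).
#' @return An object of class `gel_params`.
#' @export
gel_params <- function(T = 308, p0 = 101325, alpha = NULL, beta = 9 / 4,
                       lambda0_cubed = 3 / 2, nu_w = 1.8e-5, D_s = 1e-9,
                       R_gas = 8.314) {
  stopifnot(T > 0, p0 > 0, nu_w > 0, D_s > 0, lambda0_cubed > 1)
  lambda0 <- lambda0_cubed^(1 / 3)
  if (is.null(alpha)) alpha <- lambda0^(23 / 4)
  if (alpha <= 1) stop("alpha must exceed 1")
  structure(list(alpha = alpha, beta = beta, lambda0 = lambda0,
                 nu_w = nu_w, D_s = D_s, T = T, R_gas = R_gas, p0 = p0),
            class = "gel_params")
}

#' Reference polymer fraction of the skin from the c*-theorem
#'
#' A denser (stiffer) network carries a larger polymer fraction at preparation:
#' `phi_skin = phi_core * (G_skin/G_core)^(1/beta)`.
#'
#' @param G_core,G_skin shear moduli (Pa), `G_skin >= G_core`.
#' @param phi_core reference polymer volume fraction of the core.
#' @param beta scaling exponent (default 9/4).
#' @return Reference polymer fraction of the skin.
#' @export
skin_phi_ref <- function(G_core, G_skin, phi_core, beta = 9 / 4) {
  stopifnot(G_core > 0, G_skin > 0, phi_core > 0, beta > 0)
  out <- phi_core * (G_skin / G_core)^(1 / beta)
  if (any(out >= 1))
    stop("derived skin polymer fraction >= 1: skin denser than pure polymer")
  out
}

#' Per-layer material specification
#'
#' @param G shear modulus (Pa).
#' @param phi_ref polymer volume fraction in the unstretched state, in (0, 1).
#' @param gel a [gel_params()] object (supplies lambda0).
#' @return An object of class `layer_spec` with fields `G`, `phi_ref` and the
#'   free-swollen fraction `phi0 = phi_ref / lambda0^3`.
#' @export
layer_spec <- function(G, phi_ref, gel) {
  stopifnot(inherits(gel, "gel_params"), G > 0, phi_ref > 0, phi_ref < 1)
  structure(list(G = G, phi_ref = phi_ref, phi0 = phi_ref / gel$lambda0^3),
            class = "layer_spec")
}

#' Initial (free-swollen) geometry of the core-shell sphere
#'
#' @param R_in initial cavity radius (m).
#' @param R_m initial core/skin interface radius (m).
#' @param R_out initial outer radius (m).
#' @return An object of class `sphere_geometry`; `t_skin = R_out - R_m`.
#' @export
sphere_geometry <- function(R_in, R_m, R_out) {
  if (!(0 < R_in && R_in < R_m && R_m < R_out))
    stop("geometry requires 0 < R_in < R_m < R_out")
  structure(list(R_in = R_in, R_m = R_m, R_out = R_out,
                 t_skin = R_out - R_m),
            class = "sphere_geometry")
}

#' External drying environment
#'
#' The external water chemical potential is `mu_ext = p0 - Pi_ext`; the
#' matching relative humidity is `RH_ext = exp(-Pi_ext * nu_w / (R_gas * T))`,
#' derived automatically when not supplied.
#'
#' @param Pi_ext external osmotic pressure (Pa), >= 0.
#' @param gel a [gel_params()] object.
#' @param RH_ext external relative humidity in `[0, 1]`; default derived from
#'   `Pi_ext`.
#' @param h_air external heat-transfer coefficient (W/m^2/K); sets the mass
#'   transfer coefficient through the Lewis relation.
#' @param rho_air,cp_air air density (kg/m^3) and heat capacity (J/kg/K).
#' @param D_vap vapour diffusivity in air (m^2/s), used for the cavity-side
#'   boundary layer.
#' @return An object of class `drying_environment`.
#' @export
drying_environment <- function(Pi_ext, gel, RH_ext = NULL, h_air = 20,
                               rho_air = 1.2, cp_air = 1005, D_vap = 2.5e-5) {
  stopifnot(inherits(gel, "gel_params"), Pi_ext >= 0)
  if (is.null(RH_ext))
    RH_ext <- exp(-Pi_ext * gel$nu_w / (gel$R_gas * gel$T))
  stopifnot(RH_ext >= 0, RH_ext <= 1)
  structure(list(Pi_ext = Pi_ext, RH_ext = RH_ext, h_air = h_air,
                 rho_air = rho_air, cp_air = cp_air, D_vap = D_vap,
                 mu_ext = gel$p0 - Pi_ext,
                 beta_air = h_air / (rho_air * cp_air)),
            class = "drying_environment")
}

#' Assemble a complete drying problem from dimensionless ratios
#'
#' Convenience constructor mirroring how the reference experiments are stated:
#' stiffness ratio, scaled external osmotic pressure, and geometry fractions.
#' All headline outputs are reported in the same scaled groups
#' (`Pi_ext/G_core`, `p_gas/p0`, `r/R_out`), so the absolute defaults for
#' `G_core`, `R_out` and `D_s` cancel except through `p0/G_core`.
#'
#' @param G_core core shear modulus (Pa).
#' @param G_ratio skin-to-core stiffness ratio `G_skin/G_core` (>= 1).
#' @param Pi_ext_over_G external osmotic pressure scaled by `G_core`.
#' @param R_in_frac,t_skin_frac initial cavity radius and skin thickness as
#'   fractions of `R_out`.
#' @param R_out outer radius (m).
#' @param phi_core reference polymer fraction of the core.
#' @param T temperature (K).
#' @param ... further arguments passed to [gel_params()] and
#'   [drying_environment()] (e.g. `alpha`, `p0`, `D_s`, `h_air`, `D_vap`,
#'   `RH_ext`).
#' @return An object of class `drying_problem` with elements `gel`, `core`,
#'   `skin`, `geom`, `env` and `cavity0` (initial cavity state).
#' @export
drying_problem <- function(G_core = 1.89e5, G_ratio = 20, Pi_ext_over_G = 20,
                           R_in_frac = 0.6, t_skin_frac = 0.05, R_out = 5e-3,
                           phi_core = 0.05, T = 308, ...) {
  stopifnot(G_ratio >= 1, R_in_frac > 0, t_skin_frac > 0,
            R_in_frac + t_skin_frac < 1)
  dots <- list(...)
  gel_args <- dots[names(dots) %in% names(formals(gel_params))]
  env_args <- dots[names(dots) %in%
                     setdiff(names(formals(drying_environment)),
                             c("Pi_ext", "gel"))]
  unknown <- setdiff(names(dots),
                     c(names(gel_args), names(env_args)))
  if (length(unknown)) stop("unknown arguments: ", paste(unknown, collapse = ", "))
  gel <- do.call(gel_params, c(list(T = T), gel_args))
  G_skin <- G_core * G_ratio
  core <- layer_spec(G_core, phi_core, gel)
  skin <- layer_spec(G_skin,
                     skin_phi_ref(G_core, G_skin, phi_core, gel$beta), gel)
  geom <- sphere_geometry(R_in = R_in_frac * R_out,
                          R_m = (1 - t_skin_frac) * R_out,
                          R_out = R_out)
  env <- do.call(drying_environment,
                 c(list(Pi_ext = Pi_ext_over_G * G_core, gel = gel), env_args))
  structure(list(gel = gel, core = core, skin = skin, geom = geom, env = env,
                 cavity0 = cavity_init(geom, gel)),
            class = "drying_problem")
}

#' @export
print.drying_problem <- function(x, ...) {
  g <- x$gel
  cat("<drying_problem>\n")
  cat(sprintf("  G_core = %.4g Pa, G_skin/G_core = %.4g\n",
              x$core$G, x$skin$G / x$core$G))
  cat(sprintf("  Pi_ext/G_core = %.4g, T = %g K, p0 = %g Pa\n",
              x$env$Pi_ext / x$core$G, g$T, g$p0))
  cat(sprintf("  R_in/R_out = %.3g, t_skin/R_out = %.3g, R_out = %.3g m\n",
              x$geom$R_in / x$geom$R_out, x$geom$t_skin / x$geom$R_out,
              x$geom$R_out))
  invisible(x)
}

#' Read a flat key-value parameter config
#'
#' Lines of the form `key = value` (or `key: value`); `#` starts a comment.
#' Recognised keys: G_core, G_ratio, t_skin_frac, R_in_frac, R_out,
#' Pi_ext_over_G, T, p0, alpha, beta, lambda0_cubed, nu_w, D_s, h_air, D_vap,
#' RH_ext, phi_core.  All SI units.
#'
#' @param path file path.
#' @return A [drying_problem()] built from the file's values.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "[=:]")
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad)) stop("malformed config line(s): ", paste(lines[bad], collapse = "; "))
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- as.numeric(trimws(vapply(kv, `[[`, "", 2L)))
  if (anyNA(vals)) stop("non-numeric config value(s)")
  allowed <- c("G_core", "G_ratio", "t_skin_frac", "R_in_frac", "R_out",
               "Pi_ext_over_G", "T", "p0", "alpha", "beta", "lambda0_cubed",
               "nu_w", "D_s", "h_air", "D_vap", "RH_ext", "phi_core")
  unknown <- setdiff(keys, allowed)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(drying_problem, as.list(stats::setNames(vals, keys)))
}
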