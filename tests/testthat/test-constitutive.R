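test_that("skin reference polymer fraction follows the c*-theorem scaling", {
  expect_equal(skin_phi_ref(1e5, 1e5, 0.05), 0.05)
  expect_equal(skin_phi_ref(1e5, 20e5, 0.05), 0.05 * 20^(4 / 9),
               tolerance = 1e-12)
  expect_equal(skin_phi_ref(1e5, 20e5, 0.05), 0.1893, tolerance = 1e-3)
  expect_equal(skin_phi_ref(1e5, 10e5, 0.05), 0.1391, tolerance = 1e-3)
  expect_error(skin_phi_ref(1e5, 1e9, 0.5), "denser")
})

test_that("osmotic mixing pressure: reference point, initial state, limits", {
  g <- default_gel()
  core <- layer_spec(1.89e5, 0.05, g)
  expect_equal(osmotic_pressure_mix(core$phi_ref, core, g),
               g$alpha * core$G)
  # at the free-swollen fraction phi0 (phi_tilde = 2/3) the closed form is
  # alpha*G*(2/3)^(9/4) = G/lambda0 = (2/3)^(1/3)*G for alpha = lambda0^(23/4)
  expect_equal(osmotic_pressure_mix(core$phi0, core, g),
               core$G / g$lambda0, tolerance = 1e-12)
  expect_equal(osmotic_pressure_mix(core$phi0, core, g) / core$G,
               0.87358, tolerance = 1e-5)
  expect_lt(osmotic_pressure_mix(1e-9, core, g), 1e-3)
  # strictly increasing
  phis <- seq(0.01, 0.9, length.out = 50)
  expect_true(all(diff(osmotic_pressure_mix(phis, core, g)) > 0))
})

test_that("stress identities hold on random states", {
  g <- default_gel()
  core <- layer_spec(1.89e5, 0.05, g)
  st <- random_states(1000)
  phi <- core$phi0 / (st$lambda_r * st$lambda_theta^2)
  phi_hat <- phi / (core$phi0 * g$lambda0)
  cs <- cauchy_stress(st$lambda_r, st$lambda_theta, st$p_liq, core, g)
  # deviatoric identity sigma_rr - sigma_tt = phi_hat*G*(l_r^2 - l_t^2)
  expect_equal(cs$sigma_rr - cs$sigma_tt,
               phi_hat * core$G * (st$lambda_r^2 - st$lambda_theta^2),
               tolerance = 1e-12)
  # push-forward to the first Piola stress
  ps <- piola_stress(st$lambda_r, st$lambda_theta, st$p_liq, core, g)
  expect_equal(ps$S_RR, cs$sigma_rr * st$lambda_theta^2, tolerance = 1e-12)
  expect_equal(ps$S_tt, cs$sigma_tt * st$lambda_theta * st$lambda_r,
               tolerance = 1e-12)
})

test_that("undeformed state with p = G/lambda0 + p0 carries ambient traction", {
  g <- default_gel()
  for (G in c(1.89e5, 20 * 1.89e5)) {
    lay <- layer_spec(G, if (G > 1e6) skin_phi_ref(1.89e5, G, 0.05) else 0.05, g)
    cs <- cauchy_stress(1, 1, G / g$lambda0 + g$p0, lay, g)
    expect_equal(cs$sigma_rr, -g$p0)
    expect_equal(cs$sigma_tt, -g$p0)
    ps <- piola_stress(1, 1, G / g$lambda0 + g$p0, lay, g)
    expect_equal(ps$S_RR, -g$p0)
  }
  # isotropic stretch with no constraint pressure
  cs <- cauchy_stress(1.3, 1.3, 0, layer_spec(1e5, 0.05, g), g)
  expect_equal(cs$sigma_rr, cs$sigma_tt)
  expect_equal(piola_stress(1.3, 1.3, 0, layer_spec(1e5, 0.05, g), g)$S_RR,
               1e5 * 1.3 / g$lambda0)
})

test_that("free-swollen state is stationary: mu_w = p0 in both layers", {
  g <- default_gel()
  core <- layer_spec(1.89e5, 0.05, g)
  skin <- layer_spec(20 * 1.89e5, skin_phi_ref(1.89e5, 20 * 1.89e5, 0.05), g)
  for (lay in list(core, skin)) {
    p_init <- lay$G / g$lambda0 + g$p0
    expect_equal(chemical_potential(lay$phi0, p_init, lay, g), g$p0,
                 tolerance = 1e-9 * g$p0)
  }
  # monotonicity: drier gel at fixed pressure has lower mu
  mus <- chemical_potential(seq(0.03, 0.3, length.out = 20), 1e5, core, g)
  expect_true(all(diff(mus) < 0))
  expect_equal(chemical_potential(0.1, osmotic_pressure_mix(0.1, core, g),
                                  core, g), 0)
})

test_that("Tetens saturation pressure and water activity conversions", {
  expect_equal(p_sat_tetens(273.15), 610.78)
  expect_equal(p_sat_tetens(308.15), 5623, tolerance = 1e-3)
  expect_equal(p_sat_tetens(338.15), 25.0e3, tolerance = 5e-3)
  expect_error(p_sat_tetens(200), "Tetens")
  g <- gel_params(T = 308)
  expect_equal(water_activity(0, g), 1)
  # severe drying: Pi_ext/G_core ~ 2000 with the derived default G_core
  expect_equal(water_activity(-3.783e8, g), 0.07, tolerance = 2e-3)
  mu <- activity_to_potential(0.42, g)
  expect_equal(water_activity(mu, g), 0.42, tolerance = 1e-12)
  expect_warning(water_activity(1e6, g), "supersaturated")
})

test_that("cavity initialisation: saturated vapour at ambient pressure", {
  g <- gel_params(T = 308.15)
  geom <- sphere_geometry(0.6e-3, 0.95e-3, 1e-3)
  cav <- cavity_init(geom, g)
  expect_equal(cav$p_gas, g$p0)
  expect_equal(cav$p_vap, p_sat_tetens(308.15))
  expect_equal(cav$p_air, 101325 - 5623, tolerance = 1e-4)
  expect_equal(cav$p_air * cav$V_gas, cav$N_air * g$R_gas * g$T)
  expect_equal(cav$RH_cav, 1)
})

test_that("cavity update: equilibrium is a fixed point; gas laws hold", {
  g <- gel_params(T = 308)
  geom <- sphere_geometry(0.6e-3, 0.95e-3, 1e-3)
  cav <- cavity_init(geom, g)
  # saturated cavity at ambient pressure with a_w = 1: nothing changes
  upd <- cavity_from_pressure(-g$p0, g$p0, cav$V_gas, cav, g, mode = "volume")
  expect_equal(upd$V_gas, cav$V_gas, tolerance = 1e-12)
  expect_equal(upd$N_vap, cav$N_vap, tolerance = 1e-12)
  expect_equal(upd$p_gas, g$p0)
  # air is conserved and follows the isotherm: doubling p_air halves V_gas
  upd2 <- cavity_from_pressure(-(2 * upd$p_air + upd$p_vap), g$p0,
                               cav$V_gas, cav, g, mode = "volume")
  expect_equal(upd2$N_air, cav$N_air)
  expect_equal(upd2$V_gas, cav$V_gas * upd$p_air / upd2$p_air,
               tolerance = 1e-9)
  # vapour above total pressure is nonphysical
  expect_error(cavity_from_pressure(-1e3, g$p0, cav$V_gas, cav, g),
               "nonphysical")
})

test_that("volume ratio J round-trips between phi and concentration forms", {
  g <- default_gel()
  core <- layer_spec(1.89e5, 0.05, g)
  st <- random_states(200, seed = 7)
  J <- st$lambda_r * st$lambda_theta^2
  phi <- core$phi0 / J
  c_w <- (J - core$phi0) / g$nu_w      # J = phi0 + nu_w*c
  expect_equal(core$phi0 + g$nu_w * c_w, core$phi0 / phi, tolerance = 1e-12)
})

test_that("config round trip builds the equivalent problem", {
  path <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("G_core = 2e5", "G_ratio = 10", "Pi_ext_over_G: 15",
               "R_in_frac = 0.5  # initial pore",
               "t_skin_frac = 0.04", "T = 318"), path)
  pr <- read_config(path)
  expect_equal(pr$core$G, 2e5)
  expect_equal(pr$skin$G / pr$core$G, 10)
  expect_equal(pr$env$Pi_ext, 15 * 2e5)
  expect_equal(pr$geom$R_in / pr$geom$R_out, 0.5)
  expect_equal(pr$gel$T, 318)
  writeLines("nonsense = 1", path)
  expect_error(read_config(path), "unknown config key")
})
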