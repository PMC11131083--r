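test_that("mesh construction aligns faces with layer boundaries", {
  pr <- drying_problem(R_in_frac = 0.6, t_skin_frac = 0.05, R_out = 1)
  st <- build_mesh(pr, n_core = 10, n_skin = 4)
  expect_length(st$dV_s, 14)
  expect_equal(st$R_face[1], 0.6)
  expect_equal(st$R_face[11], 0.95)   # interface is exactly a CV boundary
  expect_equal(st$R_face[15], 1)
  # total initial volume and per-layer polymer fractions
  expect_equal(sum(st$dV_s + st$dV_w), 4 * pi / 3 * (1 - 0.6^3),
               tolerance = 1e-12)
  phi <- st$dV_s / (st$dV_s + st$dV_w)
  expect_equal(phi[st$layer == 1L], rep(pr$core$phi0, 10))
  expect_equal(phi[st$layer == 2L], rep(pr$skin$phi0, 4))
  expect_error(build_mesh(pr, n_core = 2, n_skin = 4))
})

test_that("momentum integration: uniform swelling and initial state", {
  pr <- drying_problem(Pi_ext_over_G = 0, G_ratio = 20)
  st <- build_mesh(pr, 10, 4)
  m <- integrate_momentum(st)
  gel <- pr$gel
  # lambda_r = lambda_theta = 1 everywhere: sigma_rr = -p0, outer face exact
  expect_equal(m$sigma_face, rep(-gel$p0, 15), tolerance = 1e-10)
  expect_equal(m$p_gas, gel$p0, tolerance = 1e-9)
  # p_liq = G/lambda0 + p0 per layer
  G <- ifelse(st$layer == 1L, pr$core$G, pr$skin$G)
  expect_equal(m$p_liq, G / gel$lambda0 + gel$p0, tolerance = 1e-9)
  expect_equal(m$mu, rep(gel$p0, 14), tolerance = 1e-6)
})

test_that("face fluxes: zero at uniform potential, sign and magnitude", {
  pr <- drying_problem(Pi_ext_over_G = 0)
  st <- build_mesh(pr, 10, 4)
  J <- compute_fluxes(st, mode = "closed")
  expect_equal(J, rep(0, 15), tolerance = 1e-20)
  # direct evaluation: mu difference of 1e6 Pa over 1e-3 m at r = 1e-2 m
  gel <- pr$gel
  mob <- gel$D_s * gel$nu_w / (gel$R_gas * gel$T)
  expect_equal(-mob * 1e6 / 1e-3 * 4 * pi * 1e-4,
               -mob * 1e9 * 4 * pi * 1e-4)  # water flows down-gradient
  # antisymmetry through the Dirichlet ghost: flux flips with the gradient
  f <- drygel:::fv_fields(st)
  Jd <- compute_fluxes(st, f, mode = "dirichlet")
  pr2 <- pr; pr2$env$mu_ext <- 2 * f$mu[14] - pr$env$mu_ext
  st2 <- st; st2$prob <- pr2
  Jd2 <- compute_fluxes(st2, f, mode = "dirichlet")
  expect_equal(Jd[15], -Jd2[15], tolerance = 1e-12)
})

test_that("free-swollen state is a fixed point of the transient scheme", {
  pr <- drying_problem(Pi_ext_over_G = 0, G_ratio = 20)
  st <- build_mesh(pr, 8, 4)
  s <- st
  for (k in 1:100) {
    f <- drygel:::fv_fields(s)
    s <- fv_step(s, drygel:::fv_stable_dt(s, f))
  }
  expect_equal(s$dV_w, st$dV_w, tolerance = 1e-9)
  expect_equal(s$V_gas, st$V_gas, tolerance = 1e-9)
  expect_equal(s$N_vap, st$N_vap, tolerance = 1e-9)
})

test_that("closed-system water, polymer and air are conserved exactly", {
  pr <- drying_problem(G_ratio = 5, Pi_ext_over_G = 2, R_in_frac = 0.6)
  st <- build_mesh(pr, 10, 4)
  s <- st
  tot0 <- sum(s$dV_w) + pr$gel$nu_w * s$N_vap
  for (k in 1:400) {
    f <- drygel:::fv_fields(s)
    s <- fv_step(s, drygel:::fv_stable_dt(s, f), mode = "closed")
  }
  tot1 <- sum(s$dV_w) + pr$gel$nu_w * s$N_vap
  expect_equal(tot1, tot0, tolerance = 1e-12)
  expect_identical(s$dV_s, st$dV_s)           # polymer volume untouched
  expect_identical(s$N_air, st$N_air)         # air moles untouched
  expect_gt(s$time, 0)
})

test_that("cavity update follows the air isotherm", {
  pr <- drying_problem()
  st <- build_mesh(pr, 8, 4)
  upd <- update_cavity(st)
  expect_equal(upd$dN_vap, 0, tolerance = 1e-10 * st$N_vap)
  expect_equal(upd$cavity$V_gas, st$V_gas, tolerance = 1e-6)
  expect_equal(upd$cavity$p_air * upd$cavity$V_gas,
               st$N_air * pr$gel$R_gas * pr$gel$T, tolerance = 1e-9)
})

test_that("early drying dries the outer shells first", {
  pr <- drying_problem(G_ratio = 5, Pi_ext_over_G = 4)
  st <- build_mesh(pr, 12, 4)
  s <- st
  for (k in 1:300) {
    f <- drygel:::fv_fields(s)
    s <- fv_step(s, drygel:::fv_stable_dt(s, f))
  }
  f <- drygel:::fv_fields(s)
  n <- length(f$mu)
  # chemical potential decreases towards the outer (drying) boundary
  expect_lt(f$mu[n], f$mu[1])
  # the skin dries first, from the outside in; the deep core is untouched
  expect_true(all(diff(f$phi_w[s$layer == 2L]) < 0))
  expect_equal(f$phi_w[1], 1 - pr$core$phi0, tolerance = 1e-6)
})

test_that("FV steady state matches the analytic solution for a single layer", {
  pr <- drying_problem(G_ratio = 1, Pi_ext_over_G = 10, R_in_frac = 0.6)
  sa <- core_shell_steady(pr)
  sf <- steady_state_fv(pr, n_core = 40, n_skin = 8)
  expect_equal(sf$Lambda_in, sa$Lambda_in, tolerance = 0.02)
  expect_equal(sf$p_gas, sa$p_gas, tolerance = 0.02)
  # sigma_rr at the outer face is the ambient traction, exactly
  expect_equal(-pr$gel$p0,
               max(sf$profile$sigma_rr[nrow(sf$profile)]) -
                 (sf$profile$sigma_rr[nrow(sf$profile)] + pr$gel$p0))
})

test_that("identity steady solution for the FV steady solver", {
  pr <- drying_problem(Pi_ext_over_G = 0)
  s <- steady_state_fv(pr, n_core = 12, n_skin = 4)
  expect_equal(s$Lambda_in, 1, tolerance = 1e-7)
  expect_equal(s$p_gas, pr$gel$p0, tolerance = 1e-7)
})

test_that("hoop stretch is continuous and radial stretch jumps at the interface", {
  pr <- drying_problem(G_ratio = 20, Pi_ext_over_G = 10, R_in_frac = 0.7)
  s <- steady_state_fv(pr, n_core = 40, n_skin = 8)
  prof <- s$profile
  i <- max(which(prof$layer == "core"))
  # lambda_theta continuous across the interface (neighbouring CVs agree)
  dl_t <- abs(prof$lambda_theta[i + 1] - prof$lambda_theta[i])
  expect_lt(dl_t / prof$lambda_theta[i], 0.01)
  # lambda_r jumps by a finite amount there
  dl_r <- abs(prof$lambda_r[i + 1] - prof$lambda_r[i])
  expect_gt(dl_r / prof$lambda_r[i], 0.05)
})

test_that("transient trajectory is flat without drying and dries otherwise", {
  pr0 <- drying_problem(Pi_ext_over_G = 0)
  tr0 <- run_transient_fv(pr0, t_end = 2e3, n_core = 8, n_skin = 4)
  expect_lt(diff(range(tr0$times$p_gas)) / pr0$gel$p0, 1e-8)
  expect_lt(diff(range(tr0$times$r_in)) / pr0$geom$R_in, 1e-8)
})
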