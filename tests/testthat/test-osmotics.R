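sv <- solvent_spec()  # water, 298.15 K
scl <- pressure_scale(sv)

test_that("virial mixing pressure matches hand evaluation", {
  expect_equal(mixing_pressure_virial(0.3, 0, 0, sv), 0)
  expect_equal(mixing_pressure_virial(0.05, 0.1, 0.5, sv),
               scl * (0.1 * 0.05^2 + 0.5 * 0.05^3), tolerance = 1e-14)
  # leading-order limit: Pi/phi^2 -> A2 * RT/V1
  phi <- 1e-6
  expect_equal(mixing_pressure_virial(phi, 0.1, 0.5, sv) / phi^2,
               0.1 * scl, tolerance = 1e-5)
  expect_error(mixing_pressure_virial(1.2, 0.1, 0.5, sv), "phi")
})

test_that("Flory-Huggins form matches hand evaluation and vanishes at phi -> 0", {
  expect_equal(mixing_pressure_flory_huggins(0.1, 0, 0, sv),
               -scl * (log(0.9) + 0.1), tolerance = 1e-14)
  expect_lt(abs(mixing_pressure_flory_huggins(1e-9, 0.3, 0.1, sv)) / scl, 1e-15)
  expect_error(mixing_pressure_flory_huggins(1, 0, 0, sv), "phi")
})

test_that("chi <-> virial mapping agrees with the series expansion of the FH form", {
  expect_equal(chi_to_virial(0, 0), list(A2 = 0.5, A3 = 1 / 3))
  expect_equal(chi_to_virial(0.5, 0)$A2, 0)  # theta condition
  # round trip is the identity
  ab <- chi_to_virial(0.37, -0.12)
  expect_equal(virial_to_chi(ab$A2, ab$A3), list(chi0 = 0.37, chi1 = -0.12))

  # numerical series oracle: regress the reduced FH pressure on (phi^2..phi^5)
  # at small phi; the leading coefficients must be the mapped virials
  for (chi in list(c(0, 0), c(0.5, 0.1), c(0.3, -0.2))) {
    phi <- seq(1e-4, 5e-3, length.out = 40)
    y <- mixing_pressure_flory_huggins(phi, chi[1], chi[2], sv) / scl
    cf <- stats::coef(stats::lm(y ~ 0 + I(phi^2) + I(phi^3) + I(phi^4) + I(phi^5)))
    expect_equal(cf[[1]], 0.5 - chi[1], tolerance = 1e-6)
    expect_equal(cf[[2]], 1 / 3 - chi[2], tolerance = 1e-3)
  }
})

test_that("FH-virial discrepancy is bounded by the quartic Taylor remainder", {
  # |FH - virial| / (RT/V1) <= phi^4 / (4 (1 - phi)) for phi <= 0.2
  for (chi in list(c(0, 0), c(0.45, 0.05), c(0.6, -0.3))) {
    ab <- chi_to_virial(chi[1], chi[2])
    phi <- seq(0.005, 0.2, by = 0.005)
    gap <- abs(mixing_pressure_flory_huggins(phi, chi[1], chi[2], sv) -
                 mixing_pressure_virial(phi, ab$A2, ab$A3, sv)) / scl
    expect_true(all(gap <= phi^4 / (4 * (1 - phi)) + 1e-15))
  }
})

test_that("Donnan solver reproduces the 1:1 closed form and its limits", {
  grid <- expand.grid(cf = c(0.1, 1, 5, 20, 100, 400, 1000, 4000, 1e4, 5e4),
                      cs = c(0.01, 0.1, 1, 5, 20, 40, 100, 400, 1000, 1e4))
  ic_for <- function(cs, f, Vm) {
    ionic_condition(data.frame(species = c("Na", "Cl"), z = c(1, -1),
                               conc = c(cs, cs)), f, Vm)
  }
  phi <- 0.05
  for (i in seq_len(nrow(grid))) {
    cf <- grid$cf[i]; cs <- grid$cs[i]
    # pick f, Vm so that the fixed-charge concentration equals cf at this phi
    ic <- ic_for(cs, f = 1, Vm = phi / cf)
    num <- donnan_pressure(phi, ic, sv)
    ref <- donnan_pressure_closed_form_1_1(cf, cs, sv)
    expect_lt(abs(num - ref) / ref, 1e-10)
  }
  # no fixed charge -> no ionic pressure
  expect_equal(donnan_pressure(0.05, ic_for(40, 0, 6e-5), sv), 0)
  # counter-ion ideal-gas limit c_s -> 0: Pi_ion -> RT c_f
  cf <- 50
  expect_equal(donnan_pressure_closed_form_1_1(cf, 1e-12, sv),
               sv$R * sv$T * cf, tolerance = 1e-9)
  # salt-excess limit: Pi_ion -> 0
  expect_lt(donnan_pressure_closed_form_1_1(1, 1e6, sv), 1e-3)
})

test_that("Donnan pressure is non-negative and decreases with added salt", {
  phi <- 0.08
  prev <- Inf
  for (cs in c(1, 5, 20, 50, 150, 500)) {
    ic <- ionic_condition(data.frame(species = c("Na", "Cl"), z = c(1, -1),
                                     conc = c(cs, cs)), 0.05)
    p <- donnan_pressure(phi, ic, sv)
    expect_gte(p, 0)
    expect_lt(p, prev)
    prev <- p
  }
  # divalent external salt is handled by the same solver (electroneutral mix)
  ic2 <- ionic_condition(data.frame(species = c("Na", "Cl", "Ca"),
                                    z = c(1, -1, 2), conc = c(40, 44, 2)), 0.05)
  expect_gt(donnan_pressure(phi, ic2, sv), 0)
  expect_error(ionic_condition(data.frame(species = "Na", z = 1, conc = 10), 0.1),
               "electroneutral")
})

test_that("decomposition inverts the forward model and honours trivial cases", {
  cfg <- scenario_config("polyelectrolyte_salt_sweep", noise_rel = 0)
  m <- scenario_model(cfg, 0.5)
  cu <- generate_deswelling_series(m, noise = noise_model(scale = 0))
  mix <- decompose_swelling_pressure(cu, list(C = m$C, phi_ref = m$phi_ref),
                                     m$ions, sv)
  expect_equal(mix$pressure, cu$condition$Pi_mix_true, tolerance = 1e-9)
  expect_identical(mix$pressure_kind, "mixing")

  # G_s = 0, ions off: identity map
  m0 <- gel_model(0.09, 0.4, C = 0, solvent = sv)
  cu0 <- generate_deswelling_series(m0, noise = noise_model(scale = 0))
  mix0 <- decompose_swelling_pressure(cu0, 0, NULL, sv)
  expect_equal(mix0$pressure, cu0$pressure, tolerance = 1e-14)

  # ions present but zero fixed charge: identical to ions off
  icz <- ionic_condition(data.frame(species = c("Na", "Cl"), z = c(1, -1),
                                    conc = c(40, 40)), 0)
  mixz <- decompose_swelling_pressure(cu0, 0, icz, sv)
  expect_equal(mixz$pressure, mix0$pressure, tolerance = 1e-14)

  expect_error(decompose_swelling_pressure(mix, 0, NULL, sv), "total/swelling")
  expect_error(decompose_swelling_pressure(cu0, NULL), "G_s")
})

test_that("virial fit recovers coefficients exactly from noiseless data", {
  m <- gel_model(0.09, 0.4, C = 0, solvent = sv)
  phi <- exp(seq(log(0.01), log(0.2), length.out = 12))
  cu <- osmotic_curve(phi, mixing_pressure_virial(phi, 0.09, 0.4, sv),
                      pressure_kind = "mixing")
  fit <- fit_virial_coefficients(cu, sv)
  expect_equal(fit$A2, 0.09, tolerance = 1e-12)
  expect_equal(fit$A3, 0.4, tolerance = 1e-12)
  expect_equal(fit$scale, scl)
  expect_true(isSymmetric(fit$covariance))
  expect_true(all(eigen(fit$covariance)$values >= -1e-20))

  # all pressures zero -> both coefficients zero
  fit0 <- fit_virial_coefficients(
    osmotic_curve(phi, rep(0, 12), pressure_kind = "mixing"), sv)
  expect_equal(fit0$A2, 0)
  expect_equal(fit0$A3, 0)
  expect_equal(fit0$residual_rms, 0)

  expect_error(fit_virial_coefficients(
    osmotic_curve(rep(0.05, 4), rep(1, 4), pressure_kind = "mixing"), sv),
    "rank-deficient")
  expect_error(fit_virial_coefficients(cu0 <- osmotic_curve(
    phi, cu$pressure, pressure_kind = "total"), sv), "mixing")
})

test_that("confidence intervals cover the true virials at the nominal rate", {
  cfg <- scenario_config("polyelectrolyte_salt_sweep", noise_rel = 0.05)
  m <- scenario_model(cfg, 0)
  phi <- exp(seq(log(0.01), log(0.2), length.out = 15))
  hits2 <- hits3 <- 0
  N <- 500
  for (s in 1:N) {
    cu <- generate_deswelling_series(
      m, phi, noise_model("relative_gaussian", 0.05, seed = s))
    mix <- decompose_swelling_pressure(cu, list(C = m$C, phi_ref = m$phi_ref),
                                       m$ions, sv)
    vf <- fit_virial_coefficients(mix, sv)
    tq <- stats::qt(0.975, vf$df)
    if (abs(vf$A2 - m$A2) <= tq * vf$A2_se) hits2 <- hits2 + 1
    if (abs(vf$A3 - m$A3) <= tq * vf$A3_se) hits3 <- hits3 + 1
  }
  expect_gte(hits2 / N, 0.90); expect_lte(hits2 / N, 0.99)
  expect_gte(hits3 / N, 0.90); expect_lte(hits3 / N, 0.99)
})

test_that("swelling pressure assembles its three contributions", {
  m <- gel_model(0.1, 0.5, C = 0, solvent = sv)
  phi <- c(0.02, 0.05, 0.15)
  expect_equal(swelling_pressure(phi, m),
               mixing_pressure_virial(phi, 0.1, 0.5, sv), tolerance = 1e-14)
  # monotone decreasing in the elastic prefactor at fixed phi
  p <- vapply(c(0, 1e3, 1e4, 5e4), function(C)
    swelling_pressure(0.05, gel_model(0.1, 0.5, C = C, solvent = sv)),
    numeric(1))
  expect_true(all(diff(p) < 0))
})

test_that("equilibrium roots match the dense brute-force oracle", {
  set.seed(1234)
  for (i in 1:12) {
    m <- gel_model(A2 = runif(1, -0.1, 0.3), A3 = runif(1, -1.5, 0.8),
                   C = 10^runif(1, 3, 4.7), phi_ref = 0.05, solvent = sv)
    eq <- solve_equilibrium_swelling(m)
    bf <- brute_force_equilibria(m, n = 2e5)
    expect_equal(nrow(eq), length(bf$phi))
    if (nrow(eq) > 0) {
      expect_true(all(abs(log(eq$phi) - log(bf$phi)) <= bf$spacing_rel))
      # swelling pressure vanishes at every root
      expect_true(all(abs(swelling_pressure(eq$phi, m)) <= 1e-9 * scl))
    }
  }
})

test_that("equilibrium solver classifies stability and degenerate cases", {
  # A2, A3 > 0 with elastic term: exactly one root, stable
  m <- gel_model(0.1, 0.4, C = 2e4, phi_ref = 0.05, solvent = sv)
  eq <- solve_equilibrium_swelling(m)
  expect_equal(sum(eq$stable), 1L)
  # C = 0 with repulsive virials: no root, status flag, no error
  m0 <- gel_model(0.1, 0.4, C = 0, solvent = sv)
  eq0 <- solve_equilibrium_swelling(m0)
  expect_equal(nrow(eq0), 0L)
  expect_identical(attr(eq0, "status"), "no-equilibrium")
})

test_that("longitudinal modulus matches the analytic and numerical derivative", {
  phi <- c(0.02, 0.05, 0.1)
  A2 <- 0.08; A3 <- -0.2; Gs <- 1.5e4
  m <- longitudinal_modulus(phi, A2, A3, Gs, sv)
  expect_equal(m, scl * (2 * A2 * phi^2 + 3 * A3 * phi^3) + 4 / 3 * Gs,
               tolerance = 1e-14)
  # phi -> 0: modulus -> (4/3) G_s
  expect_equal(longitudinal_modulus(1e-8, A2, A3, Gs, sv), 4 / 3 * Gs,
               tolerance = 1e-9)
  # central finite difference of the mixing pressure
  h <- phi * 1e-6
  dmix <- (mixing_pressure_virial(phi + h, A2, A3, sv) -
             mixing_pressure_virial(phi - h, A2, A3, sv)) / (2 * h)
  expect_equal(m - 4 / 3 * Gs, phi * dmix, tolerance = 1e-6)
  # elastic-derivative convention subtracts G_s/3
  m_alt <- longitudinal_modulus(phi, A2, A3, Gs, sv,
                                include_elastic_derivative = TRUE)
  expect_equal(m - m_alt, rep(Gs / 3, 3), tolerance = 1e-10)
})

test_that("M_os with the elastic derivative is positive at stable equilibria", {
  set.seed(99)
  checked <- 0
  for (i in 1:20) {
    m <- gel_model(A2 = runif(1, -0.05, 0.3), A3 = runif(1, -1, 0.8),
                   C = 10^runif(1, 3.3, 4.7), phi_ref = 0.05, solvent = sv)
    eq <- solve_equilibrium_swelling(m)
    st <- eq$phi[eq$stable]
    for (p in st) {
      Gs <- shear_modulus_scaling(p, m$C, m$phi_ref)
      mos <- longitudinal_modulus(p, m$A2, m$A3, Gs, sv,
                                  include_elastic_derivative = TRUE)
      expect_gt(mos, 0)
      checked <- checked + 1
    }
  }
  expect_gt(checked, 5)
})

test_that("M_os falls toward zero as the polyelectrolyte transition is approached", {
  cfg <- scenario_config("polyelectrolyte_salt_sweep", noise_rel = 0)
  mos <- c()
  for (ctrl in cfg$control_grid) {
    m <- scenario_model(cfg, ctrl)
    eq <- solve_equilibrium_swelling(m)
    st <- eq$phi[eq$stable]
    if (length(st) == 0) break
    p <- min(st)
    Gs <- shear_modulus_scaling(p, m$C, m$phi_ref)
    mos <- c(mos, longitudinal_modulus(p, m$A2, m$A3, Gs, m$solvent))
  }
  expect_gte(length(mos), 4)
  expect_true(all(diff(mos) < 0))
  expect_lt(mos[length(mos)] / mos[1], 0.8)
})

test_that("volume transition is detected for the polyelectrolyte scenario only", {
  cfg <- scenario_config("polyelectrolyte_salt_sweep", noise_rel = 0)
  tr <- detect_volume_transition(function(c) scenario_model(cfg, c),
                                 cfg$control_grid)
  expect_true(tr$transition)
  expect_gte(tr$jump_ratio, 2)
  expect_gt(tr$c_critical, min(cfg$control_grid))
  expect_lt(tr$c_critical, max(cfg$control_grid))
  # bracketing against a brute-force continuation on a 10x finer control grid
  fine <- seq(min(cfg$control_grid), max(cfg$control_grid), length.out = 71)
  alive <- vapply(fine, function(ctrl) {
    bf <- brute_force_equilibria(scenario_model(cfg, ctrl), n = 2e4)
    length(bf$phi) > 0 && min(bf$phi) < 0.12
  }, logical(1))
  c_lo <- max(fine[alive])
  c_hi <- min(fine[!alive])
  expect_gte(tr$c_critical, c_lo - 0.05)
  expect_lte(tr$c_critical, c_hi + 0.05)

  cfgn <- scenario_config("neutral_temperature_sweep", noise_rel = 0)
  trn <- detect_volume_transition(function(c) scenario_model(cfgn, c),
                                  cfgn$control_grid)
  expect_false(trn$transition)
  expect_true(all(is.finite(trn$phi_eq)))

  cfgb <- scenario_config("bottlebrush_salt_sweep", noise_rel = 0)
  trb <- detect_volume_transition(function(c) scenario_model(cfgb, c),
                                  cfgb$control_grid)
  expect_false(trb$transition)
})
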