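test_that("probe calibration recovers bilinear coefficients from 3 standards", {
  A <- 2 + 0.3i; B <- 0.1 + 0.05i; C <- 1 - 0.2i
  eps <- c(78.4 + 0i, 46.7 - 2i, 19.9 - 1i)   # water / DMSO / alcohol-like
  rho <- (eps - C) / (A - B * eps)
  cal <- calibrate_probe(eps, rho)
  expect_lt(Mod(cal$A - A), 1e-10)
  expect_lt(Mod(cal$B - B), 1e-10)
  expect_lt(Mod(cal$C - C), 1e-10)
  expect_lt(max(Mod(cal$apply(rho) - eps)), 1e-10)
  # linear probe (B = 0) degenerates gracefully
  rho0 <- (eps - C) / A
  cal0 <- calibrate_probe(eps, rho0)
  expect_lt(Mod(cal0$B), 1e-10)
  # duplicated standards are singular
  expect_error(calibrate_probe(eps[c(1, 1, 3)], rho[c(1, 1, 3)]), "singular|degenerate")
})

test_that("conductivity removal is exact and invertible", {
  spec <- gen_dielectric_spectrum(synthetic_spectrum_spec(conductivity = 0))
  expect_equal(remove_conductivity(spec)$eps_imag, spec$eps_imag)
  withsig <- add_conductivity(spec, 3.2)
  back <- remove_conductivity(withsig)
  expect_equal(back$eps_imag, spec$eps_imag, tolerance = 1e-12)
  expect_equal(back$eps_real, spec$eps_real)
  # a purely Ohmic loss vanishes after correction
  freq <- 10^seq(-2, 2, length.out = 50)
  ohmic <- dielectric_spectrum(freq, rep(5, 50),
                               2.5 / (2 * pi * freq * 1e9 * 8.8541878128e-12),
                               conductivity = 2.5)
  expect_lt(max(abs(remove_conductivity(ohmic)$eps_imag)), 1e-9)
  expect_error(remove_conductivity(spec, conductivity = -1), "non-negative")
})

test_that("double-Debye fitting is exact on noise-free spectra (20 random sets)", {
  set.seed(61)
  for (i in 1:20) {
    S1 <- runif(1, 20, 90); S2 <- runif(1, 0.5, 6)
    tau1 <- runif(1, 5, 15); tau2 <- runif(1, 0.1, 0.6)
    sp <- gen_dielectric_spectrum(synthetic_spectrum_spec(S1, S2, tau1, tau2))
    fit <- fit_double_debye(sp)
    expect_equal(fit$S1, S1, tolerance = 1e-6)
    expect_equal(fit$S2, S2, tolerance = 1e-6)
    expect_equal(fit$tau1, tau1, tolerance = 1e-6)
    expect_equal(fit$tau2, tau2, tolerance = 1e-6)
    expect_gt(fit$tau1, fit$tau2)
  }
})

test_that("the fitted model's static limit is S1 + S2 + eps_inf", {
  sp <- gen_dielectric_spectrum(synthetic_spectrum_spec())
  fit <- fit_double_debye(sp)
  static <- Re(double_debye_eps(1e-6, fit$S1, fit$S2, fit$tau1, fit$tau2, fit$eps_inf))
  expect_equal(static, fit$S1 + fit$S2 + fit$eps_inf, tolerance = 1e-9)
  expect_equal(glance(fit)$static_eps, fit$S1 + fit$S2 + fit$eps_inf)
})

test_that("1% multiplicative noise keeps fitted parameters within 5%", {
  sp <- gen_dielectric_spectrum(synthetic_spectrum_spec(noise = 0.01, seed = 62))
  fit <- fit_double_debye(sp)
  expect_equal(fit$S1, 72, tolerance = 0.05)
  expect_equal(fit$tau1, 8.3, tolerance = 0.05)
})

test_that("depolarization splits and trivial limits behave", {
  ref <- fit_double_debye(gen_dielectric_spectrum(synthetic_spectrum_spec()))
  # sigma = 0 and identical strengths -> all deltas 0
  same <- ref; same$conductivity <- 0; same$concentration <- 1
  dep0 <- static_depolarization(same, ref, sigma_c = 0)
  expect_equal(dep0$dS_total, 0, tolerance = 1e-9)
  expect_equal(dep0$dS_kinetic, 0)
  expect_equal(dep0$dS_static, 0, tolerance = 1e-9)
  # sigma = 0 -> static equals total
  less <- ref; less$S1 <- ref$S1 - 10; less$conductivity <- 0
  dep1 <- static_depolarization(less, ref, sigma_c = 0)
  expect_equal(dep1$dS_static, dep1$dS_total)
  expect_equal(dep1$dS_total, -10, tolerance = 1e-9)
  expect_error(static_depolarization(less, NULL), "reference")
  # dS_static = dS_total - dS_kinetic always
  less$conductivity <- 4
  dep2 <- static_depolarization(less, ref)
  expect_equal(dep2$dS_static, dep2$dS_total - dep2$dS_kinetic)
})

test_that("hydration-number algebra: zero excess depolarization gives N_hyd = 0", {
  ref <- fit_double_debye(gen_dielectric_spectrum(synthetic_spectrum_spec()))
  s0 <- ref$S1 + ref$S2
  ch2o_0 <- 55.35; ch2o_c <- 53.1; c <- 1
  # construct dS_static that exactly offsets dilution
  dep <- structure(list(dS_static = s0 * (ch2o_c / ch2o_0 - 1),
                        S_0 = s0, concentration = c,
                        water_concentration_c = ch2o_c,
                        water_concentration_0 = ch2o_0),
                   class = "depolarization_result")
  expect_equal(drs_hydration_number(dep), 0, tolerance = 1e-12)
  # symbolic identity: dS_static making the bracket vanish gives cH2O(c)/c
  dep2 <- dep; dep2$dS_static <- -s0
  expect_equal(drs_hydration_number(dep2), ch2o_c / c)
})

test_that("the full synthetic concentration series recovers the designed N_hyd", {
  series <- gen_concentration_series(c(0.5, 1, 2), N_hyd_design = 12, seed = 63)
  out <- run_drs_pipeline(series$reference, series$solutions)
  expect_equal(out$N_hyd, rep(12, 3), tolerance = 0.02)
  # with measurement noise, still within 5%
  series2 <- gen_concentration_series(1, N_hyd_design = 12, noise = 0.01, seed = 64)
  out2 <- run_drs_pipeline(series2$reference, series2$solutions)
  expect_equal(out2$N_hyd, 12, tolerance = 0.05)
})

test_that("N_hyd is invariant to resampling the frequency grid", {
  coarse <- synthetic_spectrum_spec(freq = 10^seq(log10(0.01), log10(110), length.out = 80))
  series <- gen_concentration_series(1, N_hyd_design = 10, reference = coarse, seed = 65)
  out <- run_drs_pipeline(series$reference, series$solutions)
  expect_equal(out$N_hyd, 10, tolerance = 0.02)
})

test_that("spectrum CSV round trip preserves data and metadata", {
  sp <- gen_dielectric_spectrum(synthetic_spectrum_spec(conductivity = 2, concentration = 1.5,
                                                        water_concentration = 52))
  path <- withr::local_tempfile(fileext = ".csv")
  write_dielectric_spectrum(sp, path)
  back <- read_dielectric_spectrum(path)
  expect_equal(back$eps_real, sp$eps_real)
  expect_equal(attr(back, "conductivity"), 2)
  expect_equal(attr(back, "concentration"), 1.5)
  # missing column is named in the error
  readr::write_csv(tibble::tibble(freq_GHz = 1:3, eps_real = 1:3), path)
  expect_error(read_dielectric_spectrum(path), "eps_imag")
})
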