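test_that("simulated curves honour textbook limiting behaviour", {
  # 1 mM strong acid before any titrant: pH = 3 (autoprotolysis negligible)
  sa <- simulate_titration(simulation_spec("strong_acid", c0 = 1e-3,
                                           titrant_conc = 1e-3))
  expect_equal(sa$ph[1L], 3, tolerance = 1e-3)
  # weak base mid-titration sits at its pKa (Henderson-Hasselbalch)
  wb <- simulate_titration(simulation_spec("weak_base", c0 = 1e-3,
                                           titrant_conc = 1e-3,
                                           pka_true = 8.79))
  ph_half <- approx(wb$volume_ml, wb$ph, xout = 10)$y
  expect_equal(ph_half, 8.79, tolerance = 0.02)
})

test_that("noise-free curves are monotone in the expected direction", {
  acidi <- simulate_titration(simulation_spec("weak_base", c0 = 1e-3,
                                              titrant_conc = 1e-3,
                                              pka_true = 8.5))
  expect_identical(acidi$direction, "acidimetric")
  expect_true(all(diff(acidi$ph) < 0))
  alkali <- simulate_titration(simulation_spec("weak_acid", c0 = 1e-3,
                                               titrant_conc = 1e-3,
                                               pka_true = 4.2))
  expect_identical(alkali$direction, "alkalimetric")
  expect_true(all(diff(alkali$ph) > 0))
})

test_that("the charge-balance root satisfies mass action to solver tolerance", {
  spec <- simulation_spec("weak_base", c0 = 1e-3, titrant_conc = 1e-3,
                          pka_true = 8.79, delta_true = -2.05)
  crv <- simulate_titration(spec)
  ka <- 10^(-spec$pka_true)
  V <- crv$volume_ml
  cb <- spec$c0 * spec$v0 / (spec$v0 + V)
  ccl <- spec$titrant_conc * V / (spec$v0 + V)
  h <- 10^(-(crv$ph - spec$delta_true))
  residual <- h + cb * h / (h + ka) - ccl - 1e-14 / h
  expect_true(all(abs(residual) < 1e-10))
})

test_that("simulation is deterministic under a fixed seed", {
  spec <- simulation_spec("weak_base", c0 = 1e-3, titrant_conc = 1e-3,
                          pka_true = 8.5, noise_sd = 0.01, seed = 123)
  a <- simulate_titration(spec)
  b <- simulate_titration(spec)
  expect_identical(a$ph, b$ph)
  spec2 <- simulation_spec("weak_base", c0 = 1e-3, titrant_conc = 1e-3,
                           pka_true = 8.5, noise_sd = 0.01, seed = 124)
  expect_false(identical(simulate_titration(spec2)$ph, a$ph))
})

test_that("non-physical specs are rejected", {
  expect_error(simulation_spec("weak_base", c0 = -1, titrant_conc = 1e-3,
                               pka_true = 8), "positive")
  expect_error(simulation_spec("weak_base", c0 = 1e-3, titrant_conc = 1e-3),
               "pka_true")
  expect_error(simulation_spec("strong_acid", c0 = 1e-3, titrant_conc = 1e-3,
                               noise_sd = -0.1), ">= 0")
})

test_that("e-liquid fixtures invert the speciation model exactly", {
  fx <- generate_eliquid_fixtures(25, seed = 7)
  res <- fraction_fb_from_measurements(fx$ph_app, fx$dielectric,
                                       extrapolation_policy = "silent")
  expect_equal(res$fraction_fb, fx$fb_true, tolerance = 1e-10)
  expect_true(all(fx$nicotine_conc %in% c(12, 28, 58, 60)))
  expect_identical(generate_eliquid_fixtures(25, seed = 7), fx)
  expect_false(identical(generate_eliquid_fixtures(25, seed = 8)$ph_app,
                         fx$ph_app))
})

test_that("a fixture built at a reference composition reads the reference pH", {
  # freebase fraction 0.143 at D 34.67 corresponds to an apparent pH of 6.06
  cal <- default_calibration()
  pka <- pka_at(cal$pka_base_model, 34.67)
  delta <- delta_at(cal$delta_model, 34.67)
  ph_app <- (pka - log10(1 / 0.143 - 1)) + delta
  expect_equal(ph_app, 6.06, tolerance = 0.005)
})
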