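# All ground-truth curves come from the charge-balance simulator; millimolar
# delta titrations mirror the bench protocol, while pKa recoveries run at
# 10 mM (weak bases) and 50 mM (benzoic acid) where the half-equivalence
# approximation error is well below the sampling resolution.

test_that("derivative method finds the centre of an exact sigmoid", {
  v <- seq(0, 20, by = 0.25)
  crv <- titration_curve(v, 7 + 3 * tanh(1.5 * (v - 10)))
  expect_equal(equivalence_volume(crv), 10, tolerance = 1e-6)
})

test_that("equivalence volume matches stoichiometry on simulated curves", {
  # strong acid titrated by strong base
  sa <- simulate_titration(simulation_spec("strong_acid", c0 = 1e-3,
                                           titrant_conc = 1e-3))
  expect_equal(equivalence_volume(sa), 20, tolerance = 0.1)
  # nicotine-like weak base titrated by strong acid
  wb <- simulate_titration(simulation_spec("weak_base", c0 = 1e-3,
                                           titrant_conc = 1e-3,
                                           pka_true = 8.79))
  expect_equal(equivalence_volume(wb), 20, tolerance = 0.1)
})

test_that("a featureless curve raises a no-endpoint error", {
  v <- seq(0, 20, by = 1)
  flat <- titration_curve(v, 7 + 0.01 * v)
  expect_error(equivalence_volume(flat), "no equivalence point")
})

test_that("standardization applies 1:1 stoichiometry", {
  v <- seq(0, 20, by = 0.25)
  crv <- titration_curve(v, 7 + 3 * tanh(1.5 * (v - 10)), titrant_conc = 1e-3)
  expect_equal(standardize(crv, v_eq = 20), 1e-3)
  expect_equal(standardize(crv, v_eq = 10), 5e-4)
  # recovery of an unknown analyte concentration at zero noise
  sim <- simulate_titration(simulation_spec("strong_acid", c0 = 8e-4,
                                            titrant_conc = 1e-3))
  expect_equal(standardize(sim, 1e-3), 8e-4, tolerance = 0.02 * 8e-4)
})

test_that("half-equivalence pKa recovers simulator ground truth", {
  # nicotine in pure PG: true pKa 8.79 on the real scale, delta -2.05
  nic <- simulate_titration(simulation_spec("weak_base", c0 = 0.01,
                                            titrant_conc = 0.01,
                                            pka_true = 8.79,
                                            delta_true = -2.05))
  res <- half_equivalence_pka(nic, equivalence_volume(nic), delta = -2.05)
  expect_equal(res$pka, 8.79, tolerance = 0.05)
  expect_equal(res$pka_app - res$pka, -2.05)
  # benzoic acid in water: pKa 4.20, no offset
  bz <- simulate_titration(simulation_spec("weak_acid", c0 = 0.05,
                                           titrant_conc = 0.05,
                                           pka_true = 4.20))
  expect_equal(half_equivalence_pka(bz, equivalence_volume(bz), 0)$pka,
               4.20, tolerance = 0.05)
  # delta = 0: apparent and corrected scales coincide
  v <- seq(0, 20, by = 0.5)
  crv <- titration_curve(v, 3 + 4 / (1 + exp(-(v - 10))))
  h <- half_equivalence_pka(crv, v_eq = 10, delta = 0)
  expect_equal(h$pka, h$pka_app)
  expect_error(half_equivalence_pka(crv, v_eq = 50), "outside the sampled range")
})

test_that("pKa recovery holds across a pKa x delta x noise grid", {
  for (pka in c(7.5, 8.5, 9.5)) {
    for (d in c(0, -1.6, -2.1)) {
      for (sd in c(0, 0.01)) {
        crv <- simulate_titration(simulation_spec(
          "weak_base", c0 = 0.01, titrant_conc = 0.01, pka_true = pka,
          delta_true = d, volume_step = 0.1, noise_sd = sd, seed = 404
        ))
        got <- half_equivalence_pka(crv, equivalence_volume(crv), d)$pka
        expect_equal(got, pka, tolerance = if (sd == 0) 0.05 else 0.15,
                     label = sprintf("pKa %.1f, delta %.1f, sd %.2f -> %.3f",
                                     pka, d, sd, got))
      }
    }
  }
})

test_that("delta determination returns the injected solvent offset", {
  for (d in c(0, -2.05, -1.59)) {
    crv <- simulate_titration(simulation_spec("strong_acid", c0 = 1e-3,
                                              titrant_conc = 1e-3,
                                              delta_true = d))
    expect_equal(determine_delta(crv, 1e-3, 1e-3), d, tolerance = 0.02)
  }
  # independent of the analyte concentration
  crv <- simulate_titration(simulation_spec("strong_acid", c0 = 5e-4,
                                            titrant_conc = 1e-3,
                                            delta_true = -1.78))
  expect_equal(determine_delta(crv, 5e-4, 1e-3), -1.78, tolerance = 1e-6)
  # a curve sampled only past the equivalence point has no usable points
  late <- titration_curve(seq(15, 20, by = 1), seq(10, 11, by = 0.2))
  expect_error(determine_delta(late, 5e-4, 1e-3), "no usable pre-equivalence")
})

test_that("analysis is invariant under a volume-unit rescale", {
  crv <- simulate_titration(simulation_spec("weak_base", c0 = 0.01,
                                            titrant_conc = 0.01,
                                            pka_true = 8.5))
  scaled <- titration_curve(crv$volume_ml / 1000, crv$ph,
                            analyte_volume_ml = crv$analyte_volume_ml / 1000,
                            titrant_conc = crv$titrant_conc,
                            direction = crv$direction)
  v1 <- equivalence_volume(crv); v2 <- equivalence_volume(scaled)
  expect_equal(v2 * 1000, v1, tolerance = 1e-6)
  expect_equal(standardize(scaled, 0.01, v2), standardize(crv, 0.01, v1),
               tolerance = 1e-9)
  expect_equal(half_equivalence_pka(scaled, v2, 0)$pka,
               half_equivalence_pka(crv, v1, 0)$pka, tolerance = 1e-9)
})

test_that("curve validation rejects malformed series", {
  expect_error(titration_curve(1:4, 1:4), "at least 5")
  expect_error(titration_curve(c(1, 2, 2, 3, 4), rep(7, 5)),
               "strictly increasing")
  expect_error(titration_curve(1:5, c(7, NA, 7, 7, 7)), "finite")
})
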