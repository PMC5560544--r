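test_that("temperature correction matches the linear-in-log forms and is the identity at 37", {
  expect_equal(correct_for_temperature(7.20, 50, 37),
               tibble::tibble(ph = 7.20, pco2 = 50))
  tc <- correct_for_temperature(7.40, 40, 38.5)
  expect_equal(tc$ph, 7.40 - 0.0146 * 1.5, tolerance = 1e-12)
  expect_equal(tc$pco2, 40 * 10^(0.019 * 1.5), tolerance = 1e-12)
  expect_equal(round(tc$ph, 3), 7.378)
  expect_equal(round(tc$pco2, 1), 42.7)
  tc2 <- correct_for_temperature(7.00, 60, 35, po2 = 40)
  expect_equal(tc2$ph, 7.00 - 0.0146 * (-2), tolerance = 1e-12)
  expect_equal(round(tc2$ph, 3), 7.029)
  expect_equal(tc2$pco2, 60 * 10^(0.019 * -2), tolerance = 1e-12)
  expect_equal(tc2$po2, 40 * 10^(0.0052 * -2), tolerance = 1e-12)
  expect_error(correct_for_temperature(7.4, 40, 24),
               class = "calfsid_validation_error")
  expect_error(correct_for_temperature(8.5, 40, 38),
               class = "calfsid_validation_error")
})

test_that("temperature correction round-trips analytically", {
  p <- random_panels(200)
  temps <- runif(200, 30, 42)
  fwd <- correct_for_temperature(p$ph, p$pco2, temps)
  back_ph <- fwd$ph - (-0.0146) * (temps - 37)
  back_pco2 <- fwd$pco2 / 10^(0.019 * (temps - 37))
  expect_equal(back_ph, p$ph, tolerance = 1e-9)
  expect_equal(back_pco2, p$pco2, tolerance = 1e-9)
})

test_that("bicarbonate follows Henderson-Hasselbalch with the calf constants", {
  expect_equal(bicarbonate(6.105, 100), 3.07, tolerance = 1e-12)
  expect_equal(round(bicarbonate(7.40, 40), 1), 24.2)
  expect_equal(round(bicarbonate(7.00, 47.4), 1), 11.4)
  # strictly increasing in pH at fixed pCO2; linear in pCO2 at fixed pH
  phs <- seq(6.6, 7.7, by = 0.05)
  expect_true(all(diff(bicarbonate(phs, 40)) > 0))
  expect_equal(bicarbonate(7.2, 80), 2 * bicarbonate(7.2, 40),
               tolerance = 1e-12)
})

test_that("van Slyke base excess vanishes at the reference point for any hemoglobin", {
  for (hb in seq(0, 25, by = 2.5)) {
    expect_equal(base_excess(7.4, 24.8, hb), 0, tolerance = 1e-12)
  }
  expect_equal(round(base_excess(7.0, 10, 12), 1), -20.6)
  expect_error(base_excess(7.2, 15, -1), class = "calfsid_validation_error")
})

test_that("anion gap and SIDm are the stated ionic sums", {
  expect_equal(anion_gap(140, 4, 100, 24), 20)
  expect_equal(round(anion_gap(134.7, 4.8, 101, 16.7), 1), 21.8)
  expect_equal(anion_gap(0, 0, 0, 0), 0)
  expect_equal(sid_measured(140, 4, 100, 4, 2), 38)
  expect_equal(round(sid_measured(134.7, 4.8, 101, 3.9, 1.6), 1), 33.0)
  expect_equal(sid_measured(0, 0, 0, 0, 0), 0)
})

test_that("Atot and A- reproduce the printed survivor/non-survivor values", {
  expect_equal(round(atot(57.7), 1), 19.8)
  expect_equal(round(atot(53.0), 1), 18.2)
  expect_equal(atot(0), 0)
  # half dissociation at pH = pKa, full protonation limit
  expect_equal(a_minus(19.8, 7.08), 9.9, tolerance = 1e-12)
  expect_equal(round(a_minus(19.8, 7.40), 2), 13.39)
  expect_lt(a_minus(19.8, 2.0), 1e-3)
})

test_that("SIG and USI compose as specified", {
  expect_equal(round(strong_ion_gap(19.8, 7.40, 20), 2), -6.61)
  expect_equal(strong_ion_gap(0, 7.1, 0), 0)
  expect_equal(strong_ion_gap(19.8, 7.08, 9.9), 0, tolerance = 1e-12)
  expect_equal(unidentified_strong_ions(-6.61, 4, 2), -0.61)
  expect_equal(unidentified_strong_ions(0, 0, 0), 0)
  expect_equal(round(unidentified_strong_ions(-15.0, 4.6, 2.1), 1), -8.3)
})

test_that("derive_acid_base populates all fields and enforces its identities", {
  out <- derive_acid_base(survivor_median_calf())
  expect_true(all(c("hco3", "base_excess", "anion_gap", "atot", "a_minus",
                    "sid_m", "sig", "usi") %in% names(out)))
  expect_equal(round(out$atot, 1), 19.8)
  expect_equal(out$usi, out$sig + 3.9 + 1.6, tolerance = 1e-12)
  # the survivor-median calf has a near-zero strong ion gap magnitude
  expect_equal(out$usi + out$sid_m, out$a_minus + out$hco3,
               tolerance = 1e-9)
})

test_that("derive_acid_base names missing analytes and flags implausible electrolytes", {
  calf <- survivor_median_calf()
  expect_error(derive_acid_base(dplyr::select(calf, -hb)),
               regexp = "hb", class = "calfsid_missing_columns")
  calf_bad <- dplyr::mutate(calf, na = 90, cl = 95)
  expect_warning(derive_acid_base(calf_bad), regexp = "na <= cl")
  expect_error(derive_acid_base(dplyr::mutate(calf, ph = 5.9)),
               class = "calfsid_validation_error")
})

test_that("acid-base identities hold to 1e-9 over random valid panels", {
  p <- derive_acid_base(random_panels(10000))
  scale <- pmax(abs(p$usi), 1)
  expect_lt(max(abs(p$usi - p$sig - p$d_lactate - p$l_lactate) / scale),
            1e-9)
  expect_lt(max(abs(p$usi + p$sid_m - p$a_minus - p$hco3) / scale), 1e-9)
  expect_true(all(p$a_minus > 0 & p$a_minus < p$atot))
  expect_equal(a_minus(p$atot, 7.08), p$atot / 2, tolerance = 1e-12)
})

test_that("temperature-corrected columns append without entering derivations", {
  calf <- survivor_median_calf()
  out <- derive_acid_base(calf, temp_correct = TRUE)
  expect_equal(out$hco3, bicarbonate(calf$ph, calf$pco2))
  expect_equal(out$ph_temp, calf$ph - 0.0146 * (38.8 - 37))
})
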