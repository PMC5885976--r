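test_that("a background-only spectrum is fitted exactly", {
  spec <- synthetic_spectrum_spec(
    resonances = data.frame(amplitude = numeric(0), center = numeric(0),
                            halfwidth = numeric(0)),
    nonresonant_amplitude = 2.5)
  f <- fit_spectrum(synth_spectrum(spec, "ssp"), n_peaks = 0)
  expect_true(f$converged)
  expect_equal(f$nonresonant$amplitude, 2.5, tolerance = 1e-8)
  expect_lt(f$residual, 1e-10)
})

test_that("a noise-free single resonance is recovered at its center", {
  f <- fit_spectrum(synth_spectrum(amide_i_spectrum_spec(), "ssp"),
                    n_peaks = 1)
  expect_true(f$converged)
  expect_equal(f$resonances$center, 1650, tolerance = 1e-3)
  expect_equal(f$resonances$amplitude, 5, tolerance = 1e-5)
  expect_equal(f$resonances$halfwidth, 8, tolerance = 1e-5)
})

test_that("two-resonance line shapes are recovered from perturbed inits", {
  truth <- data.frame(amplitude = c(6, -3.5), center = c(1642, 1672),
                      halfwidth = c(9, 12))
  spec <- synthetic_spectrum_spec(resonances = truth,
                                  nonresonant_amplitude = 0.8)
  s <- synth_spectrum(spec, "ppp")
  init <- truth
  init$center <- init$center + c(5, -5)
  f <- fit_spectrum(s, n_peaks = 2, init = init)
  expect_true(f$converged)
  expect_equal(f$resonances$center, truth$center, tolerance = 0.01)
  for (col in c("amplitude", "center", "halfwidth")) {
    expect_lt(max(abs(f$resonances[[col]] - truth[[col]]) /
                    abs(truth[[col]])), 0.01)
  }
  expect_equal(f$nonresonant$amplitude, 0.8, tolerance = 0.01)
})

test_that("the fit is scale-equivariant", {
  s <- synth_spectrum(amide_i_spectrum_spec(), "ssp")
  k <- 7.3
  s_scaled <- sfg_spectrum(s$wavenumber, s$intensity * k, "ssp")
  f1 <- fit_spectrum(s, 1)
  f2 <- fit_spectrum(s_scaled, 1)
  expect_equal(f2$resonances$amplitude,
               f1$resonances$amplitude * sqrt(k), tolerance = 1e-6)
  expect_equal(f2$resonances$center, f1$resonances$center,
               tolerance = 1e-6)
  expect_equal(f2$resonances$halfwidth, f1$resonances$halfwidth,
               tolerance = 1e-6)
})

test_that("noise-free residuals are negligible against signal power", {
  for (tilt in c(10, 45)) {
    sp <- forward_spectra(tilt)
    for (pol in c("ssp", "ppp")) {
      f <- fit_spectrum(sp[[pol]], 1)
      expect_lt(f$residual, 1e-8 * sum(sp[[pol]]$intensity^2))
    }
  }
})

test_that("a nonresonant background makes amplitude signs identifiable", {
  truth <- data.frame(amplitude = -3, center = 1650, halfwidth = 8)
  spec <- synthetic_spectrum_spec(resonances = truth,
                                  nonresonant_amplitude = 1)
  f <- fit_spectrum(synth_spectrum(spec, "ssp"), n_peaks = 1,
                    init = data.frame(amplitude = -2, center = 1648,
                                      halfwidth = 9))
  expect_equal(f$resonances$amplitude, -3, tolerance = 1e-4)
})

test_that("amplitude ratios carry sign and refuse a vanishing denominator", {
  expect_equal(amplitude_ratio(fake_fit(2), fake_fit(1))$value, 2.0)
  expect_equal(amplitude_ratio(fake_fit(-3), fake_fit(1.5))$value, -2.0)
  expect_error(amplitude_ratio(fake_fit(2), fake_fit(1e-17)),
               "no ssp amplitude")
  expect_error(amplitude_ratio(fake_fit(2), fake_fit(1, converged = FALSE)),
               "converged")
  expect_error(amplitude_ratio(fake_fit(2, center = 1700), fake_fit(1)),
               "within 10 cm-1")
})

test_that("amplitude ratio is invariant under a global sign flip", {
  r1 <- amplitude_ratio(fake_fit(2.4), fake_fit(-1.2))
  r2 <- amplitude_ratio(fake_fit(-2.4), fake_fit(1.2))
  expect_equal(r1$value, r2$value)
})

test_that("fitted model methods are mutually consistent", {
  s <- synth_spectrum(amide_i_spectrum_spec(noise_sd = 0.05, seed = 5),
                      "ssp")
  f <- fit_spectrum(s, 1)
  expect_equal(unname(coef(f)[["omega1"]]), f$resonances$center)
  expect_equal(residuals(f), f$intensity - fitted(f))
  expect_equal(sum(residuals(f)^2), f$residual, tolerance = 1e-10)
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_json(f, path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(j$resonances$center, f$resonances$center)
})
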