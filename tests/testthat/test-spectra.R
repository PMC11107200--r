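test_that("area normalisation has unit integral, reverses scaling, is idempotent", {
  s <- make_spectrum(list(c(400, 1, 20), c(550, 0.5, 25)))
  n1 <- area_normalize(s)
  expect_equal(pracma::trapz(n1$wavelength, abs(n1$absorbance)), 1,
               tolerance = 1e-9)
  s5 <- spectrum(s$wavelength, 5 * s$absorbance)
  expect_equal(area_normalize(s5)$absorbance, n1$absorbance,
               tolerance = 1e-12)
  expect_equal(area_normalize(n1)$absorbance, n1$absorbance,
               tolerance = 1e-9)
  # rectangular pulse of height 2 over 10 nm integrates to 20
  w <- c(300, 349.999, 350, 360, 360.001, 400)
  pulse <- spectrum(w, c(0, 0, 2, 2, 0, 0))
  expect_equal(max(area_normalize(pulse)$absorbance), 2 / 20,
               tolerance = 1e-3)
  flat <- spectrum(w, rep(0, length(w)))
  expect_error(area_normalize(flat), "zero-area")
  expect_error(area_normalize(s, c(200, 500)), "support")
})

test_that("band metrics locate peaks within the grid step", {
  s <- make_spectrum(list(c(356, 0.3, 10), c(530, 0.8, 15)))
  m <- band_metrics(s, gamma_window = c(340, 370),
                    alphabeta_window = c(490, 580))
  expect_equal(m$alphabeta$position, 530, tolerance = 1)
  expect_equal(m$gamma$position, 356, tolerance = 1)
  expect_warning(band_metrics(make_spectrum(list(c(530, 1, 10))),
                              gamma_window = c(340, 350),
                              alphabeta_window = c(490, 580)),
                 "flat")
})

test_that("a constructed red shift and gamma collapse are recovered", {
  ref <- make_spectrum(list(c(356, 1.0, 12), c(527, 0.45, 20)))
  shifted <- make_spectrum(list(c(356, 1.0, 12), c(539, 0.45, 20)))
  cmp <- compare_spectra(ref, shifted)
  expect_equal(cmp$red_shift_nm, 12, tolerance = 1)
  collapsed <- make_spectrum(list(c(356, 0.5, 12), c(527, 0.45, 20)))
  cmp2 <- compare_spectra(ref, collapsed)
  # heights compare on area-normalised spectra; renormalisation after
  # halving the gamma band inflates the ratio slightly above 1/2
  h_ref <- band_metrics(ref)$gamma$height
  h_col <- band_metrics(collapsed)$gamma$height
  expect_equal(cmp2$gamma_ratio, h_col / h_ref, tolerance = 1e-12)
  raw_ratio <- 0.5 *
    pracma::trapz(ref$wavelength, abs(ref$absorbance)) /
    pracma::trapz(collapsed$wavelength, abs(collapsed$absorbance))
  expect_equal(cmp2$gamma_ratio, raw_ratio, tolerance = 0.02)
})

test_that("comparisons are invariant to input scaling", {
  a <- make_spectrum(cobalamin_peaks("HOCbl"))
  b <- make_spectrum(cobalamin_peaks("GSCbl"))
  c1 <- compare_spectra(a, b)
  a2 <- spectrum(a$wavelength, 7 * a$absorbance)
  b2 <- spectrum(b$wavelength, 0.2 * b$absorbance)
  c2 <- compare_spectra(a2, b2)
  expect_equal(c1$red_shift_nm, c2$red_shift_nm)
  expect_equal(c1$gamma_ratio, c2$gamma_ratio, tolerance = 1e-9)
})

test_that("drift is zero for identical series and increases along a decay", {
  ref <- make_spectrum(cobalamin_peaks("GSCbl"))
  same <- stability_series(ref, times = 0:3,
                           series = replicate(4, ref, simplify = FALSE))
  expect_equal(same$drift$drift, rep(0, 4), tolerance = 1e-9)
  # monotone mixture from GSCbl-like towards HOCbl-like
  ho <- make_spectrum(cobalamin_peaks("HOCbl"))
  mix <- function(f) spectrum(ref$wavelength,
                              (1 - f) * ref$absorbance + f * ho$absorbance)
  decay <- stability_series(ref, times = 0:4,
                            series = lapply(c(0, 0.25, 0.5, 0.75, 1), mix))
  expect_true(all(diff(decay$drift$drift) > 0))
  expect_equal(decay$tau, 1)
  stable <- stability_series(ref, times = 0:4,
                             series = replicate(5, ref, simplify = FALSE))
  expect_lt(stable$tau, decay$tau)
  expect_error(stability_series(ref, 0, list(ref)), "at least 2")
})

test_that("spectrum CSV round-trips through read_spectrum", {
  s <- make_spectrum(cobalamin_peaks("HOCbl"))
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(wavelength_nm = s$wavelength,
                              absorbance = s$absorbance),
                   f, row.names = FALSE)
  s2 <- read_spectrum(f)
  expect_equal(s2$wavelength, s$wavelength)
  expect_equal(s2$absorbance, s$absorbance, tolerance = 1e-12)
})
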