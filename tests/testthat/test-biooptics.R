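cf <- model_coefficients()

test_that("coefficient tables cover the stated wavelengths", {
  expect_equal(cf$bp_table$wavelength_nm,
               c(412, 440, 488, 510, 532, 555, 650, 676, 715))
  expect_equal(cf$bbp_table$wavelength_nm,
               c(440, 488, 510, 532, 555, 650, 676, 700, 715))
  expect_true(all(cf$bp_table$A_b > 0) && all(cf$bp_table$B_b > 0))
  expect_true(all(cf$bbp_table$A_bb > 0) && all(cf$bbp_table$B_bb > 0))
})

test_that("phytoplankton absorption follows its power law", {
  expect_equal(aph(440, 0), 0)
  A440 <- cf$aph_table$A_ph[cf$aph_table$wavelength_nm == 440]
  B440 <- cf$aph_table$B_ph[cf$aph_table$wavelength_nm == 440]
  expect_equal(aph(440, 1), A440)
  expect_equal(aph(440, 2) / aph(440, 1), 2^(1 + B440))
  expect_error(aph(440, -1), "non-negative")
})

test_that("NAP absorption matches the printed anchor and slope", {
  expect_equal(anap(440, 1), 0.0124)
  expect_equal(anap(440, 0), 0)
  for (chl in c(0.2, 1, 7)) {
    expect_equal(anap(540, chl) / anap(440, chl), exp(-1.1))
  }
  expect_equal(anap(440, 2), 0.0124 * 2^0.724)
})

test_that("CDOM absorption: intercept, direct value, spectral slope", {
  expect_equal(acdom(440, 0, raw = TRUE), 0.464)
  expect_equal(acdom(440, 35), -0.012 * 35 + 0.464)
  # log-linear regression over 412-715 nm recovers the spectral slope
  wl <- seq(412, 715, by = 1)
  fit <- coef(lm(log(acdom(wl, 34)) ~ wl))
  expect_equal(unname(fit[2]), -0.0168, tolerance = 1e-10)
})

test_that("CDOM validity window: fallback and raw clamping", {
  expect_warning(lo <- acdom(440, 5), "0.04")
  expect_equal(lo, 0.04)
  expect_warning(hi <- acdom(440, 39.5), "0.04")
  expect_equal(hi, 0.04)
  expect_silent(acdom(440, 30))
  # raw mode clamps the (negative) regression at very high salinity
  expect_warning(neg <- acdom(440, 39.5, raw = TRUE), "clamped")
  expect_equal(neg, 0)
})

test_that("particulate scattering matches Table values and interpolates", {
  expect_equal(bp(555, 1), 0.219)
  expect_equal(bp(555, 0), 0)
  expect_equal(bp(555, 10), 0.219 * 10^0.829)
  # between 532 and 555 the coefficients interpolate linearly
  A_mid <- (0.203 + 0.219) / 2
  B_mid <- (0.834 + 0.829) / 2
  expect_equal(bp(543.5, 3), A_mid * 3^B_mid)
  expect_error(bp(400, 1), "\\[412, 715\\]")
  expect_error(bp(716, 1), "\\[412, 715\\]")
})

test_that("particulate backscattering: values, 412 exclusion, monotone", {
  expect_equal(bbp(650, 1), 0.001)
  expect_equal(bbp(650, 0), 0)
  expect_error(bbp(412, 1), "excluded")
  expect_error(bbp(430, 1), "\\[440, 715\\]")
  chl <- seq(0.1, 30, length.out = 50)
  expect_true(all(diff(bbp(700, chl)) > 0))
})

test_that("partial IOPs are strictly increasing in chlorophyll", {
  chl <- c(0.1, 0.5, 1, 2, 5, 10, 30)
  for (f in list(function(c) aph(488, c), function(c) anap(488, c),
                 function(c) bp(488, c), function(c) bbp(488, c))) {
    expect_true(all(diff(f(chl)) > 0))
  }
  sal <- seq(27, 35, by = 0.5)
  expect_true(all(diff(acdom(440, sal)) < 0))
})

test_that("bundle totals equal the sum of their components", {
  wl <- c(440, 488, 510, 532, 555, 650, 676, 715)
  b <- total_iops(wl, chl = 3.2, salinity = 34.1)$spectra
  expect_equal(b$a_total, b$a_w + b$a_cdom + b$a_ph + b$a_nap,
               tolerance = 1e-12)
  expect_equal(b$b_total, b$b_w + b$b_p, tolerance = 1e-12)
  expect_equal(b$bb_total, b$bb_w + b$bb_p, tolerance = 1e-12)
  expect_equal(b$a_nw, b$a_total - b$a_w, tolerance = 1e-12)
})

test_that("zero-biomass bundle reduces to water plus CDOM", {
  b <- total_iops(c(440, 555), chl = 0, salinity = 34)$spectra
  expect_equal(b$a_total, b$a_w + b$a_cdom)
  expect_equal(b$b_total, b$b_w)
  expect_equal(b$bb_total, b$bb_w)
})

test_that("bundle at 440 nm agrees with term-by-term hand evaluation", {
  # independent spreadsheet-style evaluation from the frozen constants
  b <- total_iops(c(440, 555), chl = 1, salinity = 34)$spectra
  a_w <- 0.00635
  a_cdom <- -0.012 * 34 + 0.464
  a_ph <- 0.0654                      # A_ph(440) * 1^(1+B)
  a_nap <- 0.0124
  expect_equal(b$a_total[1], a_w + a_cdom + a_ph + a_nap, tolerance = 1e-12)
  b_w440 <- 0.00222 * (500 / 440)^4.32 * (1 + 0.30 * 34 / 37)
  expect_equal(b$b_total[1], b_w440 + 0.126, tolerance = 1e-12)
  expect_equal(b$bb_total[1], b_w440 / 2 + 0.002, tolerance = 1e-12)
})

test_that("412 nm backscattering is NA in a bundle, not an error", {
  b <- total_iops(c(412, 440), chl = 1, salinity = 34)$spectra
  expect_true(is.na(b$bb_total[1]))
  expect_false(is.na(b$bb_total[2]))
})

test_that("log-log fit on noise-free model output recovers coefficients", {
  chl <- exp(seq(log(0.1), log(30), length.out = 25))
  for (k in seq_len(nrow(cf$bp_table))) {
    wl <- cf$bp_table$wavelength_nm[k]
    fit <- loglog_fit(chl, bp(wl, chl))
    expect_equal(unname(fit["A"]), cf$bp_table$A_b[k], tolerance = 1e-8)
    expect_equal(unname(fit["B"]), cf$bp_table$B_b[k], tolerance = 1e-8)
  }
})
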