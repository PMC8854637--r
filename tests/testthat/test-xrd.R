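test_that("peak lists validate angles and widths", {
  expect_error(peak_list(c(20, 200), c(0.1, 0.1)), "0, 180")
  expect_error(peak_list(20, 0), "positive")
  pk <- peak_list(c(20, 40), c(0.2, 0.3), wavelength = 0.5609)
  expect_equal(attr(pk, "wavelength"), 0.5609)
  expect_equal(attr(pk, "source"), "sample")
})

test_that("instrumental correction subtracts widths in quadrature", {
  s <- peak_list(c(20, 40), c(0.5, 0.5))
  r <- peak_list(c(10, 50), c(0.3, 0.3), source = "reference")
  corrected <- correct_instrumental(s, r)
  expect_equal(corrected$fwhm_deg, c(0.4, 0.4), tolerance = 1e-12)   # 3-4-5
  # Lorentzian mode subtracts linearly
  lin <- correct_instrumental(s, r, mode = "lorentzian")
  expect_equal(lin$fwhm_deg, c(0.2, 0.2))
  # zero instrumental width leaves the sample unchanged
  r0 <- peak_list(c(10, 50), c(1e-9, 1e-9), source = "reference")
  expect_equal(correct_instrumental(s, r0)$fwhm_deg, s$fwhm_deg,
               tolerance = 1e-8)
  # equal widths are degenerate and must name the peak
  r_eq <- peak_list(c(10, 50), c(0.5, 0.5), source = "reference")
  expect_error(correct_instrumental(s, r_eq), "2-theta = 20")
  # reference must span the sample range
  r_short <- peak_list(c(30, 50), c(0.1, 0.1), source = "reference")
  expect_error(correct_instrumental(s, r_short), "span")
})

test_that("noiseless synthetic peaks invert exactly", {
  pk <- simulate_wh_peaks(c(20, 30, 40, 55, 70), size_nm = 20, strain = 0,
                          wavelength = 1.5406, K = 0.9)
  fit <- williamson_hall_fit(pk, K = 0.9)
  expect_equal(fit$D_nm, 20, tolerance = 1e-6)
  expect_equal(fit$strain, 0, tolerance = 1e-10)
  # intercept equals K * lambda / D in Angstrom units
  expect_equal(fit$intercept, 0.9 * 1.5406 / 200, tolerance = 1e-10)
  # size and strain recovered jointly
  pk2 <- simulate_wh_peaks(c(20, 30, 40, 55, 70, 85), size_nm = 17,
                           strain = 1e-3)
  fit2 <- williamson_hall_fit(pk2)
  expect_equal(fit2$D_nm, 17, tolerance = 1e-6)
  expect_equal(fit2$strain, 1e-3, tolerance = 1e-8)
})

test_that("pure strain broadening flags the size as undefined", {
  theta <- c(20, 30, 40, 55) / 2 * pi / 180
  beta_rad <- 4 * 2e-3 * tan(theta) - 1e-6 / cos(theta)
  pk <- peak_list(c(20, 30, 40, 55), beta_rad * 180 / pi)
  fit <- williamson_hall_fit(pk)
  expect_false(fit$size_defined)
  expect_true(is.na(fit$D_nm))
  expect_error(williamson_hall_fit(peak_list(20, 0.1)), "at least 2")
})

test_that("doubling all widths halves the crystallite size", {
  pk <- simulate_wh_peaks(c(20, 35, 50, 65), size_nm = 30, strain = 0)
  fit1 <- williamson_hall_fit(pk)
  pk2 <- pk
  pk2$fwhm_deg <- 2 * pk$fwhm_deg
  fit2 <- williamson_hall_fit(pk2)
  expect_equal(fit2$D_nm, fit1$D_nm / 2, tolerance = 1e-8)
})

test_that("the fit is invariant to how the angles are tabulated", {
  # same Bragg angles entered with different wavelength tags scale D by lambda
  pk_cu <- simulate_wh_peaks(c(20, 30, 45, 60), size_nm = 25,
                             wavelength = 1.5406)
  fit_cu <- williamson_hall_fit(pk_cu)
  expect_equal(fit_cu$wavelength, 1.5406)
  fit_override <- williamson_hall_fit(pk_cu, wavelength = 2 * 1.5406)
  expect_equal(fit_override$D_nm, 2 * fit_cu$D_nm, tolerance = 1e-10)
})

test_that("2% width noise recovers the size within 15%", {
  set.seed(99)
  D_hat <- replicate(100, {
    pk <- simulate_wh_peaks(c(20, 30, 40, 55, 70, 85), size_nm = 20,
                            strain = 5e-4)
    pk$fwhm_deg <- pk$fwhm_deg * (1 + rnorm(6, 0, 0.02))
    williamson_hall_fit(pk)$D_nm
  })
  expect_true(all(abs(D_hat / 20 - 1) <= 0.15))
  expect_equal(mean(D_hat), 20, tolerance = 0.05)
})

test_that("tidy, glance and autoplot expose the fit", {
  pk <- simulate_wh_peaks(c(20, 30, 40, 55), size_nm = 17, strain = 1e-3)
  fit <- williamson_hall_fit(pk)
  td <- tidy(fit)
  expect_equal(td$term, c("size_nm", "strain", "intercept", "slope"))
  expect_equal(td$estimate[1], 17, tolerance = 1e-6)
  gl <- glance(fit)
  expect_true(gl$size_defined)
  expect_equal(gl$n_peaks, 4L)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})

test_that("peak CSV round trip preserves the table", {
  pk <- simulate_wh_peaks(c(20, 30, 40), size_nm = 20)
  f <- tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(pk)[, c("two_theta_deg", "fwhm_deg")], f,
                   row.names = FALSE)
  back <- read_peaks(f, wavelength = 1.5406)
  expect_equal(back$two_theta_deg, pk$two_theta_deg)
  expect_equal(back$fwhm_deg, pk$fwhm_deg, tolerance = 1e-12)
  unlink(f)
})
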