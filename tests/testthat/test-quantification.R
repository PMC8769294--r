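test_that("epsilon fit recovers an exact generative coefficient with zero spread", {
  fit <- fit_epsilon(calibration_series(epsilon = 2600))
  g <- glance(fit)
  expect_equal(g$epsilon_mean, 2600, tolerance = 1e-12)
  expect_equal(g$epsilon_sd, 0, tolerance = 1e-9)
  expect_equal(g$n_records, 13)
  # slope-through-origin agrees on exact data
  fit2 <- fit_epsilon(calibration_series(epsilon = 2600), method = "slope")
  expect_equal(glance(fit2)$epsilon_mean, 2600, tolerance = 1e-12)
})

test_that("a single calibration record gives the scalar Beer-Lambert ratio", {
  # oracle: A / (c l) with c in mol/m^3
  oracle <- 1.064 / (41.63e-6 * 1e3 * 0.01)
  fit <- fit_epsilon(data.frame(concentration_mol_per_L = 41.63e-6,
                                absorbance = 1.064, path_length_m = 0.01))
  expect_equal(fit$epsilon_mean, oracle, tolerance = 1e-12)
  expect_equal(round(fit$epsilon_mean), 2556)
  expect_equal(fit$epsilon_sd, 0)
})

test_that("epsilon fit under multiplicative noise is unbiased within 2 percent", {
  eps <- vapply(1:100, function(s) {
    set.seed(1000 + s)
    fit_epsilon(calibration_series(epsilon = 2555, noise_sd = 0.02))$epsilon_mean
  }, numeric(1))
  expect_lt(abs(mean(eps) - 2555) / 2555, 0.02)
})

test_that("epsilon fit is scale-consistent and validates its input", {
  curve <- calibration_series(epsilon = 2555)
  base <- fit_epsilon(curve)$epsilon_mean
  curve2 <- curve
  curve2$concentration_mol_per_L <- curve$concentration_mol_per_L * 3
  expect_equal(fit_epsilon(curve2)$epsilon_mean, base / 3, tolerance = 1e-12)
  bad <- curve; bad$concentration_mol_per_L[1] <- 0
  expect_error(fit_epsilon(bad), class = "absorbcell_invalid_input")
  bad2 <- curve; bad2$path_length_m[3] <- -1
  expect_error(fit_epsilon(bad2), class = "absorbcell_invalid_input")
  expect_error(fit_epsilon(curve[0, ]), class = "absorbcell_invalid_input")
})

test_that("pixel moles follows the closed form and is linear in A and pixel area", {
  m <- pixel_dose_model(2500, pixel_size = 1)
  expect_equal(pixel_moles(0, m), 0)
  expect_equal(pixel_moles(1, m), 4e-16)
  # negative absorbance gives negative moles, retained
  expect_equal(pixel_moles(-0.5, m), -2e-16)
  # linearity in A
  expect_equal(pixel_moles(2.5, m), 2.5 * pixel_moles(1, m))
  # quadratic in pixel size
  m2 <- pixel_dose_model(2500, pixel_size = 2)
  expect_equal(pixel_moles(1, m2), 4 * pixel_moles(1, m))
})

test_that("moles are conserved under any partition of a mask", {
  set.seed(9)
  m <- pixel_dose_model(2555, pixel_size = 0.65)
  A <- runif(200, -0.1, 1)
  parts <- split(A, sample(1:7, 200, replace = TRUE))
  whole <- pixel_moles(sum(A), m)
  by_part <- sum(vapply(parts, function(p) pixel_moles(sum(p), m), numeric(1)))
  expect_equal(by_part, whole, tolerance = 1e-12)
})

test_that("parts-based dilution reproduces the staining concentration", {
  # 1:4 staining dilution of the 4.163 mmol/L stock
  expect_equal(round(dilution_concentration(4.163e-3, 1, 4) * 1e3, 3), 0.833)
  expect_equal(dilution_concentration(2, 1, 0), 2)
  expect_equal(dilution_concentration(2, 0, 5), 0)
  expect_error(dilution_concentration(2, 0, 0), class = "absorbcell_invalid_input")
  expect_error(dilution_concentration(2, -1, 2), class = "absorbcell_invalid_input")
})

test_that("percent difference uses the symmetric mean-denominator convention", {
  expect_equal(round(percent_difference(20.6, 21.4), 1), 3.8)
  expect_equal(round(percent_difference(14.7, 11.8), 1), 21.9)
  expect_equal(percent_difference(5, 5), 0)
  expect_equal(percent_difference(3, 7), percent_difference(7, 3))
  expect_error(percent_difference(1, -1), class = "absorbcell_invalid_input")
})

test_that("cell molarity is moles over volume with positive-volume contract", {
  expect_equal(cell_molarity(1e-15, 1e-12), 1e-3)
  expect_equal(cell_molarity(0, 2e-12), 0)
  # a 20.6 fmol cell of 1.39 pL is ~14.8 mmol/L
  expect_equal(round(cell_molarity(20.6e-15, 1.39e-12) * 1e3, 1), 14.8)
  expect_error(cell_molarity(1e-15, 0), class = "absorbcell_invalid_input")
  expect_error(cell_molarity(1e-15, -1e-12), class = "absorbcell_invalid_input")
})

test_that("calibration tables round-trip through CSV", {
  curve <- calibration_series(epsilon = 2555)
  f <- withr::local_tempfile(fileext = ".csv")
  write_calibration_csv(curve, f)
  back <- read_calibration_csv(f)
  expect_equal(as.data.frame(back), curve, tolerance = 1e-12)
  write.csv(data.frame(x = 1), f, row.names = FALSE)
  expect_error(read_calibration_csv(f), class = "absorbcell_invalid_input")
})
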