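test_that("reference averaging is the per-pixel arithmetic mean, kept in float", {
  imgs <- lapply(c(100, 200, 300, 400), flat_image, role = "Imax")
  avg <- average_reference_images(imgs)
  expect_equal(avg$pixels, matrix(250, 8, 8))
  # identity case
  same <- average_reference_images(rep(list(flat_image(123, role = "Imin")), 4))
  expect_equal(same$pixels, matrix(123, 8, 8))
  # non-integer means survive
  avg2 <- average_reference_images(lapply(c(100, 101), flat_image, role = "Imax"))
  expect_equal(avg2$pixels[1, 1], 100.5)
})

test_that("reference averaging rejects mismatched or empty input", {
  a <- intensity_image(matrix(1, 64, 64), role = "Imax")
  b <- intensity_image(matrix(1, 64, 32), role = "Imax")
  expect_error(average_reference_images(list(a, b)), class = "absorbcell_invalid_input")
  expect_error(average_reference_images(list()), class = "absorbcell_invalid_input")
  c8 <- intensity_image(matrix(1, 64, 64), bit_depth = 8, role = "Imax")
  expect_error(average_reference_images(list(a, c8)), class = "absorbcell_invalid_input")
  i <- intensity_image(matrix(1, 64, 64), role = "I")
  expect_error(average_reference_images(list(a, i)), class = "absorbcell_invalid_input")
})

test_that("intensity images enforce count range and metadata invariants", {
  expect_error(intensity_image(matrix(-1, 4, 4)), class = "absorbcell_invalid_input")
  expect_error(intensity_image(matrix(300, 4, 4), bit_depth = 8),
               class = "absorbcell_invalid_input")
  expect_error(intensity_image(matrix(1, 4, 4), pixel_size = 0),
               class = "absorbcell_invalid_input")
  expect_silent(intensity_image(matrix(65535, 4, 4)))
})

test_that("absorbance conversion satisfies its closed-form contracts", {
  Imax <- flat_image(10000, role = "Imax")
  Imin <- flat_image(0, role = "Imin")
  # I = Imax -> A = 0
  expect_equal(to_absorbance(flat_image(10000), Imax, Imin)$pixels,
               matrix(0, 8, 8))
  # transmittance 0.1 -> A = 1
  expect_equal(to_absorbance(flat_image(1000), Imax, Imin)$pixels,
               matrix(1, 8, 8))
  # dark offset is removed: (I-Imin)/(Imax-Imin)
  Imin2 <- flat_image(500, role = "Imin")
  A <- to_absorbance(flat_image(1450), Imax, Imin2)
  expect_equal(A$pixels[1, 1], -log10((1450 - 500) / (10000 - 500)))
})

test_that("opaque pixels are capped and bright pixels keep negative absorbance", {
  Imax <- flat_image(10000, role = "Imax")
  Imin <- flat_image(100, role = "Imin")
  # I <= Imin -> cap
  A <- to_absorbance(flat_image(50), Imax, Imin, cap = 4)
  expect_equal(A$pixels, matrix(4, 8, 8))
  A2 <- to_absorbance(flat_image(100), Imax, Imin, cap = 2.5)
  expect_equal(A2$pixels, matrix(2.5, 8, 8))
  # I > Imax -> negative absorbance retained
  px <- matrix(10000, 8, 8); px[1, 1] <- 12000
  A3 <- to_absorbance(intensity_image(px), Imax, Imin)
  expect_lt(A3$pixels[1, 1], 0)
  expect_equal(A3$pixels[1, 1], -log10((12000 - 100) / 9900))
})

test_that("degenerate reference pairs raise an error naming the pixel count", {
  Imax <- flat_image(100, role = "Imax")
  Imin <- flat_image(100, role = "Imin")
  err <- expect_error(
    to_absorbance(flat_image(50), Imax, Imin),
    class = "absorbcell_degenerate_reference")
  expect_match(conditionMessage(err), "64 pixel")
})

test_that("pixelwise conversion equals the scalar formula applied in a loop", {
  set.seed(71)
  n <- 40
  imin <- matrix(runif(n * n, 0, 400), n, n)
  imax <- imin + matrix(runif(n * n, 2000, 40000), n, n)
  i_px <- imin + (imax - imin) * matrix(runif(n * n, 0.02, 1.2), n, n)
  A <- to_absorbance(
    intensity_image(i_px), intensity_image(imax, role = "Imax"),
    intensity_image(imin, role = "Imin"), cap = 6)
  oracle <- matrix(NA_real_, n, n)
  for (r in seq_len(n)) for (c in seq_len(n)) {
    ratio <- (i_px[r, c] - imin[r, c]) / (imax[r, c] - imin[r, c])
    oracle[r, c] <- if (ratio <= 1e-6) 6 else -log10(ratio)
  }
  expect_equal(A$pixels, oracle, tolerance = 1e-14)
})

test_that("absorbance is strictly decreasing in intensity between the references", {
  Imax <- flat_image(50000, role = "Imax")
  Imin <- flat_image(1000, role = "Imin")
  vals <- seq(1500, 50000, length.out = 50)
  As <- vapply(vals, function(v)
    to_absorbance(flat_image(v), Imax, Imin)$pixels[1, 1], numeric(1))
  expect_true(all(diff(As) < 0))
})

test_that("a known OD field round-trips through generation and conversion", {
  set.seed(5)
  od <- matrix(runif(32 * 32, 0, 1.5), 32, 32)
  tr <- triplet_from_od(od)
  A <- to_absorbance(tr$I, tr$Imax, tr$Imin)
  expect_lt(max(abs(A$pixels - od)), 1e-6)
})

test_that("exposure report counts clipped and saturated pixels", {
  # all-zero image: fully underexposed, flagged
  rep0 <- check_exposure(flat_image(0))
  expect_equal(rep0$zero_fraction, 1)
  expect_true(rep0$flagged)
  # blank at half scale: fine
  rep1 <- check_exposure(flat_image(128, bit_depth = 8))
  expect_false(rep1$flagged)
  expect_equal(rep1$top_fraction, 0)
  # 5 % saturated 16-bit pixels: flagged
  px <- matrix(30000, 20, 20)
  px[seq_len(20)] <- 65535
  rep2 <- check_exposure(intensity_image(px))
  expect_equal(rep2$top_fraction, 0.05)
  expect_true(rep2$flagged)
  expect_gte(rep2$near_top_fraction, rep2$top_fraction)
})
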