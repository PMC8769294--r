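test_that("segmentation parameter contracts hold", {
  expect_error(segmentation_params(sensitivity = 1.2),
               class = "absorbcell_invalid_input")
  expect_error(segmentation_params(r_min = 5, r_max = 5),
               class = "absorbcell_invalid_input")
  expect_error(segmentation_params(r_min = 0),
               class = "absorbcell_invalid_input")
  p <- segmentation_params()
  expect_equal(p$connectivity, 8L)
  expect_true(p$fill_holes)
})

test_that("a constant image yields no objects", {
  img <- absorbance_image(matrix(0.3, 128, 128))
  expect_equal(segment_cells(img)$n, 0)
})

test_that("the adaptive-threshold window must fit inside the image", {
  tiny <- absorbance_image(matrix(0.1, 2, 2))
  expect_error(segment_cells(tiny), class = "absorbcell_invalid_input")
})

test_that("well-separated stained disks are each found at their centroid", {
  centers <- cbind(c(25, 25, 64, 100, 100), c(25, 100, 64, 25, 100))
  img <- disk_field(centers, radius_um = 8, od = 0.4)
  seg <- segment_cells(img, segmentation_params(sensitivity = 0.45))
  expect_equal(seg$n, 5)
  labs <- seg$labels
  idx <- which(labs > 0)
  rr <- (idx - 1) %% nrow(labs) + 1
  cc <- (idx - 1) %/% nrow(labs) + 1
  cen <- cbind(tapply(rr, labs[idx], mean), tapply(cc, labs[idx], mean))
  # each true center has a segmented centroid within one pixel
  for (i in seq_len(nrow(centers))) {
    d <- sqrt((cen[, 1] - centers[i, 1])^2 + (cen[, 2] - centers[i, 2])^2)
    expect_lt(min(d), 1)
  }
})

test_that("the size filter removes objects outside the radius range", {
  # r = 2 um disk is below r_min = 4 um
  img <- disk_field(cbind(64, 64), radius_um = 2, od = 0.5)
  expect_equal(segment_cells(img)$n, 0)
  # huge blob above r_max is removed too
  img2 <- disk_field(cbind(64, 64), radius_um = 40, od = 0.5,
                     shape = c(160, 160))
  expect_equal(segment_cells(img2, segmentation_params(
    exclude_border = FALSE))$n, 0)
})

test_that("border-touching objects are excluded by default and kept on request", {
  img <- disk_field(cbind(5, 64), radius_um = 8, od = 0.5)
  expect_equal(segment_cells(img)$n, 0)
  expect_equal(segment_cells(img, segmentation_params(
    exclude_border = FALSE))$n, 1)
})

test_that("every returned object satisfies the size-filter invariant", {
  set.seed(31)
  for (case in 1:3) {
    e <- generate_experiment("DT", seed = 100 + case, n_fields = 1,
                             cells_per_field = 12, shape = c(192, 192))
    A <- to_absorbance(
      e$datasets$DT$fields[[1]]$I,
      average_reference_images(e$datasets$DT$fields[[1]]$Imax),
      average_reference_images(e$datasets$DT$fields[[1]]$Imin))
    seg <- segment_cells(A, e$params)
    m <- measure_cells(seg, A, e$model)
    expect_true(all(m$area_um2 >= pi * e$params$r_min^2))
    expect_true(all(m$area_um2 <= pi * e$params$r_max^2))
    expect_true(all(m$feret_min_um <= m$feret_max_um + 1e-9))
    # equivalent-circle diameter never exceeds the max Feret diameter
    expect_true(all(2 * sqrt(m$area_um2 / pi) <= m$feret_max_um + 1e-9))
  }
})

test_that("ellipsoid volume matches its closed forms and contracts", {
  # sphere of diameter 10 um
  expect_equal(ellipsoid_volume(10, 10), (4 / 3) * pi * 125 * 1e-15)
  expect_equal(round(ellipsoid_volume(10, 10) * 1e15), 524)
  # prolate spheroid 16 x 9 um
  expect_equal(ellipsoid_volume(16, 9), (4 / 3) * pi * 8 * 4.5 * 4.5 * 1e-15)
  expect_error(ellipsoid_volume(10, 0), class = "absorbcell_invalid_input")
  expect_error(ellipsoid_volume(0, 0), class = "absorbcell_invalid_input")
  expect_error(ellipsoid_volume(8, 10), class = "absorbcell_invalid_input")
})

test_that("measured content of a uniform square matches the closed form", {
  A <- absorbance_image(matrix(0, 64, 64))
  A$pixels[20:29, 30:39] <- 0.2
  labels <- matrix(0L, 64, 64)
  labels[20:29, 30:39] <- 1L
  m <- measure_cells(labels, A, pixel_dose_model(2500, 1))
  expect_equal(nrow(m), 1)
  expect_equal(m$area_px, 100L)
  expect_equal(m$sum_absorbance, 20)
  expect_equal(m$moles_fmol, 8)   # 20 * 1e-12 / 2500 mol
  # 10 x 10 px square: both Feret diameters from pixel corners
  expect_equal(m$feret_min_um, 10)
  expect_equal(m$feret_max_um, 10 * sqrt(2))
})

test_that("per-object moles equal a brute-force pixel enumeration oracle", {
  set.seed(12)
  A <- absorbance_image(matrix(runif(64 * 64, -0.05, 0.6), 64, 64))
  labels <- matrix(0L, 64, 64)
  labels[sample(64 * 64, 500)] <- sample(1:6, 500, replace = TRUE)
  model <- pixel_dose_model(2555, 0.8)
  m <- measure_cells(labels, A, model)
  for (l in m$label) {
    sum_or <- 0
    for (r in 1:64) for (c in 1:64)
      if (labels[r, c] == l) sum_or <- sum_or + A$pixels[r, c]
    expect_equal(m$sum_absorbance[m$label == l], sum_or, tolerance = 1e-12)
    expect_equal(m$moles_fmol[m$label == l],
                 sum_or * (0.8e-6)^2 / 2555 * 1e15, tolerance = 1e-12)
  }
})

test_that("empty label sets and absent labels are handled", {
  A <- absorbance_image(matrix(0.1, 32, 32))
  labels <- matrix(0L, 32, 32)
  m <- measure_cells(labels, A, pixel_dose_model(2500, 1))
  expect_equal(nrow(m), 0)
  labels[5:10, 5:10] <- 1L
  expect_warning(
    m2 <- measure_cells(labels, A, pixel_dose_model(2500, 1), which = c(1, 7)),
    "absent")
  expect_equal(m2$label, 1L)
})

test_that("a single-pixel object has Feret diameter equal to the pixel size", {
  A <- absorbance_image(matrix(0.1, 32, 32), pixel_size = 0.7)
  labels <- matrix(0L, 32, 32)
  labels[16, 16] <- 1L
  m <- measure_cells(labels, A, pixel_dose_model(2500, 0.7))
  expect_equal(m$feret_min_um, 0.7)
  expect_equal(m$feret_max_um, 0.7 * sqrt(2))
})

test_that("doubling the pixel size quadruples areas but not pixel counts", {
  mk <- function(px) {
    A <- absorbance_image(matrix(0, 64, 64), pixel_size = px)
    A$pixels[20:31, 20:31] <- 0.3
    labels <- matrix(0L, 64, 64); labels[20:31, 20:31] <- 1L
    measure_cells(labels, A, pixel_dose_model(2500, px))
  }
  m1 <- mk(1); m2 <- mk(2)
  expect_equal(m1$area_px, m2$area_px)
  expect_equal(m2$area_um2, 4 * m1$area_um2)
  expect_equal(m2$moles_fmol, 4 * m1$moles_fmol)
})

test_that("hole filling closes scattering rings into full disks", {
  # an annulus only: with fill_holes the object area includes the interior
  m <- matrix(0, 96, 96)
  rr <- outer((1:96) - 0.5 - 48, rep(1, 96))
  cc <- t(rr)
  ring <- rr^2 + cc^2 <= 9^2 & rr^2 + cc^2 >= 7^2
  m[ring] <- 0.3
  img <- absorbance_image(m)
  seg_fill <- segment_cells(img, segmentation_params(sensitivity = 0.45))
  seg_open <- segment_cells(img, segmentation_params(sensitivity = 0.45,
                                                     fill_holes = FALSE))
  expect_equal(seg_fill$n, 1)
  expect_gt(sum(seg_fill$labels > 0), sum(ring))
  expect_true(all(seg_fill$labels[rr^2 + cc^2 < 7^2] == 1))
  # without filling, the annulus alone is thinner than its filled disk
  expect_lt(sum(seg_open$labels > 0), sum(seg_fill$labels > 0))
})
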