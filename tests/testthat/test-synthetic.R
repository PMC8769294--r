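test_that("an empty noise-free phantom has I identical to Imax", {
  spec <- phantom_spec(shape = c(64, 64), read_noise_sd = 0,
                       shot_noise = FALSE, medium_od = 0, seed = 1)
  fld <- generate_field(spec)
  expect_identical(fld$I$pixels, fld$Imax$pixels)
  expect_true(all(fld$Imin$pixels == spec$dark_level))
  expect_equal(nrow(fld$truth), 0)
})

test_that("generation is bit-identical for equal seeds and differs across seeds", {
  spec1 <- phantom_spec(shape = c(64, 64), seed = 7)
  f1 <- generate_field(spec1)
  f2 <- generate_field(spec1)
  expect_identical(f1$I$pixels, f2$I$pixels)
  expect_identical(f1$Imax$pixels, f2$Imax$pixels)
  spec2 <- phantom_spec(shape = c(64, 64), seed = 8)
  f3 <- generate_field(spec2)
  expect_false(identical(f1$I$pixels, f3$I$pixels))
})

test_that("generated OD equals -log10(I/Imax) in the noise-free, zero-dark limit", {
  cells <- tibble::tibble(row_um = 40, col_um = 40, a_um = 7, b_um = 6.5,
                          theta = 0.4, moles_fmol = 15, ring_od = 0.15,
                          ring_width_um = 1)
  spec <- phantom_spec(shape = c(96, 96), dark_level = 0, read_noise_sd = 0,
                       shot_noise = FALSE, illumination_gradient = 0,
                       medium_od = 0.2, cells = cells, seed = 3)
  fld <- generate_field(spec)
  od <- -log10(fld$I$pixels / fld$Imax$pixels)
  # medium everywhere outside the cell
  expect_equal(od[5, 5], 0.2, tolerance = 1e-12)
  # total intracellular OD integrates back to the generated moles
  area_m2 <- (spec$pixel_size * 1e-6)^2
  tot_od_cell <- sum(od - 0.2) -
    0.15 * sum(abs(od - 0.2 - 0.15) < 1e-9)   # remove ring contribution
  moles_back <- tot_od_cell * area_m2 / spec$epsilon * 1e15
  expect_equal(moles_back, 15, tolerance = 1e-3)
})

test_that("a single noise-free 20 fmol cell is recovered by the pipeline within 1 percent", {
  cells <- tibble::tibble(row_um = 60, col_um = 64, a_um = 7, b_um = 7,
                          theta = 0, moles_fmol = 20, ring_od = 0,
                          ring_width_um = 1)
  spec <- phantom_spec(shape = c(128, 128), read_noise_sd = 0,
                       shot_noise = FALSE, medium_od = 0, cells = cells,
                       seed = 5)
  fld <- generate_field(spec)
  A <- to_absorbance(fld$I, fld$Imax, fld$Imin)
  seg <- segment_cells(A, segmentation_params(sensitivity = 0.45))
  m <- measure_cells(seg, A, pixel_dose_model(spec$epsilon, spec$pixel_size))
  expect_equal(nrow(m), 1)
  expect_equal(m$moles_fmol, 20, tolerance = 0.01)
})

test_that("phantom specs reject out-of-bounds and overlapping cells", {
  bad1 <- tibble::tibble(row_um = 3, col_um = 32, a_um = 7, b_um = 7,
                         moles_fmol = 0)
  expect_error(phantom_spec(shape = c(64, 64), cells = bad1),
               class = "absorbcell_generation")
  bad2 <- tibble::tibble(row_um = c(30, 35), col_um = c(30, 35),
                         a_um = 7, b_um = 7, moles_fmol = 0)
  expect_error(phantom_spec(shape = c(64, 64), cells = bad2),
               class = "absorbcell_generation")
  expect_error(phantom_spec(shape = c(64, 64),
                            cells = tibble::tibble(row_um = 30, col_um = 30,
                                                   a_um = 7, b_um = 7,
                                                   moles_fmol = -1)),
               class = "absorbcell_invalid_input")
})

test_that("random layouts respect margins and separations; impossible ones error", {
  set.seed(61)
  lay <- random_cell_layout(20, c(256, 256), 1)
  d <- as.matrix(dist(cbind(lay$row_um, lay$col_um)))
  diag(d) <- Inf
  lim <- outer(lay$a_um + 1, lay$a_um + 1, "+") + 3
  expect_true(all(d > lim))
  expect_true(all(lay$row_um > lay$a_um & lay$row_um < 256 - lay$a_um))
  expect_error(random_cell_layout(500, c(64, 64), 1, max_attempts = 20),
               class = "absorbcell_generation")
})

test_that("experiment-level truth tables match the treatment designs", {
  e <- generate_experiment(c("LD", "MIXTURE"), seed = 9, n_fields = 2,
                           cells_per_field = 10, shape = c(192, 192))
  # live-in-buffer cells carry no dye
  expect_true(all(e$truth$LD$moles_fmol == 0))
  expect_true(all(!e$truth$LD$dead))
  # mixtures are exactly half dead by construction
  expect_equal(nrow(e$truth$MIXTURE), 20)
  expect_equal(mean(e$truth$MIXTURE$dead), 0.5)
  expect_true(all(e$truth$MIXTURE$moles_fmol[e$truth$MIXTURE$dead] >= 0))
  expect_true(all(e$truth$MIXTURE$moles_fmol[!e$truth$MIXTURE$dead] == 0))
  # reference frames: four blanks and four darks shared per treatment
  expect_length(e$datasets$LD$fields[[1]]$Imax, 4)
  expect_length(e$datasets$LD$fields[[1]]$Imin, 4)
})
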