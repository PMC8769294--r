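# Run code with a temporary RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specify a synthetic brightfield phantom
#'
#' Describes one synthetic field of view: the camera (shape, bit depth,
#' pixel size), the illumination (base count plus a smooth linear
#' gradient), the dark level, the noise model (Gaussian read noise and
#' optional Poisson shot noise), a uniform medium absorbance (0 for
#' plain-buffer preparations, ~0.3 for dye-stained media), and the cells.
#'
#' Each cell is an ellipse whose intracellular dye (`moles_fmol`) is
#' spread uniformly over its footprint as optical density
#' `OD = moles * epsilon / (area_px * pixel_area)`, plus a positive OD
#' ring of width `ring_width_um` just outside its boundary -- a
#' phenomenological stand-in for the edge scattering of real cells, not
#' a physical-optics model. Cells must lie fully inside the image and
#' must not overlap (checked on bounding circles including rings).
#'
#' @param shape Integer c(rows, cols) of the image grid.
#' @param pixel_size Micrometres per pixel.
#' @param bit_depth Camera bit depth (8 or 16).
#' @param illumination_base Blank-field counts at the image center.
#' @param illumination_gradient Relative amplitude of the smooth linear
#'   illumination gradient (0 = flat field).
#' @param dark_level Dark (closed-shutter) counts.
#' @param read_noise_sd Gaussian read noise SD in counts (applied to
#'   every frame).
#' @param shot_noise Apply Poisson shot noise to the photo-signal?
#' @param medium_od Uniform absorbance of the suspension medium.
#' @param epsilon Molar absorption coefficient (m^2/mol) used to convert
#'   each cell's moles into its OD footprint.
#' @param cells Data frame with one row per cell: `row_um`, `col_um`
#'   (center), `a_um`, `b_um` (semi-axes), `theta` (orientation, rad),
#'   `moles_fmol`, `ring_od`, `ring_width_um`, and optionally `dead`.
#'   May be empty. An optional `ring_fmol` column (apparent scattering
#'   content in fmol) overrides `ring_od`: the amplitude is then chosen
#'   so the discrete ring integrates to exactly that content.
#' @param seed Integer seed; the whole field is a deterministic function
#'   of the spec including this seed.
#' @return An object of class `"phantom_spec"`.
#' @export
phantom_spec <- function(shape = c(320, 320), pixel_size = 1, bit_depth = 16,
                         illumination_base = 30000,
                         illumination_gradient = 0.05,
                         dark_level = 500, read_noise_sd = 60,
                         shot_noise = TRUE, medium_od = 0, epsilon = 2555,
                         cells = NULL, seed = 1) {
  if (length(shape) != 2 || any(shape < 16))
    .stop_input("`shape` must be two dimensions of at least 16 pixels")
  if (pixel_size <= 0) .stop_input("`pixel_size` must be positive")
  if (!bit_depth %in% c(8, 16)) .stop_input("`bit_depth` must be 8 or 16")
  top <- 2^bit_depth - 1
  if (illumination_base <= dark_level || illumination_base > top)
    .stop_input("`illumination_base` must lie in (dark_level, 2^bit_depth - 1]")
  if (medium_od < 0) .stop_input("`medium_od` must be non-negative")
  if (epsilon <= 0) .stop_input("`epsilon` must be positive")
  if (is.null(cells)) {
    cells <- tibble(row_um = double(), col_um = double(), a_um = double(),
                    b_um = double(), theta = double(), moles_fmol = double(),
                    ring_od = double(), ring_width_um = double(),
                    dead = logical())
  }
  cells <- as_tibble(cells)
  if (!"theta" %in% names(cells)) cells$theta <- 0
  if (!"ring_od" %in% names(cells)) cells$ring_od <- 0
  if (!"ring_width_um" %in% names(cells)) cells$ring_width_um <- 1
  if (!"dead" %in% names(cells)) cells$dead <- cells$moles_fmol > 0
  need <- c("row_um", "col_um", "a_um", "b_um", "moles_fmol")
  if (nrow(cells) > 0) {
    if (!all(need %in% names(cells)))
      .stop_input(paste("`cells` must have columns",
                        paste(need, collapse = ", ")))
    if (any(cells$moles_fmol < 0)) .stop_input("cell moles must be >= 0")
    if (any(cells$a_um <= 0 | cells$b_um <= 0 | cells$b_um > cells$a_um))
      .stop_input("cell semi-axes must satisfy 0 < b_um <= a_um")
    ext <- shape * pixel_size
    r_out <- cells$a_um + cells$ring_width_um
    inside <- cells$row_um - r_out >= 0 & cells$row_um + r_out <= ext[1] &
      cells$col_um - r_out >= 0 & cells$col_um + r_out <= ext[2]
    if (!all(inside))
      abort("cell(s) extend outside the image", class = "absorbcell_generation")
    if (nrow(cells) > 1) {
      d <- as.matrix(stats::dist(cbind(cells$row_um, cells$col_um)))
      lim <- outer(r_out, r_out, "+")
      diag(d) <- Inf
      if (any(d <= lim))
        abort("cells overlap", class = "absorbcell_generation")
    }
  }
  structure(list(shape = as.integer(shape), pixel_size = pixel_size,
                 bit_depth = as.integer(bit_depth),
                 illumination_base = illumination_base,
                 illumination_gradient = illumination_gradient,
                 dark_level = dark_level, read_noise_sd = read_noise_sd,
                 shot_noise = isTRUE(shot_noise), medium_od = medium_od,
                 epsilon = epsilon, cells = cells, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec [%d x %d]> %d cell(s), medium OD %g, seed %d\n",
              x$shape[1], x$shape[2], nrow(x$cells), x$medium_od, x$seed))
  invisible(x)
}

# Smooth illumination field (clean blank counts, no noise).
.illumination_field <- function(spec) {
  nr <- spec$shape[1]; nc <- spec$shape[2]
  yn <- (seq_len(nr) - 0.5) / nr - 0.5
  xn <- (seq_len(nc) - 0.5) / nc - 0.5
  g <- spec$illumination_gradient
  amp <- spec$illumination_base - spec$dark_level
  spec$dark_level +
    amp * (1 + g * outer(yn * 0.5, xn, `+`))
}

# Clean optical-density field implied by the spec's medium and cells.
.od_field <- function(spec) {
  nr <- spec$shape[1]; nc <- spec$shape[2]
  px <- spec$pixel_size
  od <- matrix(spec$medium_od, nr, nc)
  area_m2 <- (px * .const$um_to_m)^2
  cells <- spec$cells
  for (i in seq_len(nrow(cells))) {
    a <- cells$a_um[i]; b <- cells$b_um[i]; th <- cells$theta[i]
    w <- cells$ring_width_um[i]
    cy <- cells$row_um[i]; cx <- cells$col_um[i]
    r_out <- a + w
    rr <- max(1L, floor((cy - r_out) / px)):min(nr, ceiling((cy + r_out) / px))
    cc <- max(1L, floor((cx - r_out) / px)):min(nc, ceiling((cx + r_out) / px))
    y <- (rr - 0.5) * px - cy
    x <- (cc - 0.5) * px - cx
    u <- outer(y, x, function(yy, xx) xx * cos(th) + yy * sin(th))
    v <- outer(y, x, function(yy, xx) -xx * sin(th) + yy * cos(th))
    inside <- (u / a)^2 + (v / b)^2 <= 1
    outer_m <- (u / (a + w))^2 + (v / (b + w))^2 <= 1
    n_in <- sum(inside)
    if (n_in == 0)
      abort("cell footprint smaller than one pixel",
            class = "absorbcell_generation")
    add <- matrix(0, length(rr), length(cc))
    add[inside] <- cells$moles_fmol[i] / .const$mol_to_fmol *
      spec$epsilon / (n_in * area_m2)
    ring <- outer_m & !inside
    ring_amp <- if ("ring_fmol" %in% names(cells) &&
                    !is.na(cells$ring_fmol[i])) {
      # exact apparent content spread over the discrete ring pixels
      n_ring <- sum(ring)
      if (n_ring == 0) 0
      else cells$ring_fmol[i] / .const$mol_to_fmol * spec$epsilon /
        (n_ring * area_m2)
    } else cells$ring_od[i]
    add[ring] <- add[ring] + ring_amp
    od[rr, cc] <- od[rr, cc] + add
  }
  od
}

# Render one noisy, quantized frame from clean counts. In the fully
# noise-free limit (no read noise, no shot noise) the ideal real-valued
# counts are returned unquantized, so closed-form round trips are exact.
.render_frame <- function(clean, spec, role) {
  noisefree <- spec$read_noise_sd == 0 && !spec$shot_noise
  top <- 2^spec$bit_depth - 1
  counts <- if (noisefree) {
    clean
  } else {
    signal <- pmax(clean - spec$dark_level, 0)
    if (spec$shot_noise) signal <- stats::rpois(length(signal), signal)
    out <- spec$dark_level + signal +
      rnorm(length(clean), sd = spec$read_noise_sd)
    matrix(pmin(pmax(round(out), 0), top), nrow(clean), ncol(clean))
  }
  intensity_image(counts, bit_depth = spec$bit_depth,
                  pixel_size = spec$pixel_size, role = role)
}

#' Generate one synthetic brightfield triplet
#'
#' Renders the blank reference (`Imax`, the illumination field), the
#' dark reference (`Imin`, the dark level) and the sample frame
#' (`I = Imin_clean + (Imax_clean - Imin_clean) * 10^-OD`, with the OD
#' field built from the medium and the cells), each with the spec's
#' noise model and 16-bit (or 8-bit) quantization. With zero read noise
#' and shot noise disabled, ideal real-valued counts are returned, so
#' the generated OD is recovered exactly by the absorbance conversion.
#'
#' Everything is a deterministic function of the spec: the same spec
#' (including its seed) yields bit-identical frames.
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `I`, `Imax`, `Imin`
#'   ([intensity_image()]s) and `truth`, a tibble of the generating
#'   cells (center, axes, true moles, ring parameters, `dead` flag,
#'   `area_px` of the intracellular footprint).
#' @export
generate_field <- function(spec) {
  if (!inherits(spec, "phantom_spec"))
    .stop_input("`spec` must be a phantom_spec")
  .with_seed(spec$seed, {
    imax_clean <- .illumination_field(spec)
    imin_clean <- matrix(spec$dark_level, spec$shape[1], spec$shape[2])
    od <- .od_field(spec)
    i_clean <- imin_clean + (imax_clean - imin_clean) * 10^(-od)
    Imax <- .render_frame(imax_clean, spec, "Imax")
    Imin <- .render_frame(imin_clean, spec, "Imin")
    I <- .render_frame(i_clean, spec, "I")
    truth <- spec$cells
    if (nrow(truth) > 0) {
      px <- spec$pixel_size
      truth$area_px <- vapply(seq_len(nrow(truth)), function(i) {
        # count intracellular pixels the same way .od_field does
        a <- truth$a_um[i]; b <- truth$b_um[i]; th <- truth$theta[i]
        cy <- truth$row_um[i]; cx <- truth$col_um[i]
        rr <- max(1L, floor((cy - a) / px)):min(spec$shape[1], ceiling((cy + a) / px))
        cc <- max(1L, floor((cx - a) / px)):min(spec$shape[2], ceiling((cx + a) / px))
        y <- (rr - 0.5) * px - cy
        x <- (cc - 0.5) * px - cx
        u <- outer(y, x, function(yy, xx) xx * cos(th) + yy * sin(th))
        v <- outer(y, x, function(yy, xx) -xx * sin(th) + yy * cos(th))
        sum((u / a)^2 + (v / b)^2 <= 1)
      }, numeric(1))
    }
    list(I = I, Imax = Imax, Imin = Imin, truth = truth)
  })
}

#' Draw a random non-overlapping cell layout
#'
#' Places `n` elliptical cells uniformly at random inside the image,
#' fully inside a margin and pairwise non-overlapping (bounding circles
#' including scattering rings plus a minimum gap), by rejection
#' sampling. Uses the ambient RNG stream; callers seed it.
#'
#' @param n Number of cells.
#' @param shape,pixel_size Image geometry (pixels, um/pixel).
#' @param radius_um Range of major semi-axis `a` (uniform draw).
#' @param aspect Range of the axis ratio `b/a` (uniform draw).
#' @param ring_width_um Scattering-ring width added to each bounding
#'   radius.
#' @param min_gap_um Minimum clearance between bounding circles.
#' @param max_attempts Rejection attempts per cell before failing with a
#'   generation error.
#' @return Tibble with `row_um`, `col_um`, `a_um`, `b_um`, `theta`.
#' @export
random_cell_layout <- function(n, shape, pixel_size, radius_um = c(6, 8),
                               aspect = c(0.85, 1), ring_width_um = 1,
                               min_gap_um = 3, max_attempts = 2000) {
  ext <- shape * pixel_size
  rows <- cols <- aa <- bb <- tt <- numeric(n)
  r_out <- numeric(n)
  for (i in seq_len(n)) {
    a <- runif(1, radius_um[1], radius_um[2])
    b <- a * runif(1, aspect[1], aspect[2])
    th <- runif(1, 0, pi)
    ri <- a + ring_width_um
    margin <- ri + 2 * pixel_size
    ok <- FALSE
    for (att in seq_len(max_attempts)) {
      cy <- runif(1, margin, ext[1] - margin)
      cx <- runif(1, margin, ext[2] - margin)
      if (i == 1 || all(sqrt((rows[seq_len(i - 1)] - cy)^2 +
                             (cols[seq_len(i - 1)] - cx)^2) >
                        r_out[seq_len(i - 1)] + ri + min_gap_um)) {
        ok <- TRUE
        break
      }
    }
    if (!ok)
      abort(sprintf("could not place cell %d of %d after %d attempts",
                    i, n, max_attempts),
            class = "absorbcell_generation")
    rows[i] <- cy; cols[i] <- cx; aa[i] <- a; bb[i] <- b; tt[i] <- th
    r_out[i] <- ri
  }
  tibble(row_um = rows, col_um = cols, a_um = aa, b_um = bb, theta = tt)
}

#' Generate a full synthetic experiment
#'
#' Emulates the standard treatment design for dye-exclusion viability
#' work: per treatment, four blank and four dark reference frames plus
#' `n_fields` sample fields of view. Live cells (`LD`, `LT`, and the
#' live half of `MIXTURE`) carry no intracellular dye, only a
#' scattering ring; dead cells draw their dye content from
#' `Normal(dead_moles_mean, dead_moles_sd)` truncated at zero; stained
#' treatments (`LT`, `DT`, `MIXTURE`) add a uniform medium absorbance.
#' `MIXTURE` fields are an exact 1:1 live:dead draw (half of each
#' field's cells dead).
#'
#' All randomness flows from `seed` through per-treatment, per-field
#' sub-seeds, so the whole experiment is reproducible.
#'
#' @param treatments Character vector of roles among `"LD"`, `"LT"`,
#'   `"DD"`, `"DT"`, `"MIXTURE"`.
#' @param seed Integer master seed.
#' @param shape,pixel_size,bit_depth,illumination_base,illumination_gradient,dark_level,read_noise_sd,shot_noise,epsilon
#'   Passed to [phantom_spec()].
#' @param n_fields,n_blank,n_dark Frames per treatment.
#' @param cells_per_field Cells per sample field (use an even number
#'   with `MIXTURE`).
#' @param medium_od Medium absorbance of the stained treatments.
#' @param dead_moles_mean,dead_moles_sd Dead-cell dye content (fmol),
#'   truncated at 0.
#' @param ring_fmol_mean,ring_fmol_sd Apparent per-cell dye content of
#'   the scattering ring (fmol, truncated at 0), drawn per cell and
#'   realized as the ring's OD amplitude over its annulus area. The
#'   default of 3.3 fmol is the apparent content of live stained cells
#'   after background subtraction reported for Jurkat-sized cells.
#' @param ring_width_um Scattering-ring width.
#' @param radius_um,aspect,min_gap_um Layout controls, see
#'   [random_cell_layout()].
#' @param sensitivity,r_min,r_max Segmentation parameters recorded on
#'   each dataset.
#' @return An object of class `"synthetic_experiment"`: list with
#'   `datasets` (named list of [treatment_dataset()]s), `truth` (named
#'   list of per-treatment truth tibbles with a `field` column),
#'   `model` (the [pixel_dose_model()]), and the generation settings.
#' @export
generate_experiment <- function(treatments = c("LD", "LT", "DD", "DT"),
                                seed = 1,
                                shape = c(320, 320), pixel_size = 1,
                                bit_depth = 16, illumination_base = 30000,
                                illumination_gradient = 0.05,
                                dark_level = 500, read_noise_sd = 60,
                                shot_noise = TRUE, epsilon = 2555,
                                n_fields = 10, n_blank = 4, n_dark = 4,
                                cells_per_field = 50, medium_od = 0.3,
                                dead_moles_mean = 20.6, dead_moles_sd = 3,
                                ring_fmol_mean = 3.3, ring_fmol_sd = 0.4,
                                ring_width_um = 1,
                                radius_um = c(6, 8), aspect = c(0.85, 1),
                                min_gap_um = 3,
                                sensitivity = 0.45, r_min = 4, r_max = 16) {
  treatments <- match.arg(treatments,
                          c("LD", "LT", "DD", "DT", "MIXTURE"),
                          several.ok = TRUE)
  model <- pixel_dose_model(epsilon, pixel_size)
  params <- segmentation_params(sensitivity = sensitivity,
                                r_min = r_min, r_max = r_max)
  base_spec <- function(cells, medium, sub_seed)
    phantom_spec(shape = shape, pixel_size = pixel_size,
                 bit_depth = bit_depth,
                 illumination_base = illumination_base,
                 illumination_gradient = illumination_gradient,
                 dark_level = dark_level, read_noise_sd = read_noise_sd,
                 shot_noise = shot_noise, medium_od = medium,
                 epsilon = epsilon, cells = cells, seed = sub_seed)
  datasets <- list()
  truth <- list()
  for (ti in seq_along(treatments)) {
    role <- treatments[ti]
    stained <- role %in% c("LT", "DT", "MIXTURE")
    medium <- if (stained) medium_od else 0
    sub <- function(k) (seed * 1000L + ti * 100L + k) %% .Machine$integer.max
    empty <- base_spec(NULL, 0, 0L)
    blanks <- lapply(seq_len(n_blank), function(k)
      .with_seed(sub(k), .render_frame(.illumination_field(empty), empty, "Imax")))
    darks <- lapply(seq_len(n_dark), function(k)
      .with_seed(sub(n_blank + k),
                 .render_frame(matrix(dark_level, shape[1], shape[2]),
                               empty, "Imin")))
    fields <- vector("list", n_fields)
    ttruth <- vector("list", n_fields)
    for (fi in seq_len(n_fields)) {
      fs <- sub(n_blank + n_dark + fi)
      cells <- .with_seed(fs, {
        lay <- random_cell_layout(cells_per_field, shape, pixel_size,
                                  radius_um = radius_um, aspect = aspect,
                                  ring_width_um = ring_width_um,
                                  min_gap_um = min_gap_um)
        n <- nrow(lay)
        dead <- switch(role,
          LD = rep(FALSE, n), LT = rep(FALSE, n),
          DD = rep(TRUE, n), DT = rep(TRUE, n),
          MIXTURE = seq_len(n) %in% sample.int(n, floor(n / 2)))
        lay$dead <- dead
        lay$moles_fmol <- ifelse(dead,
                                 pmax(0, rnorm(n, dead_moles_mean,
                                               dead_moles_sd)), 0)
        # per-cell scattering drawn as apparent fmol and realized
        # exactly over the discrete ring pixels (Normal in fmol, so the
        # live-reference peak fit is an unbiased offset estimate)
        lay$ring_fmol <- pmax(0, rnorm(n, ring_fmol_mean, ring_fmol_sd))
        lay$ring_od <- NA_real_
        lay$ring_width_um <- ring_width_um
        lay
      })
      spec <- base_spec(cells, medium, fs)
      fld <- generate_field(spec)
      fields[[fi]] <- list(I = fld$I, Imax = blanks, Imin = darks)
      ttruth[[fi]] <- dplyr::mutate(fld$truth, field = fi, .before = 1)
    }
    datasets[[role]] <- treatment_dataset(role, fields, params, model)
    truth[[role]] <- dplyr::bind_rows(ttruth)
  }
  structure(list(datasets = datasets, truth = truth, model = model,
                 params = params, seed = seed, epsilon = epsilon,
                 pixel_size = pixel_size),
            class = "synthetic_experiment")
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  cat(sprintf("<synthetic_experiment> seed %d, treatments: %s\n",
              x$seed, paste(names(x$datasets), collapse = ", ")))
  for (nm in names(x$datasets))
    cat(sprintf("  %s: %d field(s), %d cell(s)\n", nm,
                length(x$datasets[[nm]]$fields), nrow(x$truth[[nm]])))
  invisible(x)
}
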