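#' Fit the molar absorption coefficient from a calibration series
#'
#' The Beer-Lambert law, `A = epsilon * c * l`, links the absorbance `A`
#' of a dye solution to its concentration `c` and the optical path length
#' `l` through the wavelength-specific molar absorption coefficient
#' `epsilon`. Given a dilution series measured at one wavelength, each
#' record yields `epsilon_i = A_i / (c_i * l_i)`; the coefficient is
#' reported as the per-record mean with its sample standard deviation
#' (the field's conventional "mean +/- SD over dilutions"). A
#' slope-through-origin least-squares fit is available via
#' `method = "slope"`.
#'
#' Concentrations are supplied in mol/L and converted internally to
#' mol/m^3 with path lengths in metres, so epsilon carries m^2/mol.
#'
#' @param curve Data frame with columns `concentration_mol_per_L`,
#'   `absorbance` and `path_length_m` (one row per dilution), e.g. as
#'   read by [read_calibration_csv()].
#' @param wavelength Wavelength of the measurements in nm (metadata).
#' @param method `"mean"` (default): mean +/- SD of per-record epsilons;
#'   `"slope"`: least-squares slope of A on `c*l` through the origin.
#' @return An object of class `"epsilon_fit"`; see [tidy.epsilon_fit()]
#'   and [glance.epsilon_fit()].
#' @examples
#' curve <- data.frame(
#'   concentration_mol_per_L = c(10, 20, 40) * 1e-6,
#'   absorbance = 2600 * c(10, 20, 40) * 1e-6 * 1e3 * 0.01,
#'   path_length_m = 0.01
#' )
#' glance(fit_epsilon(curve))  # epsilon_mean 2600, epsilon_sd 0
#' @export
fit_epsilon <- function(curve, wavelength = 610, method = c("mean", "slope")) {
  method <- match.arg(method)
  curve <- as.data.frame(curve)
  need <- c("concentration_mol_per_L", "absorbance", "path_length_m")
  if (!all(need %in% names(curve)))
    .stop_input(paste("`curve` must have columns", paste(need, collapse = ", ")))
  if (nrow(curve) < 1) .stop_input("`curve` must have at least one record")
  c_molL <- curve$concentration_mol_per_L
  A <- curve$absorbance
  l <- curve$path_length_m
  if (any(c_molL <= 0)) .stop_input("all concentrations must be positive")
  if (any(l <= 0)) .stop_input("all path lengths must be positive")
  if (any(A < 0)) .stop_input("calibration absorbances must be non-negative")
  c_m3 <- c_molL * .const$mol_per_L_to_mol_per_m3
  eps_i <- A / (c_m3 * l)
  if (method == "mean") {
    eps_mean <- mean(eps_i)
    eps_sd <- if (length(eps_i) > 1) sd(eps_i) else 0
  } else {
    x <- c_m3 * l
    eps_mean <- sum(A * x) / sum(x^2)
    eps_sd <- if (length(x) > 1) {
      sqrt(sum((A - eps_mean * x)^2) / (length(x) - 1) / sum(x^2))
    } else 0
  }
  structure(
    list(records = tibble(
           concentration_mol_per_L = c_molL, absorbance = A,
           path_length_m = l, epsilon_m2_per_mol = eps_i),
         epsilon_mean = eps_mean, epsilon_sd = eps_sd,
         wavelength = wavelength, method = method),
    class = "epsilon_fit"
  )
}

#' @export
print.epsilon_fit <- function(x, ...) {
  cat(sprintf("<epsilon_fit> %d record(s) at %g nm (method: %s)\n",
              nrow(x$records), x$wavelength, x$method))
  cat(sprintf("  epsilon = %.0f +/- %.0f m^2/mol\n", x$epsilon_mean, x$epsilon_sd))
  invisible(x)
}

#' Tidy methods for epsilon fits
#'
#' `tidy()` returns one row per calibration record with its implied
#' epsilon; `glance()` returns the one-row fit summary.
#'
#' @param x An `"epsilon_fit"` from [fit_epsilon()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.epsilon_fit <- function(x, ...) x$records

#' @rdname tidy.epsilon_fit
#' @export
glance.epsilon_fit <- function(x, ...) {
  tibble(epsilon_mean = x$epsilon_mean, epsilon_sd = x$epsilon_sd,
         n_records = nrow(x$records), wavelength = x$wavelength,
         method = x$method)
}

#' Per-pixel dose model
#'
#' Couples a fitted molar absorption coefficient to a pixel size so that
#' a pixel's absorbance can be converted to moles of dye in the light
#' path through that pixel.
#'
#' @param epsilon Molar absorption coefficient in m^2/mol (> 0).
#' @param pixel_size Isotropic pixel size in micrometres (> 0).
#' @return An object of class `"pixel_dose_model"`.
#' @examples
#' pixel_dose_model(2500, pixel_size = 1)
#' @export
pixel_dose_model <- function(epsilon, pixel_size) {
  if (!is.numeric(epsilon) || length(epsilon) != 1 || epsilon <= 0)
    .stop_input("`epsilon` must be a single positive number (m^2/mol)")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0)
    .stop_input("`pixel_size` must be a single positive number (um)")
  structure(list(epsilon = epsilon, pixel_size = pixel_size),
            class = "pixel_dose_model")
}

#' @export
print.pixel_dose_model <- function(x, ...) {
  cat(sprintf("<pixel_dose_model> epsilon=%g m^2/mol, pixel_size=%g um\n",
              x$epsilon, x$pixel_size))
  invisible(x)
}

#' Moles of dye behind a pixel (or summed region) of given absorbance
#'
#' Inverts the Beer-Lambert law for an imaging geometry: the amount of
#' dye in the column of solution imaged by one pixel is
#' `moles = A * pixel_area / epsilon`, with the pixel area in m^2. The
#' relation is linear, so it applies equally to a summed absorbance over
#' a segmented object. Negative absorbances yield negative moles, which
#' are retained -- the downstream correction strategies rely on the noise
#' staying symmetric.
#'
#' @param A Absorbance (OD), scalar or vector; a summed OD*pixels value
#'   is valid input.
#' @param model A [pixel_dose_model()].
#' @return Moles of dye (mol), same length as `A`.
#' @examples
#' pixel_moles(1, pixel_dose_model(2500, 1))  # 4e-16 mol = 0.4 fmol
#' @export
pixel_moles <- function(A, model) {
  if (!inherits(model, "pixel_dose_model"))
    .stop_input("`model` must be a pixel_dose_model")
  if (any(!is.finite(A))) .stop_input("`A` must be finite")
  area_m2 <- (model$pixel_size * .const$um_to_m)^2
  A * area_m2 / model$epsilon
}

#' Concentration after a parts-based dilution
#'
#' Staining protocols state dilutions as volume parts, e.g. dye stock
#' added to a cell suspension "at a 1:4 ratio". The final concentration
#' is `stock * parts_stock / (parts_stock + parts_diluent)`.
#'
#' @param stock Stock concentration (any concentration unit; mol/L here).
#' @param parts_stock,parts_diluent Non-negative volume parts; their sum
#'   must be positive.
#' @return Final concentration in the unit of `stock`.
#' @examples
#' dilution_concentration(4.163e-3, 1, 4)  # 0.833 mmol/L staining level
#' @export
dilution_concentration <- function(stock, parts_stock, parts_diluent) {
  if (parts_stock < 0 || parts_diluent < 0)
    .stop_input("parts must be non-negative")
  if (parts_stock + parts_diluent <= 0)
    .stop_input("at least one part must be positive")
  stock * parts_stock / (parts_stock + parts_diluent)
}

#' Symmetric percent difference between two values
#'
#' `100 * |x - y| / mean(x, y)` -- the symmetric convention with the mean
#' of the two values in the denominator, used when comparing paired
#' measurements (e.g. the same sample on two instruments) where neither
#' value is the reference.
#'
#' @param x,y Numbers whose mean is non-zero.
#' @return Percent difference (symmetric in `x` and `y`).
#' @examples
#' percent_difference(20.6, 21.4)  # 3.8
#' @export
percent_difference <- function(x, y) {
  m <- (x + y) / 2
  if (!is.finite(m) || m == 0)
    .stop_input("mean of `x` and `y` must be non-zero and finite")
  100 * abs(x - y) / abs(m)
}

#' Intracellular molarity from moles and cell volume
#'
#' @param moles Moles of dye in the cell (mol).
#' @param volume Cell volume in litres (> 0).
#' @return Concentration in mol/L.
#' @examples
#' cell_molarity(20.6e-15, 1.39e-12) * 1e3  # ~14.8 mmol/L
#' @export
cell_molarity <- function(moles, volume) {
  if (any(!is.finite(volume)) || any(volume <= 0))
    .stop_input("`volume` must be positive")
  moles / volume
}

#' Read or write a calibration table as CSV
#'
#' The on-disk format is a plain CSV with header
#' `concentration_mol_per_L,absorbance,path_length_m`.
#'
#' @param path File path.
#' @return `read_calibration_csv()` returns a tibble with those columns.
#' @export
read_calibration_csv <- function(path) {
  df <- read.csv(path, check.names = TRUE)
  need <- c("concentration_mol_per_L", "absorbance", "path_length_m")
  if (!all(need %in% names(df)))
    .stop_input(paste("calibration CSV must have columns",
                      paste(need, collapse = ", ")))
  as_tibble(df[need])
}

#' @param curve Data frame with the three calibration columns.
#' @rdname read_calibration_csv
#' @export
write_calibration_csv <- function(curve, path) {
  need <- c("concentration_mol_per_L", "absorbance", "path_length_m")
  write.csv(as.data.frame(curve)[need], path, row.names = FALSE)
  invisible(path)
}
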