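#' Intensity and absorbance image containers
#'
#' An `intensity_image` holds raw camera counts from a single-channel
#' brightfield micrograph together with the acquisition metadata the
#' downstream quantification needs: the camera bit depth, the isotropic
#' pixel size in micrometres, and the role the frame plays in an
#' absorbance triplet -- the sample frame `"I"`, the open-shutter blank
#' reference `"Imax"`, or the closed-shutter dark reference `"Imin"`.
#'
#' An `absorbance_image` holds per-pixel optical density (dimensionless
#' absorbance, base-10) at a stated wavelength, plus the cap applied to
#' opaque pixels.
#'
#' @param pixels Numeric matrix of camera counts (rows x columns). Counts
#'   must be finite, non-negative and at most `2^bit_depth - 1`. Averaged
#'   references may carry non-integer counts.
#' @param bit_depth Camera bit depth, 8 or 16.
#' @param pixel_size Isotropic pixel size in micrometres (> 0).
#' @param role One of `"I"`, `"Imax"`, `"Imin"`.
#' @return `intensity_image()` returns an object of class
#'   `"intensity_image"`; `absorbance_image()` an object of class
#'   `"absorbance_image"`. Both are lists wrapping the pixel matrix and
#'   metadata.
#' @examples
#' img <- intensity_image(matrix(1000, 8, 8), bit_depth = 16, pixel_size = 0.5)
#' dim(img$pixels)
#' @export
intensity_image <- function(pixels, bit_depth = 16, pixel_size = 1,
                            role = c("I", "Imax", "Imin")) {
  role <- match.arg(role)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    .stop_input("`pixels` must be a numeric matrix")
  if (!bit_depth %in% c(8, 16))
    .stop_input("`bit_depth` must be 8 or 16")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0)
    .stop_input("`pixel_size` must be a single positive number (um/pixel)")
  if (anyNA(pixels) || any(!is.finite(pixels)))
    .stop_input("intensity pixels must all be finite")
  top <- 2^bit_depth - 1
  if (any(pixels < 0) || any(pixels > top))
    .stop_input(sprintf("intensity pixels must lie in [0, %d] for bit depth %d",
                        top, bit_depth))
  storage.mode(pixels) <- "double"
  structure(
    list(pixels = pixels, bit_depth = as.integer(bit_depth),
         pixel_size = pixel_size, role = role),
    class = "intensity_image"
  )
}

#' @param wavelength Wavelength in nm at which the absorbance was measured.
#' @param cap Maximum representable absorbance (OD) in the image.
#' @rdname intensity_image
#' @export
absorbance_image <- function(pixels, pixel_size = 1, wavelength = 610,
                             cap = 4) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    .stop_input("`pixels` must be a numeric matrix")
  if (anyNA(pixels) || any(!is.finite(pixels)))
    .stop_input("absorbance pixels must all be finite")
  if (cap <= 0) .stop_input("`cap` must be positive")
  if (any(pixels > cap + 1e-12))
    .stop_input("absorbance pixels must not exceed `cap`")
  if (pixel_size <= 0) .stop_input("`pixel_size` must be positive")
  structure(
    list(pixels = pixels, pixel_size = pixel_size,
         wavelength = wavelength, cap = cap),
    class = "absorbance_image"
  )
}

#' @export
print.intensity_image <- function(x, ...) {
  cat(sprintf("<intensity_image [%d x %d]> role=%s bit_depth=%d pixel_size=%g um\n",
              nrow(x$pixels), ncol(x$pixels), x$role, x$bit_depth, x$pixel_size))
  cat(sprintf("  counts: min %.1f, mean %.1f, max %.1f\n",
              min(x$pixels), mean(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
print.absorbance_image <- function(x, ...) {
  cat(sprintf("<absorbance_image [%d x %d]> wavelength=%g nm pixel_size=%g um cap=%g OD\n",
              nrow(x$pixels), ncol(x$pixels), x$wavelength, x$pixel_size, x$cap))
  cat(sprintf("  OD: min %.4f, mean %.4f, max %.4f\n",
              min(x$pixels), mean(x$pixels), max(x$pixels)))
  invisible(x)
}

.check_same_grid <- function(a, b, what = "images") {
  if (!identical(dim(a$pixels), dim(b$pixels)))
    .stop_input(sprintf("%s must share the same grid shape", what))
}

#' Average replicate reference frames
#'
#' Reference frames (blank `Imax` and dark `Imin`) are usually captured
#' several times; averaging them before conversion reduces read noise in
#' the reference without touching the sample frame. The average is kept in
#' floating point -- it is not re-quantized to integer counts.
#'
#' @param images List of [intensity_image()] objects sharing shape, bit
#'   depth, pixel size and role.
#' @return A single [intensity_image()] with the per-pixel arithmetic mean.
#' @examples
#' imgs <- lapply(c(100, 200, 300, 400), function(v)
#'   intensity_image(matrix(v, 4, 4), role = "Imax"))
#' average_reference_images(imgs)$pixels[1, 1]  # 250
#' @export
average_reference_images <- function(images) {
  if (!is.list(images) || length(images) == 0)
    .stop_input("`images` must be a non-empty list of intensity images")
  if (!all(vapply(images, inherits, logical(1), "intensity_image")))
    .stop_input("all elements must be intensity_image objects")
  ref <- images[[1]]
  for (img in images[-1]) {
    .check_same_grid(ref, img)
    if (img$bit_depth != ref$bit_depth)
      .stop_input("all images must share the same bit depth")
    if (img$pixel_size != ref$pixel_size)
      .stop_input("all images must share the same pixel size")
    if (img$role != ref$role)
      .stop_input("all images must share the same role")
  }
  acc <- Reduce(`+`, lapply(images, function(i) i$pixels)) / length(images)
  out <- ref
  out$pixels <- acc
  out
}

#' Convert a brightfield triplet to an absorbance image
#'
#' Per-pixel conversion of raw counts to base-10 absorbance (optical
#' density) relative to the blank and dark references:
#' `A = -log10((I - Imin) / (Imax - Imin))`. Pixels whose transmittance
#' ratio falls at or below `10^-cap` (including `I <= Imin`) are assigned
#' the cap -- they are opaque beyond the measurable dynamic range. Pixels
#' brighter than the blank (`I > Imax`, noise) yield small negative
#' absorbances which are deliberately retained, so that background fitting
#' sees a symmetric noise distribution around zero.
#'
#' @param I Sample [intensity_image()].
#' @param Imax Blank (open-shutter) reference image, typically the average
#'   of several frames (see [average_reference_images()]).
#' @param Imin Dark (closed-shutter) reference image.
#' @param cap Maximum absorbance to report (OD), default 4.
#' @param wavelength Wavelength in nm recorded on the output, default 610
#'   (near the trypan blue absorption peak).
#' @return An [absorbance_image()] with the same grid shape as `I`.
#' @examples
#' I    <- intensity_image(matrix(1000, 4, 4))
#' Imax <- intensity_image(matrix(10000, 4, 4), role = "Imax")
#' Imin <- intensity_image(matrix(0, 4, 4), role = "Imin")
#' to_absorbance(I, Imax, Imin)$pixels[1, 1]  # -log10(0.1) = 1
#' @export
to_absorbance <- function(I, Imax, Imin, cap = 4, wavelength = 610) {
  for (obj in list(I, Imax, Imin))
    if (!inherits(obj, "intensity_image"))
      .stop_input("I, Imax and Imin must be intensity_image objects")
  .check_same_grid(I, Imax)
  .check_same_grid(I, Imin)
  if (!is.numeric(cap) || length(cap) != 1 || cap <= 0)
    .stop_input("`cap` must be a single positive number")
  denom <- Imax$pixels - Imin$pixels
  n_bad <- sum(denom <= 0)
  if (n_bad > 0)
    abort(sprintf(
      "degenerate reference pair: Imax <= Imin at %d pixel(s)", n_bad),
      class = "absorbcell_degenerate_reference")
  ratio <- (I$pixels - Imin$pixels) / denom
  A <- matrix(cap, nrow(ratio), ncol(ratio))
  ok <- ratio > 10^(-cap)
  A[ok] <- -log10(ratio[ok])
  absorbance_image(A, pixel_size = I$pixel_size,
                   wavelength = wavelength, cap = cap)
}

#' Exposure sanity report for an intensity image
#'
#' Quantitative imaging requires counts inside the camera's linear range:
#' clipped (zero) or saturated pixels carry no absorbance information.
#' This reports the fraction of pixels at zero, at the top count for the
#' image's bit depth, and within `saturation_margin` of the top, and flags
#' the image when more than 0.1 % of pixels are saturated or at zero.
#'
#' @param img An [intensity_image()].
#' @param saturation_margin Fraction of full scale counted as "near
#'   saturation" (default 0.02).
#' @return A one-row tibble with columns `zero_fraction`, `top_fraction`,
#'   `near_top_fraction`, `flagged`.
#' @examples
#' check_exposure(intensity_image(matrix(128, 8, 8), bit_depth = 8))
#' @export
check_exposure <- function(img, saturation_margin = 0.02) {
  if (!inherits(img, "intensity_image"))
    .stop_input("`img` must be an intensity_image")
  top <- 2^img$bit_depth - 1
  px <- img$pixels
  n <- length(px)
  zero_fraction <- sum(px <= 0) / n
  top_fraction <- sum(px >= top) / n
  near_top_fraction <- sum(px >= top * (1 - saturation_margin)) / n
  tibble(
    zero_fraction = zero_fraction,
    top_fraction = top_fraction,
    near_top_fraction = near_top_fraction,
    flagged = top_fraction > 0.001 || zero_fraction > 0.001
  )
}
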