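#' Read a single-channel brightfield TIFF as an intensity image
#'
#' Accepts single-plane 8- or 16-bit grayscale TIFFs; color images are
#' accepted only when `channel` names the channel to extract (the red
#' channel matches a 610 nm bandpass). Multi-plane and floating-point
#' TIFFs are rejected. Counts are read as-is (no rescaling); the bit
#' depth is inferred from the file's sample format. The pixel size
#' comes from the caller (the manifest); TIFF resolution tags, when
#' present, are used only as a cross-check that warns on disagreement.
#'
#' @param path TIFF file path.
#' @param pixel_size Micrometres per pixel (from the experiment
#'   manifest).
#' @param role Frame role: `"I"`, `"Imax"` or `"Imin"`.
#' @param channel For color input, one of `"red"`, `"green"`, `"blue"`.
#' @return An [intensity_image()].
#' @export
load_intensity_image <- function(path, pixel_size = 1,
                                 role = c("I", "Imax", "Imin"),
                                 channel = NULL) {
  role <- match.arg(role)
  planes <- tryCatch(
    tiff::readTIFF(path, as.is = TRUE, info = TRUE, all = TRUE),
    error = function(e) abort(
      sprintf("unsupported TIFF format in '%s': %s", path, conditionMessage(e)),
      class = "absorbcell_unsupported_format"))
  if (length(planes) != 1)
    abort(sprintf("'%s' has %d planes; only single-plane TIFFs are supported",
                  path, length(planes)),
          class = "absorbcell_unsupported_format")
  x <- planes[[1]]
  bits <- attr(x, "bits.per.sample")
  fmt <- attr(x, "sample.format")
  if (!is.null(fmt) && identical(fmt, "float"))
    abort(sprintf("'%s' is a floating-point TIFF; intensity input must be integer counts", path),
          class = "absorbcell_unsupported_format")
  if (is.null(bits) || !bits %in% c(8, 16))
    abort(sprintf("'%s' is %s-bit; only 8- and 16-bit input is supported",
                  path, bits %||% "unknown"),
          class = "absorbcell_unsupported_format")
  if (length(dim(x)) == 3) {
    if (is.null(channel))
      abort(sprintf("'%s' is a color image; pass `channel` to extract one channel", path),
            class = "absorbcell_unsupported_format")
    idx <- match(match.arg(channel, c("red", "green", "blue")),
                 c("red", "green", "blue"))
    if (dim(x)[3] < idx)
      abort(sprintf("'%s' has no %s channel", path, channel),
            class = "absorbcell_unsupported_format")
    x <- x[, , idx]
  }
  xres <- attr(x, "x.resolution")
  unit <- attr(x, "resolution.unit")
  if (!is.null(xres) && is.finite(xres) && xres > 0 && !is.null(unit)) {
    um_per_px <- switch(unit, inch = 25400 / xres, cm = 1e4 / xres, NA_real_)
    if (is.finite(um_per_px) &&
        abs(um_per_px - pixel_size) / pixel_size > 0.02)
      warn(sprintf(
        "'%s': TIFF resolution tags imply %.3g um/pixel but the manifest says %.3g",
        path, um_per_px, pixel_size))
  }
  intensity_image(matrix(as.numeric(x), nrow(x), ncol(x)),
                  bit_depth = bits, pixel_size = pixel_size, role = role)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write images and cell tables to disk
#'
#' `write_intensity_tiff()` stores integer counts as 8- or 16-bit
#' grayscale TIFF (round-tripping bit-identically through
#' [load_intensity_image()]); `write_absorbance_tiff()` stores
#' absorbance as uncompressed 32-bit IEEE-float grayscale TIFF
#' (absorbance can be negative, which fixed-point TIFF cannot carry);
#' `read_absorbance_tiff()` reads such a file back;
#' `write_cell_table()` writes a per-cell CSV with the standard columns
#' `label,area_um2,feret_max_um,feret_min_um,sum_absorbance,volume_pL,moles_fmol,molarity_mmol_per_L`
#' (plus any extra columns present).
#'
#' @param img Image object of the matching class.
#' @param path Output path.
#' @return The path, invisibly (writers); an [absorbance_image()]
#'   (reader).
#' @export
write_intensity_tiff <- function(img, path) {
  if (!inherits(img, "intensity_image"))
    .stop_input("`img` must be an intensity_image")
  top <- 2^img$bit_depth - 1
  tiff::writeTIFF(round(img$pixels) / top, path,
                  bits.per.sample = img$bit_depth, compression = "none")
  invisible(path)
}

#' @rdname write_intensity_tiff
#' @export
write_absorbance_tiff <- function(img, path) {
  if (!inherits(img, "absorbance_image"))
    .stop_input("`img` must be an absorbance_image")
  .write_float_tiff(img$pixels, path)
  invisible(path)
}

#' @param pixel_size,wavelength,cap Metadata to attach on read (not
#'   stored in the TIFF).
#' @rdname write_intensity_tiff
#' @export
read_absorbance_tiff <- function(path, pixel_size = 1, wavelength = 610,
                                 cap = 4) {
  x <- tiff::readTIFF(path)
  absorbance_image(matrix(as.numeric(x), nrow(x), ncol(x)),
                   pixel_size = pixel_size, wavelength = wavelength,
                   cap = max(cap, max(x)))
}

# Minimal uncompressed little-endian grayscale float32 TIFF writer
# (single strip, SampleFormat = IEEE float). Written by hand because
# absorbance values include negatives, which [0,1] fixed-point TIFF
# writers cannot represent.
.write_float_tiff <- function(m, path) {
  nr <- nrow(m); nc <- ncol(m)
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 4L * nr * nc
  ifd_offset <- 8L + data_bytes
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(ifd_offset, con, size = 4, endian = "little")
  writeBin(as.numeric(t(m)), con, size = 4, endian = "little")
  entries <- list(
    c(256L, 3L, 1L, nc),          # ImageWidth
    c(257L, 3L, 1L, nr),          # ImageLength
    c(258L, 3L, 1L, 32L),         # BitsPerSample
    c(259L, 3L, 1L, 1L),          # Compression: none
    c(262L, 3L, 1L, 1L),          # Photometric: black is zero
    c(273L, 4L, 1L, 8L),          # StripOffsets
    c(277L, 3L, 1L, 1L),          # SamplesPerPixel
    c(278L, 3L, 1L, nr),          # RowsPerStrip
    c(279L, 4L, 1L, data_bytes),  # StripByteCounts
    c(339L, 3L, 1L, 3L))          # SampleFormat: IEEE float
  writeBin(length(entries), con, size = 2, endian = "little")
  for (e in entries) {
    writeBin(e[1], con, size = 2, endian = "little")
    writeBin(e[2], con, size = 2, endian = "little")
    writeBin(e[3], con, size = 4, endian = "little")
    if (e[2] == 3L) {
      writeBin(e[4], con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(e[4], con, size = 4, endian = "little")
    }
  }
  writeBin(0L, con, size = 4, endian = "little")
}

#' @param cells Per-cell tibble from [measure_cells()] or
#'   [run_strategy()].
#' @rdname write_intensity_tiff
#' @export
write_cell_table <- function(cells, path) {
  lead <- c("label", "area_um2", "feret_max_um", "feret_min_um",
            "sum_absorbance", "volume_pL", "moles_fmol",
            "molarity_mmol_per_L")
  cols <- c(intersect(lead, names(cells)),
            setdiff(names(cells), lead))
  write.csv(as.data.frame(cells)[cols], path, row.names = FALSE)
  invisible(path)
}

#' Read or write an experiment manifest
#'
#' The manifest is a YAML (or JSON) document describing one experiment:
#' global settings `pixel_size` (um), `wavelength` (nm), exactly one
#' epsilon source (`epsilon` in m^2/mol, or `calibration_csv` pointing
#' to a calibration table), `cap`, `strategy` (1-3), a `segmentation`
#' block (`sensitivity`, `r_min`, `r_max`), and a `treatments` list in
#' which each entry has a `role` and `sample`, `blank`, `dark` path
#' lists. Relative paths are resolved against the manifest's directory.
#'
#' @param path Manifest file (`.yaml`/`.yml` or `.json`).
#' @return A list with the manifest contents; paths resolved.
#' @export
read_manifest <- function(path) {
  m <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  base <- dirname(normalizePath(path))
  fix <- function(p) {
    p <- as.character(p)
    ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  }
  m$treatments <- lapply(m$treatments, function(t) {
    for (k in c("sample", "blank", "dark"))
      if (!is.null(t[[k]])) t[[k]] <- fix(unlist(t[[k]]))
    t
  })
  if (!is.null(m$calibration_csv)) m$calibration_csv <- fix(m$calibration_csv)
  .validate_manifest(m)
  m
}

.validate_manifest <- function(m) {
  if (is.null(m$treatments) || length(m$treatments) == 0)
    .stop_input("manifest must list at least one treatment")
  if (is.null(m$pixel_size) || m$pixel_size <= 0)
    .stop_input("manifest must state a positive pixel_size (um)")
  has_eps <- !is.null(m$epsilon)
  has_cal <- !is.null(m$calibration_csv)
  if (has_eps == has_cal)
    .stop_input("manifest must provide exactly one of `epsilon` or `calibration_csv`")
  for (t in m$treatments) {
    if (is.null(t$role)) .stop_input("every treatment needs a `role`")
    for (k in c("sample", "blank", "dark")) {
      if (is.null(t[[k]]) || length(t[[k]]) == 0)
        .stop_input(sprintf("treatment %s: missing `%s` image list", t$role, k))
      missing_f <- t[[k]][!file.exists(t[[k]])]
      if (length(missing_f) > 0)
        .stop_input(sprintf("treatment %s: missing file(s): %s", t$role,
                            paste(missing_f, collapse = ", ")))
    }
  }
  invisible(m)
}
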