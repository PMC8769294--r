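#' Segmentation parameters
#'
#' Controls for turning an absorbance image into labeled cell objects:
#' a locally adaptive threshold produces a binary image, 8-connected
#' components are extracted, and objects are kept when their
#' equivalent-circle radius lies in `[r_min, r_max]`.
#'
#' The adaptive threshold is Bradley-style: a pixel is foreground when
#' its absorbance exceeds the local mean over a square window (window
#' side = odd integer nearest 1/8 of the smaller image dimension) plus
#' `k` times the global absorbance range, with `k = 1 - 2*sensitivity`.
#' At the default `sensitivity = 0.5` this reduces to a plain local-mean
#' comparison; lower sensitivities demand more contrast and suppress
#' noise speckle, higher ones admit fainter objects. The sensitivity is
#' deliberately a per-image knob: optimal values vary with staining and
#' illumination.
#'
#' @param sensitivity Threshold sensitivity in \[0, 1\] (default 0.5).
#' @param r_min,r_max Equivalent-circle radius bounds in micrometres
#'   (defaults 4 and 16, the radius range of Jurkat-sized cells).
#' @param exclude_border Drop objects touching the image border (default
#'   `TRUE`; partial cells bias volume and moles).
#' @param fill_holes Fill enclosed holes before labeling (default `TRUE`;
#'   unstained live cells image as scattering rings that must be closed
#'   into disks before area and Feret measurement).
#' @return An object of class `"segmentation_params"`.
#' @examples
#' segmentation_params(sensitivity = 0.4)
#' @export
segmentation_params <- function(sensitivity = 0.5, r_min = 4, r_max = 16,
                                exclude_border = TRUE, fill_holes = TRUE) {
  if (!is.numeric(sensitivity) || sensitivity < 0 || sensitivity > 1)
    .stop_input("`sensitivity` must lie in [0, 1]")
  if (r_min <= 0 || r_max <= r_min)
    .stop_input("need 0 < r_min < r_max")
  structure(list(sensitivity = sensitivity, r_min = r_min, r_max = r_max,
                 connectivity = 8L, exclude_border = isTRUE(exclude_border),
                 fill_holes = isTRUE(fill_holes)),
            class = "segmentation_params")
}

#' @export
print.segmentation_params <- function(x, ...) {
  cat(sprintf(
    "<segmentation_params> sensitivity=%g, r=[%g, %g] um, 8-connected, border=%s, fill_holes=%s\n",
    x$sensitivity, x$r_min, x$r_max,
    if (x$exclude_border) "excluded" else "kept", x$fill_holes))
  invisible(x)
}

# Mean over a w x w window clipped to the image, via an integral image.
.local_mean <- function(m, w) {
  nr <- nrow(m); nc <- ncol(m)
  half <- w %/% 2
  S <- matrix(0, nr + 1, nc + 1)
  S[-1, -1] <- apply(apply(m, 2, cumsum), 1, cumsum) |> t()
  r1 <- pmax(1, seq_len(nr) - half); r2 <- pmin(nr, seq_len(nr) + half)
  c1 <- pmax(1, seq_len(nc) - half); c2 <- pmin(nc, seq_len(nc) + half)
  R1 <- rep(r1, times = nc); R2 <- rep(r2, times = nc)
  C1 <- rep(c1, each = nr); C2 <- rep(c2, each = nr)
  tot <- S[cbind(R2 + 1, C2 + 1)] - S[cbind(R1, C2 + 1)] -
    S[cbind(R2 + 1, C1)] + S[cbind(R1, C1)]
  cnt <- (R2 - R1 + 1) * (C2 - C1 + 1)
  matrix(tot / cnt, nr, nc)
}

#' Segment cells in an absorbance image
#'
#' Applies the adaptive threshold described in [segmentation_params()],
#' optionally fills holes, labels 8-connected components, applies the
#' equivalent-circle-radius size filter, and optionally removes
#' border-touching objects. Surviving objects are relabeled 1..n in
#' raster-scan order, so labeling is deterministic.
#'
#' @param img An [absorbance_image()].
#' @param params A [segmentation_params()].
#' @return An object of class `"cell_labels"`: a list with the integer
#'   label matrix `labels`, object count `n`, `pixel_size`, and the
#'   `params` used.
#' @export
segment_cells <- function(img, params = segmentation_params()) {
  if (!inherits(img, "absorbance_image"))
    .stop_input("`img` must be an absorbance_image")
  if (!inherits(params, "segmentation_params"))
    .stop_input("`params` must be segmentation_params")
  A <- img$pixels
  nr <- nrow(A); nc <- ncol(A)
  w <- floor(min(nr, nc) / 8)
  w <- max(3L, as.integer(if (w %% 2 == 0) w + 1 else w))
  if (w > min(nr, nc))
    .stop_input("adaptive-threshold window larger than the image")
  k <- 1 - 2 * params$sensitivity
  thr <- .local_mean(A, w) + k * (max(A) - min(A))
  # strict comparison with a numerical guard: the integral-image mean of a
  # constant region differs from the pixel value by rounding error only
  eps <- 1e-9 * max(1, abs(max(A)), abs(min(A)))
  fg <- A > thr + eps
  if (params$fill_holes) fg <- fill_holes_cpp(fg)
  lab <- label_components_cpp(fg, params$connectivity)
  n0 <- max(lab)
  keep <- integer(0)
  if (n0 > 0) {
    area_px <- tabulate(lab[lab > 0L], nbins = n0)
    r_eq <- sqrt(area_px * img$pixel_size^2 / pi)
    ok <- r_eq >= params$r_min & r_eq <= params$r_max
    if (params$exclude_border) {
      border_labels <- unique(c(lab[1, ], lab[nr, ], lab[, 1], lab[, nc]))
      ok[border_labels[border_labels > 0L]] <- FALSE
    }
    keep <- which(ok)
  }
  relab <- integer(n0 + 1L)            # old label -> new label (0 stays 0)
  relab[keep + 1L] <- seq_along(keep)
  out <- matrix(relab[lab + 1L], nr, nc)
  structure(list(labels = out, n = length(keep),
                 pixel_size = img$pixel_size, params = params),
            class = "cell_labels")
}

#' @export
print.cell_labels <- function(x, ...) {
  cat(sprintf("<cell_labels [%d x %d]> %d object(s), pixel_size=%g um\n",
              nrow(x$labels), ncol(x$labels), x$n, x$pixel_size))
  invisible(x)
}

#' Volume of an ellipsoid from Feret diameters
#'
#' A suspended cell is modeled as a prolate spheroid: semi-axis `a` is
#' half the maximum Feret diameter and the two equatorial semi-axes
#' `b = c` are half the minimum Feret diameter. The volume
#' `(4/3) * pi * a * b * c` is returned in litres.
#'
#' @param feret_max,feret_min Maximum and minimum Feret diameters in
#'   micrometres; both positive, `feret_min <= feret_max`.
#' @return Volume in litres.
#' @examples
#' ellipsoid_volume(10, 10)  # sphere, 5.236e-13 L (~0.524 pL)
#' @export
ellipsoid_volume <- function(feret_max, feret_min) {
  if (any(!is.finite(feret_max)) || any(!is.finite(feret_min)) ||
      any(feret_max <= 0) || any(feret_min <= 0))
    .stop_input("Feret diameters must be positive")
  if (any(feret_min > feret_max + 1e-9))
    .stop_input("feret_min must not exceed feret_max")
  a <- feret_max / 2
  b <- feret_min / 2
  (4 / 3) * pi * a * b * b * .const$um3_to_L
}

# Feret diameters of one object by rotating calipers over the convex
# hull of its pixel-corner coordinates (corners, not centers, so a
# single pixel has feret = pixel_size rather than 0).
.feret_diameters <- function(rows, cols, pixel_size) {
  # corners of pixel (r, c) with 0-based convention: (r-1, c-1) .. (r, c);
  # chull tolerates duplicate corner points, so no dedup needed
  pr <- c(rows - 1, rows, rows - 1, rows)
  pc <- c(cols - 1, cols - 1, cols, cols)
  pts <- cbind(pr, pc) * pixel_size
  h <- grDevices::chull(pts[, 1], pts[, 2])
  hp <- pts[h, , drop = FALSE]
  m <- nrow(hp)
  if (m == 1) return(c(feret_max = 0, feret_min = 0))
  d2 <- outer(hp[, 1], hp[, 1], "-")^2 + outer(hp[, 2], hp[, 2], "-")^2
  fmax <- sqrt(max(d2))
  # min width: for each hull edge, the max distance of hull points from
  # the edge's supporting line
  fmin <- Inf
  for (i in seq_len(m)) {
    j <- if (i == m) 1L else i + 1L
    e <- hp[j, ] - hp[i, ]
    len <- sqrt(sum(e^2))
    if (len == 0) next
    nrm <- c(-e[2], e[1]) / len
    proj <- (hp[, 1] - hp[i, 1]) * nrm[1] + (hp[, 2] - hp[i, 2]) * nrm[2]
    fmin <- min(fmin, max(proj) - min(proj))
  }
  if (!is.finite(fmin)) fmin <- fmax
  c(feret_max = fmax, feret_min = fmin)
}

#' Measure geometry and dye content of segmented cells
#'
#' For every labeled object: pixel count and area in um^2, minimum and
#' maximum Feret diameters (rotating calipers over the convex hull of
#' pixel corners), summed absorbance (OD*pixels), moles of dye via
#' [pixel_moles()], ellipsoid volume via [ellipsoid_volume()], and
#' molarity = moles/volume. Output units follow the field's reporting
#' conventions: um^2, um, pL, fmol, mmol/L.
#'
#' @param labels A [segment_cells()] result (or a bare integer label
#'   matrix, in which case `img`'s pixel size is used).
#' @param img The [absorbance_image()] the labels were derived from
#'   (same shape).
#' @param model A [pixel_dose_model()].
#' @param which Optional integer vector of label ids to measure; ids not
#'   present in the label image are skipped with a warning. Default: all
#'   labels present.
#' @return A tibble with one row per object: `label`, `area_px`,
#'   `area_um2`, `feret_max_um`, `feret_min_um`, `sum_absorbance`,
#'   `volume_pL`, `moles_fmol`, `molarity_mmol_per_L`.
#' @export
measure_cells <- function(labels, img, model, which = NULL) {
  if (inherits(labels, "cell_labels")) labels <- labels$labels
  if (!inherits(img, "absorbance_image"))
    .stop_input("`img` must be an absorbance_image")
  if (!inherits(model, "pixel_dose_model"))
    .stop_input("`model` must be a pixel_dose_model")
  if (!identical(dim(labels), dim(img$pixels)))
    .stop_input("labels and image must share the same shape")
  px <- img$pixel_size
  present <- sort(unique(labels[labels > 0L]))
  ids <- if (is.null(which)) present else {
    missing_ids <- setdiff(which, present)
    if (length(missing_ids) > 0)
      warn(sprintf("label(s) %s absent from the image; skipped",
                   paste(missing_ids, collapse = ", ")))
    intersect(which, present)
  }
  empty <- tibble(label = integer(), area_px = integer(), area_um2 = double(),
                  feret_max_um = double(), feret_min_um = double(),
                  sum_absorbance = double(), volume_pL = double(),
                  moles_fmol = double(), molarity_mmol_per_L = double())
  if (length(ids) == 0) return(empty)
  idx <- which(labels > 0L)
  lab_v <- labels[idx]
  ord <- order(lab_v)
  idx <- idx[ord]; lab_v <- lab_v[ord]
  nr <- nrow(labels)
  rows_all <- ((idx - 1L) %% nr) + 1L
  cols_all <- ((idx - 1L) %/% nr) + 1L
  A_all <- img$pixels[idx]
  grp <- split(seq_along(idx), lab_v)
  out <- purrr::map(as.character(ids), function(id) {
    g <- grp[[id]]
    fer <- .feret_diameters(rows_all[g], cols_all[g], px)
    sumA <- sum(A_all[g])
    vol_L <- ellipsoid_volume(fer["feret_max"], fer["feret_min"])
    mol <- pixel_moles(sumA, model)
    tibble(label = as.integer(id),
           area_px = length(g),
           area_um2 = length(g) * px^2,
           feret_max_um = unname(fer["feret_max"]),
           feret_min_um = unname(fer["feret_min"]),
           sum_absorbance = sumA,
           volume_pL = vol_L * .const$L_to_pL,
           moles_fmol = mol * .const$mol_to_fmol,
           molarity_mmol_per_L = cell_molarity(mol, vol_L) *
             .const$mol_per_L_to_mmol_per_L)
  })
  dplyr::bind_rows(out)
}
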