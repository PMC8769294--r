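#' Estimate the background absorbance of a field of view
#'
#' When the suspension medium itself absorbs (stained preparations with
#' dye in the medium) the pixel-absorbance histogram of a field is
#' bimodal: a large background component from medium-only pixels and a
#' higher-absorbance component from pixels inside cells. A two-component
#' Gaussian mixture is fitted to the pixel absorbances and the mean of
#' the lower-mean component is returned as the background level.
#'
#' The mixture fit falls back to the histogram mode when it is not
#' trustworthy: when the two fitted components overlap
#' (`|mu1 - mu2| < max(sd1, sd2)`), when either weight is below 5 %, or
#' when the fit does not converge (with a warning in that case).
#' Degenerate images where one exact value dominates (e.g. a constant
#' image) short-circuit to that value.
#'
#' @param img An [absorbance_image()] with at least 10^4 pixels.
#' @param max_points Cap on the number of pixels passed to the mixture
#'   fit; pixels are subsampled deterministically (every k-th) above it.
#'   Kept at 2000 so the mixture initialization never draws a random
#'   subset, keeping the fit fully deterministic.
#' @return The background level (OD scalar), with the fitted
#'   [peak_fit()] attached as attribute `"fit"`.
#' @importFrom mclust Mclust mclustBIC
#' @export
background_level <- function(img, max_points = 2000) {
  if (!inherits(img, "absorbance_image"))
    .stop_input("`img` must be an absorbance_image")
  px <- as.vector(img$pixels)
  if (length(px) < 1e4)
    .stop_input("background fitting needs at least 10^4 pixels")
  sub <- px[seq(1, length(px), length.out = min(max_points, length(px)))]
  tab <- sort(table(sub), decreasing = TRUE)
  if (tab[1] / length(sub) >= 0.2) {
    lvl <- as.numeric(names(tab)[1])
    attr(lvl, "fit") <- peak_fit(lvl, 0, 1, fit_kind = "mode")
    return(lvl)
  }
  mix <- tryCatch(
    suppressWarnings(Mclust(sub, G = 2, modelNames = "V",
                            verbose = FALSE)),
    error = function(e) NULL)
  use_mode <- FALSE
  if (is.null(mix) || is.null(mix$parameters)) {
    warn("Gaussian-mixture background fit did not converge; using histogram mode")
    use_mode <- TRUE
  } else {
    mu <- mix$parameters$mean
    sg <- sqrt(mix$parameters$variance$sigmasq)
    if (length(sg) == 1) sg <- rep(sg, 2)
    w <- mix$parameters$pro
    if (abs(diff(mu)) < max(sg) || min(w) < 0.05) use_mode <- TRUE
  }
  if (use_mode) {
    lvl <- .sample_mode(px)
    attr(lvl, "fit") <- peak_fit(lvl, 0, 1, fit_kind = "mode")
    return(lvl)
  }
  lo <- which.min(mu)
  lvl <- unname(mu[lo])
  attr(lvl, "fit") <- peak_fit(unname(mu[order(mu)]), unname(sg[order(mu)]),
                               unname(w[order(mu)]),
                               fit_kind = "gaussian_mixture")
  lvl
}

#' Subtract a background absorbance level
#'
#' Per-pixel subtraction of a scalar background level, typically the one
#' fitted by [background_level()]; after subtraction the background peak
#' of the histogram centers on zero.
#'
#' @param img An [absorbance_image()].
#' @param level Finite OD scalar.
#' @return An [absorbance_image()] with `level` subtracted everywhere.
#' @export
subtract_background <- function(img, level) {
  if (!inherits(img, "absorbance_image"))
    .stop_input("`img` must be an absorbance_image")
  if (!is.numeric(level) || length(level) != 1 || !is.finite(level))
    .stop_input("`level` must be a single finite number")
  out <- img
  out$pixels <- img$pixels - as.numeric(level)
  out
}

#' Scattering offset of unstained live cells
#'
#' Live cells exclude the dye but still register apparent dye content
#' because their edges scatter light. The offset is estimated from the
#' per-cell content of a live stained reference: a single Gaussian is
#' fitted to the dominant peak of the value histogram, after excluding
#' values above the 95th percentile so that the few genuinely dead cells
#' present in any live culture do not bias the peak. The fitted mean is
#' the offset subtracted by the third correction strategy.
#'
#' @param values Per-cell dye contents of the live reference (>= 50
#'   cells; any consistent unit -- fmol/cell in this package's tables).
#' @return A [peak_fit()] with one peak: `$means[1]` is the offset,
#'   `$sds[1]` its width.
#' @export
scattering_offset <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 50)
    .stop_input("scattering offset needs at least 50 cells")
  if (any(!is.finite(values))) .stop_input("values must be finite")
  if (diff(range(values)) == 0)
    return(peak_fit(values[1], 0, 1, fit_kind = "gaussian"))
  keep <- values <= quantile(values, 0.95)
  g <- .fit_gaussian_histogram(values[keep])
  peak_fit(unname(g["mean"]), unname(g["sd"]), 1, fit_kind = "gaussian")
}
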