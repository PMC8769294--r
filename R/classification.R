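#' Live/dead threshold from the minimum between two fitted peaks
#'
#' Given per-cell dye contents of a live reference and a dead reference,
#' the combined histogram is fitted with a two-peak model -- a pair of
#' Lorentzians for moles-per-cell data, a pair of Gaussians for molarity
#' data -- and the threshold is placed at the minimum of the fitted
#' curve between the two peak centers (located by a dense 1-D scan).
#' Cells of an unknown sample below the threshold are called live, at or
#' above it dead.
#'
#' The peaks must be separable: the two population means must differ by
#' more than the pooled standard deviation, otherwise a
#' degenerate-distributions error is raised. If the nonlinear fit fails,
#' or with `curve = "histogram"`, the threshold falls back to the
#' midpoint of the emptiest histogram bin between the two modes.
#'
#' @param live_values,dead_values Per-cell contents (>= 50 each) of the
#'   live and dead references, in the same unit.
#' @param unit `"moles"` (Lorentzian pair, default) or `"molarity"`
#'   (Gaussian pair).
#' @param curve `"fitted"` (default) locates the minimum on the fitted
#'   continuous curve; `"histogram"` on the raw histogram counts.
#' @return The threshold (same unit as the inputs), with the fitted
#'   [peak_fit()] attached as attribute `"fit"`.
#' @export
cmin_threshold <- function(live_values, dead_values,
                           unit = c("moles", "molarity"),
                           curve = c("fitted", "histogram")) {
  unit <- match.arg(unit)
  curve <- match.arg(curve)
  live_values <- as.numeric(live_values)
  dead_values <- as.numeric(dead_values)
  if (length(live_values) < 50 || length(dead_values) < 50)
    .stop_input("need at least 50 live and 50 dead reference cells")
  n1 <- length(live_values); n2 <- length(dead_values)
  pooled_sd <- sqrt(((n1 - 1) * var(live_values) +
                     (n2 - 1) * var(dead_values)) / (n1 + n2 - 2))
  if (abs(mean(live_values) - mean(dead_values)) <= pooled_sd)
    abort("live and dead distributions are not separable (peak centers differ by less than the pooled SD)",
          class = "absorbcell_degenerate_distributions")
  all_v <- c(live_values, dead_values)
  # FD bin width per population: the pooled IQR spans both peaks and
  # would under-resolve them
  fd <- function(v) 2 * stats::IQR(v) / length(v)^(1 / 3)
  bw <- min(fd(live_values), fd(dead_values))
  h <- .hist_fd(all_v, bw = if (bw > 0) bw else NULL)
  centers <- .two_modes(h, min_sep = pooled_sd)
  if (is.null(centers))
    centers <- sort(c(median(live_values), median(dead_values)))
  widths <- pmax(c(sd(live_values), sd(dead_values)), h$binwidth)
  kind <- if (unit == "moles") "lorentzian_pair" else "gaussian_pair"
  fit <- if (curve == "fitted") .fit_two_peaks(h, centers, widths, kind) else NULL
  if (is.null(fit)) {
    if (curve == "fitted")
      warn("two-peak fit did not converge; using the raw-histogram minimum")
    inb <- which(h$mids > centers[1] & h$mids < centers[2])
    if (length(inb) == 0)
      abort("no histogram bins between the two peaks",
            class = "absorbcell_degenerate_distributions")
    thr <- h$mids[inb[which.min(h$counts[inb])]]
    pf <- peak_fit(centers, widths, fit_kind = "mode")
  } else {
    p <- fit$par
    m <- sort(c(p[["m1"]], p[["m2"]]))
    grid <- seq(m[1], m[2], length.out = 2001)
    thr <- grid[which.min(fit$fn(grid))]
    ord <- order(c(p[["m1"]], p[["m2"]]))
    pf <- peak_fit(c(p[["m1"]], p[["m2"]])[ord],
                   abs(c(p[["g1"]], p[["g2"]]))[ord],
                   c(p[["a1"]], p[["a2"]])[ord],
                   fit_kind = kind)
  }
  attr(thr, "fit") <- pf
  thr
}

#' Live/dead threshold three standard deviations above the live peak
#'
#' Fits a Gaussian to the live-reference peak (via the
#' [scattering_offset()] fit, which excludes the upper 5 % of values so
#' the few dead cells in a live culture do not bias it) and returns
#' `mean + 3*sd`. Under the Gaussian model this cutoff captures 99.9 %
#' of live cells, so cells above it are called dead. Useful when no dead
#' reference is available, e.g. for degraded batches of unknown
#' viability.
#'
#' @param live_values Per-cell contents of the live reference (>= 50).
#' @return The cutoff (same unit as input), with the [peak_fit()]
#'   attached as attribute `"fit"`.
#' @export
three_sigma_cutoff <- function(live_values) {
  pf <- scattering_offset(live_values)
  thr <- pf$means[1] + 3 * pf$sds[1]
  attr(thr, "fit") <- pf
  thr
}

#' Classify cells live or dead by a dye-content threshold
#'
#' Cells with dye content strictly below the threshold are live; cells
#' at or above it are dead. Counting boundary cells as dead is the
#' conservative choice for dose-safety applications, where missing a
#' dead cell is costlier than discarding a live one.
#'
#' @param values Per-cell dye contents (finite, non-empty).
#' @param threshold Threshold in the same unit, e.g. from
#'   [cmin_threshold()] or [three_sigma_cutoff()].
#' @param method Label recorded on the result: `"cmin"`,
#'   `"three_sigma"` or `"manual"`.
#' @return An object of class `"classification_result"`; see
#'   [tidy.classification_result()] and
#'   [glance.classification_result()].
#' @examples
#' r <- classify_cells(c(1, 2, 3, 10, 12), threshold = 5)
#' glance(r)  # 3 live, 2 dead, 40 % dead
#' @export
classify_cells <- function(values, threshold,
                           method = c("manual", "cmin", "three_sigma")) {
  method <- match.arg(method)
  values <- as.numeric(values)
  if (length(values) == 0) .stop_input("`values` must be non-empty")
  if (any(!is.finite(values))) .stop_input("`values` must be finite")
  threshold <- as.numeric(threshold)
  dead <- values >= threshold
  structure(
    list(threshold = threshold, method = method,
         values = values, dead = dead,
         n_live = sum(!dead), n_dead = sum(dead),
         percent_dead = 100 * sum(dead) / length(values)),
    class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification_result> method=%s, threshold=%.4g\n",
              x$method, x$threshold))
  cat(sprintf("  %d live, %d dead (%.1f%% dead) of %d cells\n",
              x$n_live, x$n_dead, x$percent_dead, length(x$values)))
  invisible(x)
}

#' Tidy methods for classification results
#'
#' `tidy()` returns one row per cell with its value and live/dead call;
#' `glance()` the one-row summary (threshold, counts, percent dead).
#'
#' @param x A `"classification_result"` from [classify_cells()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.classification_result <- function(x, ...) {
  tibble(value = x$values,
         status = ifelse(x$dead, "dead", "live"))
}

#' @rdname tidy.classification_result
#' @export
glance.classification_result <- function(x, ...) {
  tibble(threshold = x$threshold, method = x$method,
         n_live = x$n_live, n_dead = x$n_dead,
         percent_dead = x$percent_dead)
}
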