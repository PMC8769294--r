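#' Fitted peak parameters
#'
#' Container for the parameters of one- or two-peak fits to value
#' histograms: Gaussian background/scattering peaks, two-component
#' Gaussian mixtures, and Lorentzian pairs.
#'
#' @param means,sds,weights Numeric vectors of equal length (one entry
#'   per peak); `sds` non-negative, `weights` non-negative.
#' @param fit_kind One of `"gaussian"`, `"gaussian_mixture"`,
#'   `"lorentzian_pair"`, `"gaussian_pair"`, `"mode"`.
#' @return An object of class `"peak_fit"`.
#' @export
peak_fit <- function(means, sds, weights = rep(1, length(means)),
                     fit_kind = "gaussian") {
  if (length(means) != length(sds) || length(means) != length(weights))
    .stop_input("means, sds and weights must have equal length")
  if (any(sds < 0)) .stop_input("sds must be non-negative")
  if (any(weights < 0)) .stop_input("weights must be non-negative")
  structure(list(means = means, sds = sds, weights = weights,
                 fit_kind = fit_kind),
            class = "peak_fit")
}

#' @export
print.peak_fit <- function(x, ...) {
  cat(sprintf("<peak_fit> kind=%s\n", x$fit_kind))
  for (i in seq_along(x$means))
    cat(sprintf("  peak %d: mean=%.4g, sd=%.4g, weight=%.3g\n",
                i, x$means[i], x$sds[i], x$weights[i]))
  invisible(x)
}

#' @param x A `"peak_fit"`.
#' @param ... Unused.
#' @rdname peak_fit
#' @export
tidy.peak_fit <- function(x, ...) {
  tibble(peak = seq_along(x$means), mean = x$means, sd = x$sds,
         weight = x$weights, fit_kind = x$fit_kind)
}

# Freedman-Diaconis histogram, fixed here for reproducibility of all
# histogram-based fits. Falls back to Sturges-like binning when the IQR
# is degenerate. `bw` overrides the bin width (used for bimodal data,
# where the FD rule is applied per population instead of to the pooled
# sample, whose IQR spans both peaks and would give far too few bins).
.hist_fd <- function(x, bw = NULL) {
  rng <- range(x)
  if (diff(rng) == 0) {
    b <- c(rng[1] - 0.5, rng[1] + 0.5)
    return(list(mids = rng[1], counts = length(x), breaks = b,
                binwidth = 1))
  }
  if (is.null(bw)) {
    iqr <- stats::IQR(x)
    bw <- 2 * iqr / length(x)^(1 / 3)
  }
  if (bw <= 0) bw <- diff(rng) / ceiling(log2(length(x)) + 1)
  nb <- max(2L, min(5000L, ceiling(diff(rng) / bw)))
  breaks <- seq(rng[1], rng[2], length.out = nb + 1L)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE, right = TRUE,
                      include.lowest = TRUE)
  list(mids = h$mids, counts = h$counts, breaks = h$breaks,
       binwidth = diff(breaks[1:2]))
}

# Mode of a sample: the exact most frequent value if it dominates
# (discrete/degenerate data), otherwise the midpoint of the fullest
# Freedman-Diaconis bin.
.sample_mode <- function(x, dominance = 0.2) {
  tab <- sort(table(x), decreasing = TRUE)
  if (tab[1] / length(x) >= dominance)
    return(as.numeric(names(tab)[1]))
  h <- .hist_fd(x)
  h$mids[which.max(h$counts)]
}

# Fit a single Gaussian to the dominant peak of a histogram by
# nonlinear least squares on bin counts. Returns c(mean, sd, amplitude);
# falls back to the sample mean/sd when the fit fails.
.fit_gaussian_histogram <- function(x) {
  mu0 <- .sample_mode(x)
  sd0 <- sd(x)
  if (!is.finite(sd0) || sd0 == 0)
    return(c(mean = mean(x), sd = 0, amplitude = length(x)))
  h <- .hist_fd(x)
  a0 <- max(h$counts)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      counts ~ a * exp(-(mids - m)^2 / (2 * s^2)),
      data = data.frame(mids = h$mids, counts = h$counts),
      start = list(a = a0, m = mu0, s = sd0),
      lower = c(a = 0, m = -Inf, s = 1e-12),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    warn("Gaussian peak fit did not converge; using sample mean and SD")
    return(c(mean = mean(x), sd = sd0, amplitude = a0))
  }
  cf <- stats::coef(fit)
  c(mean = unname(cf["m"]), sd = abs(unname(cf["s"])),
    amplitude = unname(cf["a"]))
}

# Locate the two highest well-separated modes of a histogram: the global
# maximum bin, then the highest bin at least `min_sep` away from it.
.two_modes <- function(h, min_sep) {
  i1 <- which.max(h$counts)
  far <- abs(h$mids - h$mids[i1]) >= min_sep
  if (!any(far)) return(NULL)
  i2 <- which(far)[which.max(h$counts[far])]
  sort(c(h$mids[i1], h$mids[i2]))
}

# Fit a two-peak model (Lorentzian or Gaussian pair) to histogram counts
# by nonlinear least squares; returns list(par = named vector, fn =
# fitted curve function) or NULL on failure.
.fit_two_peaks <- function(h, centers, widths, kind) {
  df <- data.frame(mids = h$mids, counts = h$counts)
  a0 <- vapply(centers, function(m) max(h$counts[which.min(abs(h$mids - m))], 1),
               numeric(1))
  form <- if (kind == "lorentzian_pair") {
    counts ~ a1 / (1 + ((mids - m1) / g1)^2) + a2 / (1 + ((mids - m2) / g2)^2)
  } else {
    counts ~ a1 * exp(-(mids - m1)^2 / (2 * g1^2)) +
      a2 * exp(-(mids - m2)^2 / (2 * g2^2))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      form, data = df,
      start = list(a1 = a0[1], m1 = centers[1], g1 = widths[1],
                   a2 = a0[2], m2 = centers[2], g2 = widths[2]),
      lower = c(a1 = 0, m1 = -Inf, g1 = 1e-12,
                a2 = 0, m2 = -Inf, g2 = 1e-12),
      control = minpack.lm::nls.lm.control(maxiter = 400)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  p <- stats::coef(fit)
  fn <- if (kind == "lorentzian_pair") {
    function(x) p["a1"] / (1 + ((x - p["m1"]) / p["g1"])^2) +
      p["a2"] / (1 + ((x - p["m2"]) / p["g2"])^2)
  } else {
    function(x) p["a1"] * exp(-(x - p["m1"])^2 / (2 * p["g1"]^2)) +
      p["a2"] * exp(-(x - p["m2"])^2 / (2 * p["g2"]^2))
  }
  list(par = p, fn = fn)
}
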