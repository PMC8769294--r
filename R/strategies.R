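#' Bundle the fields of view of one treatment
#'
#' A treatment dataset groups the fields of view captured for one
#' preparation -- live or dead cells, suspended in plain buffer or in
#' dye solution -- with the segmentation parameters and dose model used
#' to analyze them. Fields may be supplied either as brightfield
#' triplets (`list(I = , Imax = , Imin = )`, where `Imax`/`Imin` may be
#' lists of replicate frames to average) or as precomputed
#' [absorbance_image()]s.
#'
#' @param role One of `"LD"`, `"LT"`, `"DD"`, `"DT"`, `"MIXTURE"`,
#'   `"UNKNOWN"`: live/dead cells in buffer (D) or dye (T), a live:dead
#'   mixture, or an unknown sample.
#' @param fields Non-empty list of fields of view (triplets or
#'   absorbance images) with a consistent pixel size.
#' @param params [segmentation_params()] for this treatment.
#' @param model [pixel_dose_model()] for this treatment.
#' @param cap Absorbance cap used when converting triplets.
#' @return An object of class `"treatment_dataset"`.
#' @export
treatment_dataset <- function(role, fields, params = segmentation_params(),
                              model, cap = 4) {
  role <- match.arg(role, c("LD", "LT", "DD", "DT", "MIXTURE", "UNKNOWN"))
  if (!is.list(fields) || length(fields) == 0)
    .stop_input("`fields` must be a non-empty list of fields of view")
  if (!inherits(model, "pixel_dose_model"))
    .stop_input("`model` must be a pixel_dose_model")
  px <- vapply(fields, function(f) {
    if (inherits(f, "absorbance_image")) f$pixel_size
    else if (is.list(f) && all(c("I", "Imax", "Imin") %in% names(f))) {
      f$I$pixel_size
    } else .stop_input(
      "each field must be an absorbance_image or a list(I, Imax, Imin)")
  }, numeric(1))
  if (length(unique(px)) != 1)
    .stop_input("all fields must share the same pixel size")
  structure(list(role = role, fields = fields, params = params,
                 model = model, cap = cap),
            class = "treatment_dataset")
}

#' @export
print.treatment_dataset <- function(x, ...) {
  cat(sprintf("<treatment_dataset> role=%s, %d field(s) of view\n",
              x$role, length(x$fields)))
  invisible(x)
}

# Resolve one field of view to an absorbance image, averaging replicate
# reference frames first when given a brightfield triplet.
.field_absorbance <- function(field, cap) {
  if (inherits(field, "absorbance_image")) return(field)
  imax <- field$Imax
  imin <- field$Imin
  if (is.list(imax) && !inherits(imax, "intensity_image"))
    imax <- average_reference_images(imax)
  if (is.list(imin) && !inherits(imin, "intensity_image"))
    imin <- average_reference_images(imin)
  to_absorbance(field$I, imax, imin, cap = cap)
}

#' Run one of the three correction strategies over a treatment dataset
#'
#' The three strategies form a ladder of increasing correction:
#' * **Strategy 1 ("raw")**: segment and measure on the raw absorbance
#'   images. Per-cell content then includes the dye in the medium above
#'   and below each cell and the scattering at its edges.
#' * **Strategy 2 ("background subtracted")**: fit and subtract the
#'   per-field background level ([background_level()]) before
#'   segmentation, removing the medium contribution.
#' * **Strategy 3 ("background and scattering subtracted")**: strategy 2,
#'   then subtract the live-reference scattering offset `mu_LT_noBG`
#'   ([scattering_offset()]) from every cell's moles; molarity is
#'   recomputed from the corrected moles.
#'
#' The offset for strategy 3 is estimated once from all fields of the
#' live stained reference pooled, then applied to every treatment of the
#' experiment.
#'
#' @param ds A [treatment_dataset()].
#' @param strategy 1, 2 or 3.
#' @param lt_reference For strategy 3: a live-stained
#'   [treatment_dataset()] (analyzed internally with strategy 2), an
#'   already computed [scattering_offset()] `peak_fit`, or a bare
#'   numeric offset in fmol/cell.
#' @return A tibble of per-cell records: `field`, `label`, geometry and
#'   content columns as in [measure_cells()], plus `strategy`,
#'   `background_od` (0 for strategy 1) and, for strategy 3,
#'   `mu_lt_noBG_fmol`.
#' @export
run_strategy <- function(ds, strategy = 1, lt_reference = NULL) {
  if (!inherits(ds, "treatment_dataset"))
    .stop_input("`ds` must be a treatment_dataset")
  if (!strategy %in% 1:3) .stop_input("`strategy` must be 1, 2 or 3")
  mu_lt <- NULL
  if (strategy == 3) {
    if (is.null(lt_reference))
      .stop_input("strategy 3 requires an LT reference or a precomputed offset")
    mu_lt <- if (is.numeric(lt_reference)) {
      as.numeric(lt_reference)
    } else if (inherits(lt_reference, "peak_fit")) {
      lt_reference$means[1]
    } else if (inherits(lt_reference, "treatment_dataset")) {
      lt2 <- run_strategy(lt_reference, strategy = 2)
      scattering_offset(lt2$moles_fmol)$means[1]
    } else .stop_input("`lt_reference` must be a dataset, peak_fit or number")
  }
  per_field <- purrr::imap(ds$fields, function(field, i) {
    A <- .field_absorbance(field, ds$cap)
    bg <- 0
    if (strategy >= 2) {
      bg <- as.numeric(background_level(A))
      A <- subtract_background(A, bg)
    }
    seg <- segment_cells(A, ds$params)
    cells <- measure_cells(seg, A, ds$model)
    dplyr::mutate(cells, field = as.integer(i), background_od = bg,
                  .before = 1)
  })
  out <- dplyr::bind_rows(per_field)
  out$strategy <- as.integer(strategy)
  if (strategy == 3) {
    out$mu_lt_noBG_fmol <- mu_lt
    out$moles_fmol <- out$moles_fmol - mu_lt
    # mmol/L == fmol / pL, so molarity recomputes directly
    out$molarity_mmol_per_L <- out$moles_fmol / out$volume_pL
  }
  out
}
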