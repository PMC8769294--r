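# absorbcell

Traceable cell-viability measurement from brightfield absorbance
microscopy, for anyone who needs trypan blue live/dead counts that are
comparable across microscopes: cell-therapy manufacturing QC, assay
development, and imaging labs replacing arbitrary intensity thresholds
with quantities in SI units.

## The method

The trypan blue dye-exclusion test stains dead cells blue; classifying
cells from raw pixel intensities ties the result to one particular
microscope, camera and exposure. `absorbcell` instead converts each
brightfield frame into a per-pixel absorbance (optical density) image
using a blank and a dark reference captured with the same settings:

```
A = -log10( (I - Imin) / (Imax - Imin) )
```

Absorbance is ratiometric, so it transfers between instruments. The
Beer–Lambert law `A = ε·c·l`, with the molar absorption coefficient
`ε(610 nm)` fitted from a dye dilution series, then turns each
segmented cell's summed absorbance into **moles of trypan blue per
cell** (and, with an ellipsoid volume from the cell's Feret diameters,
**intracellular molarity**). Three correction strategies of increasing
rigor remove (1) nothing, (2) the absorbance of dye in the medium
(per-field Gaussian-mixture background fit), and (3) additionally the
apparent content caused by cell-edge scattering, estimated from live
stained reference cells. Live/dead calls come from the per-cell
dye-content histogram: either the minimum between the fitted live and
dead peaks (Lorentzian pair for moles, Gaussian for molarity), or a
mean + 3σ cutoff above the live peak when no dead reference exists.

A synthetic phantom generator reproduces the standard four-treatment
control design (live/dead × buffer/dye, plus 1:1 mixtures) with known
ground truth — cells, scattering rings, medium absorbance, illumination
gradient, shot/read noise and quantization — so the whole chain is
testable end to end without a microscope.

## Worked example

```r
library(absorbcell)

# a synthetic experiment: live-stained (LT), dead-stained (DT) references
# and a 1:1 live:dead mixture, 3 fields of 40 cells each
exp <- generate_experiment(c("LT", "DT", "MIXTURE"), seed = 42,
                           n_fields = 3, cells_per_field = 40,
                           shape = c(320, 320))

# scattering offset from the live stained reference (strategy 2 output)
lt2    <- run_strategy(exp$datasets$LT, 2)
offset <- scattering_offset(lt2$moles_fmol)
offset
#> <peak_fit> kind=gaussian
#>   peak 1: mean=3.278, sd=0.3995, weight=1

# fully corrected per-cell tables (background + scattering subtracted)
lt3 <- run_strategy(exp$datasets$LT, 3, lt_reference = offset)
dt3 <- run_strategy(exp$datasets$DT, 3, lt_reference = offset)
mx3 <- run_strategy(exp$datasets$MIXTURE, 3, lt_reference = offset)
head(dt3, 3)[c("field", "label", "area_um2", "feret_max_um",
               "moles_fmol", "molarity_mmol_per_L")]
#>   field label area_um2 feret_max_um moles_fmol molarity_mmol_per_L
#> 1     1     1      157         15.3       20.6               13.1
#> 2     1     2      187         16.8       18.7                9.44
#> 3     1     3      157         15.3       22.1               14.1

# live/dead threshold at the minimum between the fitted LT and DT peaks
thr <- cmin_threshold(lt3$moles_fmol, dt3$moles_fmol, unit = "moles")
result <- classify_cells(mx3$moles_fmol, thr, method = "cmin")
result
#> <classification_result> method=cmin, threshold=7.431
#>   60 live, 60 dead (50.0% dead) of 120 cells
```

The scattering offset (3.28 fmol/cell) is the apparent dye content of
live cells — edge scattering, not uptake — and is subtracted from every
cell in strategy 3, after which live cells center on 0 fmol. Dead cells
here carry 20.7 fmol/cell on average (the generator drew them from
Normal(20.6, 3) fmol truncated at zero), the threshold lands in the
valley at 7.4 fmol/cell, and the 1:1 mixture is counted as exactly 50 %
dead. `glance()`/`tidy()` methods give tibble summaries of every fitted
object, and `autoplot()` methods draw the absorbance images,
calibration fits and classified histograms.

File-based workflows use the same functions: `read_manifest()` +
`run_pipeline()` run a whole experiment from a YAML manifest of TIFF
paths and write absorbance TIFFs, per-cell CSVs, a classification JSON
and an audit log; `inst/cli/absorbcell.R` exposes `convert`,
`calibrate`, `analyze`, `classify` and `simulate` subcommands for shell
use.

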