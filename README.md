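# monocal

Calibration of monolithic-crystal PET detector modules with
Voronoi-tessellation lookup tables, including two accelerated
system-level calibration schemes and a synthetic detector simulator for
end-to-end validation.

## The problem

A monolithic scintillator block (here 50 × 50 × 15 mm LYSO on a 12 × 12
SiPM array at 4.2 mm pitch) reports, per 511 keV photon, the row and
column channel sums of its light distribution.  From these one
estimates a planar position (squared-weight centre of gravity, COG²),
an energy *E* (channel sum) and a raw depth-of-interaction statistic
*E*/*I*max.  All three are biased by light truncation at the crystal
faces, gain non-uniformities and the unitless DOI scale.

The standard correction irradiates each module with an 11 × 11 array of
collimated sources (4.6 mm pitch), locates the 121 measured centroids,
partitions the flood map with their Voronoi tessellation, and attaches
five factors to each cell *i*:

* planar: `f_X,i = x_mech,i − x_meas,i` and `f_Y,i` (normalized units),
* energy: `f_E,i` = photopeak channel of the cell,
* DOI: `f_DOI1,i = a_i − σ_int,i`, `f_DOI2,i = b_i + σ_int,i` from the
  edges of the cell's *E*/*I*max histogram, anchored to 0 and 15 mm.

The factors are rasterized into five lookup tables (LUT_X, LUT_Y,
LUT_DOI1, LUT_DOI2, LUT_Energy) applied event by event.  Because
calibrating every module this way is slow on a real scanner, two
accelerations are implemented: **TEST1** (share one module's LUTs
verbatim) and **TEST2** (average three modules' calibration maps into a
reference, then correct it per module with a shift map interpolated from
the corners of that module's uniformity flood map; energy and DOI
factors come from the uniformity events themselves).  Calibrations are
compared through per-cell correlation factors
`CF_i = factor_TEST,i / factor_Normal,i` averaged over the 121 cells,
and through the FWHM of calibrated point-source profiles.

## Worked example

```r
library(monocal)

cfg  <- detector_config()                 # one simulated module
grid <- source_grid()                     # 11 x 11 sources, 4.6 mm pitch

est <- simulate_grid_acquisition(grid, 250, cfg, seed = 1) |>
  estimate_events()
cal <- normal_calibrate(est, grid, grid_n = 150)
glance(cal)
#> # A tibble: 1 × 10
#>   detector_id n_cells n_events converged mean_abs_f_x mean_abs_f_y central_peak
#>   <chr>         <int>    <int> <lgl>            <dbl>        <dbl>        <dbl>
#> 1 D01             121    30250 TRUE             0.101        0.101       13289.
#> # ℹ 3 more variables: doi1_mean <dbl>, doi2_mean <dbl>, n_fallback <int>

calibrated <- calibrate_events(est, cal$luts)
```

`n_cells = 121` is the Voronoi partition of the 11 × 11 flood map;
`mean_abs_f_x ≈ 0.10` says the average planar correction is about
2.5 mm (normalized units × 25 mm), dominated by edge compression;
`central_peak` is the 511 keV photopeak of the central cell in ADC
channels — the reference the energy correction scales every other cell
to.  `calibrated` adds `x_cal_mm`, `y_cal_mm`, `E_cal` and `doi_cal_mm`
columns; per source, the mean calibrated position lands on the
mechanical grid with an RMS error of about 0.2 mm over the interior
nodes.

A full ring comparison (24 modules, 5% gain spread, 0.5 mm alignment
spread; TEST1 donor module 1, TEST2 donors modules 1–3):

```r
st <- bank_study(n_detectors = 24, seed = 1)
glance(st)
#> # A tibble: 1 × 7
#>   n_detectors mean_abs_cf_dev_xy_test1 mean_abs_cf_dev_xy_test2 fwhm_normal_mm
#>         <int>                    <dbl>                    <dbl>          <dbl>
#> 1          24                     1.23                    0.259          0.871
#> # ℹ 3 more variables: fwhm_test1_mm <dbl>, fwhm_test2_mm <dbl>,
#> #   recovery_rms_mm <dbl>
```

The shift-map calibration (TEST2) tracks the per-module ground truth
several times more closely than plain LUT sharing (mean per-cell
|CF − 1| of 0.26 versus 1.23 for the planar factors), and the
ring-pooled point-source profile stays sharper (FWHM 1.38 mm versus
1.98 mm for TEST1, with 0.87 mm under full Normal calibration).

A thin command-line driver is installed with the package
(`exec/monocal`): `monocal demo --seed 1 --out runs/demo` runs the
simulate → calibrate → evaluate pipeline and writes LUT directories, a
correlation-factor report and a reproducibility manifest.

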