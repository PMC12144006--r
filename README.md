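# petphantom

Digital wall-less PET sphere phantoms and volume-reproducing threshold
analysis.

## What this is for

Threshold-based region growing is the most common way to delineate
hot lesions in PET. Its calibration is traditionally validated with
fillable phantoms — hollow NEMA spheres filled with tracer — but the
inactive plastic **wall** between sphere and background depresses the
intensities at the boundary and makes the optimal threshold depend on
image contrast. Wall-less phantoms (radioactive 3D-printed spheres
sitting directly in active background) remove that artifact.

`petphantom` reproduces this comparison entirely in software, for
anyone developing or validating threshold-based PET segmentation:

* a synthetic-data generator for voxelized, PSF-blurred, optionally
  noisy sphere phantoms — wall-less or with a cold wall shell — across a
  series of signal-to-background ratios (SBR), plus a high-resolution
  autoradiography-like 2D count field;
* seeded connected-threshold segmentation and a bisection search for
  the absolute **volume-reproducing threshold** `T`, the threshold at
  which the grown region's volume equals the sphere's true volume;
* the background-corrected relative threshold

  ```
  VRT = (T - B) / (A - B)
  ```

  with `A` the sphere's reference activity concentration (by default
  the image mean over the true sphere geometry) and `B` the background
  concentration, plus its contrast-dependence statistics (CV across
  SBRs), the wall-less vs. fillable differences, and the volume
  overestimation caused by cross-applying fillable-derived thresholds
  to wall-less images;
* uniformity statistics (CV, Kullback–Leibler divergence,
  Kolmogorov–Smirnov test) for comparing voxel-intensity distributions;
* the bilinear CT Hounsfield-unit → 511 keV attenuation conversion;
* NIfTI-1 input/output and a YAML-configured experiment driver.

## Worked example

```r
library(petphantom)
cfg <- experiment_config()          # six NEMA spheres, SBR 2-10, 7 mm FWHM
ex  <- run_vrt_experiment(cfg)
print(ex)
```

```
<vrt_experiment> 6 spheres x 5 SBR levels x 2 variants
  mean VRT CV over SBRs: wall-less 0.00%, fillable 9.46%
  max VRT difference: 14.8 pp; max volume overestimation: 50.5%
```

`summary(ex)` prints the full tables. The wall-less spheres hold their
VRT exactly across contrasts (each row constant; the CV is at
floating-point rounding because noiseless wall-less contrast
independence is exact by linearity):

```
-- wall-less --
           sbr_target
diameter_mm    2    4    6    8   10
         10 69.6 69.6 69.6 69.6 69.6
         13 65.4 65.4 65.4 65.4 65.4
         17 60.7 60.7 60.7 60.7 60.7
         22 57.1 57.1 57.1 57.1 57.1
         28 55.8 55.8 55.8 55.8 55.8
         37 54.0 54.0 54.0 54.0 54.0
```

Note the size trend: smaller spheres need a higher relative threshold
because blurring depresses their mean. With a 1 mm cold wall the same
spheres lose contrast independence — the curves bend down at low SBR
(mean CV 9.5%):

```
-- fillable (cold wall) --
           sbr_target
diameter_mm    2    4    6    8   10
         10 54.8 66.4 67.8 68.4 68.7
         ...
         37 40.7 49.7 51.5 52.2 52.6
```

Using the fillable-derived thresholds to segment the wall-less images
overestimates volumes, mildly at high contrast and badly at low
contrast, worst for the smallest sphere:

```
Volume overestimation (%) from cross-applied fillable thresholds
           sbr_target
diameter_mm    2    4    6    8   10
         10 50.5 10.0  5.8  5.4  4.3
         37 14.6  4.3  2.5  1.8  1.3
```

`plot(ex)` draws the VRT-vs-SBR curves;
`plot(ex, which = "overestimation")` the volume errors. And the CT
number of the printed resin converts as

```r
hu_to_mu511(153)
#> [1] 0.105918
```

i.e. 0.106 cm⁻¹ at 511 keV.

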