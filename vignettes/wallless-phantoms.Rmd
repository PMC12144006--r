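---
title: "Digital wall-less phantoms and the volume-reproducing threshold"
author: "petphantom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital wall-less phantoms and the volume-reproducing threshold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petphantom)
```

## The problem: cold walls bias threshold-based PET delineation

Threshold-based segmentation is the workhorse of PET target delineation:
grow a region from a seed voxel, keeping every connected voxel whose
intensity is at least some threshold `T`.  For a sphere of known volume
one can ask for the *volume-reproducing threshold* (VRT) — the `T` at
which the segmented volume equals the true volume — and report it in
background-corrected relative form,

    VRT = (T - B) / (A - B),

with `A` the sphere's reference activity concentration and `B` the
background concentration.  For a wall-less radioactive sphere sitting
directly in active background, this relative threshold is a property of
the scanner resolution and the sphere geometry only: it does not depend
on the contrast (the signal-to-background ratio, SBR).  Conventional
fillable phantom inserts, however, have an *inactive wall* between the
hot interior and the hot background.  The cold shell depresses
intensities around the boundary, and the lower the contrast the larger
the relative bite it takes — so a VRT calibrated on a fillable phantom is
contrast-dependent and, applied at low SBR, overestimates volumes.

This package replaces the physical experiment (3D-printed radioactive
spheres vs. fillable NEMA inserts, scanned at five background levels)
with a desk-scale digital simulation that reproduces the wall effect,
plus the analysis chain used to quantify it.

## The simulation model

An image is produced in three steps, each a separate operation so that
every intermediate is testable:

1. **Rasterization** (`rasterize_phantom`).  Spheres (optionally with a
   cold wall shell of configurable thickness placed *outside* the
   nominal NEMA inner diameter, displacing background) are voxelized on
   the reconstruction grid.  Voxels wholly inside one compartment are
   assigned directly; voxels cut by a surface are anti-aliased with a
   regular sub-voxel sample grid.  The sample pitch is kept *isotropic*:
   `oversample` points per axis per unit of the smallest voxel pitch, so
   on the 1 x 1 x 2 mm grid `oversample = 4` uses 4 x 4 x 8 points.  With
   an anisotropic pitch the coarse z-sampling leaves a systematic volume
   bias of about +0.5% for grid-aligned spheres; the isotropic pitch
   brings it almost an order of magnitude down with negligible cost.
2. **Noise** (`add_noise`).  Zero-mean Gaussian noise with standard
   deviation `relative_sigma * mean(image)`, added *before* filtering so
   the reconstruction-like smoothing correlates it.  Count statistics of
   the real acquisition are not recoverable from the publication (frame
   durations were adjusted to match sphere counts), so the noise level is
   a free parameter and the default is noiseless, which makes the
   headline results deterministic.
3. **Point-spread function** (`apply_psf`).  Separable Gaussian
   convolution with a physical FWHM, per-axis in voxel units, with
   bin-integrated normalized kernels truncated at 4 sigma and
   constant-value padding at the grid boundary.  Padding with the
   background level is the physically right boundary condition here: the
   real sphere sits in an extended uniform background.  The convolution
   is written in the package (FFT-based per axis) because it must honour
   anisotropic voxel spacing in mm and a *specified* constant pad value.

The default effective resolution is **7 mm FWHM**.  The reconstruction
used a 5 mm FWHM Gaussian filter, and the intrinsic scanner resolution
(4-5 mm for the systems concerned) combines with it roughly in
quadrature; 7 mm is that combination, and it is a configurable parameter
of every simulation rather than a constant.

Sphere sub-volumes (default 80 x 80 x 60 voxels of 1 x 1 x 2 mm) are
simulated one sphere at a time: each sphere is analysed independently in
the protocol, and the sub-volumes keep a full experiment in well under a
minute.  Sphere centres are given a fixed, generic sub-voxel offset.  A
physical sphere is never aligned with the voxel grid, and exact alignment
is also numerically degenerate: grid symmetry creates 8-fold (or worse)
intensity ties, which coarsen the set of attainable segmented volumes so
that the half-voxel volume tolerance of the threshold search cannot be
met.

The SBR series fixes the sphere activity and sets the background to
`A / SBR` for each target (activity is *added* to the background between
acquisitions in the physical protocol), rasterizing, noising and
filtering each member independently.

## The threshold search

`connected_threshold` implements seeded region growing with an
*inclusive* comparison (`>= T`), which makes "threshold equal to a voxel
value" well defined and lets the brute-force flood-fill oracle in the
test suite match it exactly.  Default connectivity is 6 (faces);
26-connectivity is available, and for blurred phantoms the two give
identical thresholds, which a test asserts.

`find_vrt_threshold` exploits the monotonicity of segmented volume in
`T` and bisects.  Termination: volume within half a voxel of the target,
or bracket narrower than 1e-6 of its initial width; the best-visited
iterate wins, ties toward the lower threshold.  On a discrete image the
volume is a step function of `T`, constant on the interval between two
consecutive distinct voxel values, so the returned threshold is snapped
to the canonical representative of its plateau — the smallest voxel value
producing the identical segment.  This makes the result independent of
bisection trajectory and well defined on plateaus (for a two-level image
any threshold in `(low, high]` reproduces the inner volume; the snap
reports `high`, the unique distinct-value candidate).

Bisection bounds default in the experiment driver to (background level,
image maximum); the lower bound segments the whole grid, the upper a
single voxel, so the target volume is always bracketed.  Seed voxels are
the centre-of-mass voxel of a generous spherical VOI around the known
centre — the protocol assigned seeds manually, without stating how, and
centre-of-mass seeding is deterministic and unambiguous here.

## The reference activity A

The relative threshold needs a reference concentration `A`.  Two
definitions are implemented (`a_definition`):

* `"image_mean"` (default): the mean image intensity over the sphere's
  true geometry.  Under Gaussian blurring this mean falls with
  decreasing sphere size, which makes the relative VRT *rise* for small
  spheres — the size trend the measured data show, with values spanning
  roughly 50-70%.
* `"true"`: the specified concentration, for sensitivity analysis.  With
  it the VRT of small spheres would fall rather than rise, contradicting
  the observed size trend; that is why image-mean is the default.

`B` is the true background concentration in simulations; for external
images it should be the mean of a user-supplied background VOI.

## Contrast independence, exactly

For noiseless wall-less simulations contrast independence is not
approximate but exact, by linearity: the image at background `B` is
`B + (A - B) * h(x)` with `h` the blurred sphere indicator, identical
across SBRs.  The volume-matching threshold then sits at the same level
of `h`, and with the image-mean reference the relative VRT reduces to
`h_T / mean(h)` — every `A`, `B` cancels.  The simulated per-sphere CV
across SBRs is therefore at floating-point rounding (~1e-14), far below
the ~2% the physical measurement reports, which includes noise and
repositioning.  The walled spheres break this invariance because the
cold shell contributes `-B * h_wall(x)`: a *background-dependent* term
that bends the VRT-vs-SBR curves downward at low contrast.

## Uniformity statistics

Activity-distribution uniformity inside sphere cores (27 mm VOIs, to
exclude spill effects) is compared with three statistics: the CV of
voxel intensities, a histogram Kullback-Leibler divergence, and the
two-sample Kolmogorov-Smirnov statistic.  Choices the source protocol
left open, fixed here: 64 shared equal-width histogram bins with an
epsilon of 1e-12 added per bin before normalization (KL is insensitive
to the bin count in the tested 16-256 range for the simulated
distributions); KL direction is `KL(test || reference)`, first argument
the test distribution; the KS p-value uses the asymptotic approximation,
appropriate at thousands of voxels.  Voxel intensities are treated as
i.i.d. samples, as the VOI-level protocol implicitly does; PSF-induced
spatial correlation is acknowledged, not modelled.

## The autoradiography generator

`generate_autoradiography_field` emulates a 25 um phosphor-plate image
of a 60 x 20 mm printed slab: uniform baseline, Poisson-placed Gaussian
hotspots (microscopic regions of elevated counts in the cured resin),
independent pixel noise.  The defaults — 0.06 hotspots/mm^2, amplitude
0.5 of baseline, 1.2 mm FWHM, 5% pixel noise — come from the closed-form
shot-noise relations for a Poisson field of Gaussian bumps: hotspot CV
`= a * sqrt(lambda * pi * sigma_h^2)` raw, attenuated by
`sigma_h / sqrt(sigma_h^2 + sigma_s^2)` after smoothing with a Gaussian
of width `sigma_s`.  Solving those for a raw CV near 11.7% that falls to
roughly 2.4% under the 5 mm reconstruction filter gives the defaults;
the smoothed value depends on the (unmeasured) hotspot correlation
length, so only the *decrease* is asserted in tests.  A generated field
at the default geometry lands near 10.8% raw and 1.8% smoothed.

## What the generator does and does not emulate

It reproduces: the partial-volume effect (Gaussian resolution), the
cold-wall geometry, the SBR series with fixed sphere activity,
reconstruction-correlated noise, anisotropic clinical voxels.  It does
not reproduce: projection-domain physics (attenuation, scatter,
randoms), OSEM convergence behaviour and its non-stationary noise, sphere
repositioning between acquisitions, CT images, or leaching of activity
from printed material.  Passing tests therefore demonstrate the
*geometric and resolution-driven* claims — contrast independence without
walls, its loss with walls, the size dependence of mean-based
thresholds — not scanner-specific quantitative accuracy.

## Numerical choices and degenerate inputs

* Inclusive thresholding (`>= T`); the flood-fill oracle uses the same
  convention.
* Bisection tolerance: half a voxel volume; bracket floor 1e-6 of the
  initial width; plateau snap to the smallest equivalent voxel value.
* Empty spherical VOIs are legal (flagged with a message); empty or
  non-positive regions for centre-of-mass and CV are errors.
* `relative_vrt` requires `A > B`; SBR targets must exceed 1.
* All random draws (noise, autoradiography) run under a caller-supplied
  seed and restore the caller's RNG state; series elements use
  `seed + i - 1`, recorded in the output.
* The HU conversion anchors its upper branch at the 47 HU breakpoint
  (`mu(47) + 5.1e-5 * (HU - 47)`), making the bilinear transform
  continuous by construction; the implied intercept, 0.047115, is the
  published rounded constant 4.71e-2 to three significant digits.

## Problem sizes

The package's own analyses use per-sphere sub-volumes of 80 x 80 x 60
voxels, the six NEMA diameters, five SBR levels and two variants (60
threshold searches); a full experiment runs in about half a minute on
one core, and the unit suite builds its fixtures on grids of 12^3 to
48 x 48 x 36.  Autoradiography unit tests use reduced 20 x 10 mm fields
at 50 um; the full 60 x 20 mm field at 25 um runs in a few seconds and
is exercised by the command-line driver.

## Known limitations

* No projection/sinogram simulation; resolution is a single stationary
  Gaussian, while real OSEM resolution varies with position and count
  level.
* The wall thickness of commercial fillable inserts is not published;
  the 1 mm default is a plausible value and the wall-effect *magnitudes*
  scale with it, though the directions and orderings tested do not.
* The mean-based VRT near the 5 pp acceptance band edge for the largest
  sphere is sensitive to the effective FWHM; 7 mm is stated, not fitted.
* KS/KL treat voxels as independent; with PSF correlation the effective
  sample size is smaller than the voxel count, so p-values are
  optimistic.
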