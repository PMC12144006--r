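Package: petphantom
Title: Digital Wall-Less PET Sphere Phantoms and Volume-Reproducing
    Threshold Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates reconstructed PET images of NEMA-style sphere
    phantoms, both wall-less (active object directly in active background)
    and fillable (inactive wall shell between object and background), at a
    series of signal-to-background ratios.  Determines the absolute
    volume-reproducing threshold of each sphere by bisection over seeded
    connected-threshold segmentations, converts it to the
    background-corrected relative threshold, and quantifies its contrast
    dependence, the volume errors caused by cold phantom walls, and the
    uniformity of the activity distribution (coefficient of variation,
    Kullback-Leibler divergence, Kolmogorov-Smirnov statistic).  Also
    provides a high-resolution autoradiography-like field generator, the
    bilinear CT Hounsfield-unit to 511 keV attenuation conversion, and
    NIfTI input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    RNifti,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
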