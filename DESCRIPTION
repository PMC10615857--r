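Package: mitomorph
Title: Morphometrics of Mitochondria, Cristae and Mitochondria-ER Contacts
    from Electron Microscopy Label Maps
Version: 0.1.0
Authors@R:
    person("Morphometry", "Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies organelle architecture from segmented transmission
    electron microscopy (TEM) sections and volume-EM (SBF-SEM / FIB-SEM)
    label stacks. Provides per-object 2D morphometrics (area, sub-pixel
    perimeter, circularity index 4*pi*A/P^2, Feret length), cristae metrics
    (count, volume density, membrane-length surface proxy, lamellar versus
    tubular classification, 0-4 cristae-score validation), detection and
    measurement of mitochondria-ER contact sites (MERCs) in 2D and 3D via
    anisotropy-aware distance transforms (gap statistics, contact length and
    area, cleft volume, percent coverage, calcium-transfer band), 3D
    morphometrics (voxel volume, smoothed-isosurface area, centerline
    skeletonization, branch statistics, nanotunnel / mitochondria-on-a-string
    detection), a synthetic phantom generator with closed-form ground truth
    for every metric, and two-group statistics with the significance-star
    convention used in EM morphometry studies. Reads and writes integer label
    maps as multi-page TIFF, PNG and HDF5.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    png,
    rhdf5,
    yaml,
    optparse,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
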