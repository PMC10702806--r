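Package: memlens
Title: Quantitative Analysis of Local Membrane Remodeling Around Membrane Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Reconstructs smooth membrane-leaflet surfaces from scattered
    point data (for example leaflet segmentations of cryo-electron tomography
    maps) by Delaunay interpolation followed by local quadratic regression
    (LOESS), and derives local membrane descriptors from them: mean and
    Gaussian curvature maps, regional radii of curvature, least-squares
    sphere fits, and bilayer thickness maps.  Companion trajectory analyses
    quantify deuterium acyl-chain order parameters, lipid flip-flop events,
    lateral-gate helix distances, superposition RMSD, hydrogen-bond
    occupancy, and buried interface areas (Shrake-Rupley solvent-accessible
    surface area).  A synthetic-membrane generator provides analytic ground
    truth (curved leaflet point clouds, lensed bilayers, lipid trajectories
    with prescribed order and flip-flop rates, toy structures) so that every
    stage of the pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    interp,
    FNN,
    bio3d,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
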