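Package: archflow
Title: Wall Shear Stress, OSI and Pulse Wave Velocity Mapping from 4D Flow
    Velocity Fields of the Murine Aortic Arch
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes time-resolved wall shear stress (WSS) vectors from
    volumetric phase-contrast velocity fields and lumen segmentations,
    decomposes them into longitudinal, circumferential and radial components
    in a centerline-based cylindrical frame, derives the oscillatory shear
    index (OSI), unwraps per-node wall values onto regular (z, theta)
    projection maps, and estimates transit-time pulse wave velocity and
    time-resolved lumen volume. Includes pixel-wise group statistics over
    aligned map stacks (difference, p-value and significance maps,
    inter-animal dispersion summaries) and scalar statistics with outlier
    exclusion and normality-gated test selection. A synthetic flow-phantom
    generator with analytic ground truth (Poiseuille and helical profiles,
    pulsatile waveforms with prescribed wave speed) supports validation of
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
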