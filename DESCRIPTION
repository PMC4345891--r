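Package: optomap
Title: Patterned Optogenetic Stimulation Mapping and Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
                  role = c("aut", "cre"))
Description: Hardware-free toolkit for digital-micromirror-device (DMD)
    based optogenetic stimulus-response mapping. Defines regions of
    interest and hierarchical stimulation grids on a camera field of view,
    rasterizes them to binary DMD pattern masks, builds automated,
    paired-delay and dendritic-integration stimulation protocols, simulates
    the acquisition rig (leaky-integrator neuron with a spatial
    photosensitivity map, spike nonlinearity, TTL trigger channel), extracts
    trigger-aligned epochs from multi-channel recordings, computes
    depolarization heat maps with spontaneous-spike artifact rejection,
    quantifies supralinear summation of paired stimuli, and renders and
    archives the results reproducibly.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    mgcv,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
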