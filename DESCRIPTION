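Package: spindlemorph
Title: Morphometry, Kinematics and Genotyping for Maize Meiotic Spindle Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of meiotic spindle architecture from
    multi-channel 3D fluorescence stacks and 4D time-lapse series, built
    around the divergent spindle 1 (dv1) kinesin-14A phenotype in maize
    meiocytes. Provides a seeded synthetic-data generator (spindle phantoms
    with a tunable pole-divergence parameter, anaphase time-lapse, qPCR Ct
    tables, count tables, CAPS amplicons), automated segmentation and
    spindle morphometry (metaphase plate width, half-spindle length,
    spindle width at a fractional position, and their focus ratio),
    chromosome-offset and anaphase kinematics from centroid tracks,
    one-way ANOVA with compact letter displays, Wilson binomial
    proportions, relative expression by the 2^-ddCt method, and in-silico
    CAPS restriction-digest genotyping.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    igraph,
    tiff,
    withr,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
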