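Package: junctionmech
Title: Breakpoint-Junction Analysis and Repair-Mechanism Classification for
    Terminal 22q13-Style Rearrangements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates, decomposes and classifies structural-variant
    breakpoint junctions of the kinds observed at broken chromosome ends:
    de novo telomere addition (healing) onto truncated sequence, telomere
    capture of subtelomeric/TAR blocks, blunt and microhomology-mediated
    non-homologous end joining (terminal, interstitial, ring and
    translocation junctions), and replication-based FoSTeS/MMBIR junctions
    carrying inverted templated insertions.  Includes detection of telomere
    hexamer (GGTTAG) arrays with variant units, fusion-point microhomology
    with the telomere repeat, junction microhomology and untemplated
    insertions, array-CGH log2-ratio segmentation with mosaic-fraction
    estimation for stepped mosaic terminal deletions, and a machine-readable
    cohort catalog with its aggregate statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
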