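Package: rdcolony
Title: Reaction-Diffusion and Positional-Information Analysis of Micropatterned Stem-Cell Colonies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates BMP4/antagonist reaction-diffusion signalling on geometrically
    confined stem-cell colony domains, including Nodal-pathway inhibition, and maps the
    resulting pSMAD1-like signalling histories to fate labels under a positional-information
    dose-by-time rule. Re-implements the single-cell colony quantification pipeline used for
    micropatterned-plate immunofluorescence data (density-based colony assignment, annular
    radial profiles with confidence intervals, hexagonal-bin expression maps, percent-positive
    statistics), nearest-neighbour periodicity statistics for signalling foci with
    Monte-Carlo significance, and delta-delta-Ct expression analysis with responder
    clustering. Ships seeded synthetic-data generators for per-cell plate tables, reference
    point patterns, and qPCR Ct tables so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
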