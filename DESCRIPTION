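Package: tubvar
Title: Residue-Level Mapping and Enrichment Analysis of Tubulin Missense Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping heterozygous missense variants of alpha-tubulin
    onto a tubulin heterodimer structure and testing whether variants linked to
    particular cortical malformations are enriched in secondary-structure
    elements or functional domains of the protein. Provides a residue-level
    structure model with three-class secondary-structure annotation, a
    microtubule lattice-neighborhood model that partitions every residue into
    one of seven mutually exclusive functional domains (longitudinal, lateral,
    MAP binding, GTP binding, lumen, intradimer, other), a taxonomy of
    amino-acid-property changes for substitutions, chi-squared goodness-of-fit
    tests against a residue-composition-proportional null, exact two-sided
    Fisher enrichment scans per phenotype and category, and a synthetic
    toy-lattice generator with planted ground truth for end-to-end validation
    and power/calibration simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
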