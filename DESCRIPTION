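Package: dirsel
Title: Directional Selection Analysis of Protein Physicochemical Properties
Version: 0.1.0
Authors@R:
    person("Dirsel", "Developers", email = "dirsel-dev@example.org",
           role = c("aut", "cre"))
Description: Detects directional (Darwinian) selection in proteins by scoring
    each inferred amino-acid replacement as a signed change in a quantitative
    physicochemical property and testing, per property and per sequence
    partition, whether the mean change differs from zero with a two-tailed
    one-sample t-test. Ships a curated 25-scale property panel spanning
    hydrophobicity, ionization, size, energy, polarity, and structural
    tendencies, a reader for the AAindex flat-file format, replacement
    extraction from aligned proteins, coding sequences, BLAST tabular output,
    or external replacement tables, whole-sequence, sliding-window, and
    region partitioning, signed significance reporting, a command-line
    interface, and null/power simulation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
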