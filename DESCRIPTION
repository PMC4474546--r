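Package: rdmlkit
Title: Read, Validate, Migrate and Analyse RDML qPCR Data Files
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the Real-time PCR Data Markup Language (RDML), the
    zip-compressed XML interchange format for quantitative PCR experiments.
    Reads and writes RDML containers for format versions 1.0, 1.1 and 1.2,
    validates documents against version-aware structural and referential
    rules, migrates files between versions with an explicit report of every
    transformation and information loss, reconstructs plate tables and
    fluorescence curves with CSV and SVG export, and estimates PCR
    amplification efficiency with uncertainty from standard curves or
    per-curve efficiency values. Includes a deterministic generator of
    synthetic RDML documents with simulated amplification and melt curves,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
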