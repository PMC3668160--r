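Package: coulsonplot
Title: Coulson Plots: Matrix-of-Pie-Chart Visualization of Presence/Absence Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Parses presence/absence tables of protein-complex subunit
    occupancy across taxa (the CPG spreadsheet dialect: hierarchical
    taxonomy header rows, complex and subunit label columns, '+'/'-' or
    '1'/'0' data cells), validates them with cell-level diagnostics, and
    renders deterministic, publication-quality Coulson plots -- a matrix
    of pie charts in which each pie is one complex in one taxon and each
    sector one subunit -- as editable SVG, with optional PDF conversion.
    Includes a seeded synthetic-fixture generator and a command-line
    interface for validation, plotting and example generation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    xml2,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
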