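Package: tmesim
Title: Cell-Fate and 3D Tumor-Microenvironment Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits an empirical event-transition model to single-cell lineage
    databases (bipolar/multipolar division, cell death, cell fusion), generates
    "deduced" cell populations with controllable alpha2-6 sialylation (SNA1
    lectin) expression by back-propagating terminal measurements up lineage
    trees, and simulates the fate of those populations among suppressive,
    permissive and lethal microenvironment cells placed uniformly in a 3D
    sphere. Includes lineage-level analytics (population curves, fate-pattern
    counts, doubling-time statistics, per-lineage SNA1 summaries), per-case
    immune-landscape categorization from tumor cell-composition tables, grid
    parameter sweeps, synthetic-data generators for every input, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
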