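Package: modevol
Title: Structural Diffs and Evolution Statistics for SBML and CellML Model Histories
Version: 0.1.0
Authors@R: person("Model", "Evolution Tools", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Computes typed structural differences (insertions, deletions,
    updates, moves and their triggered descendants) between versions of
    computational biology models encoded in SBML or CellML, classifies every
    change with COMODI-style Change/Target/XmlEntity terms, and aggregates
    whole version histories into per-version, per-transition and
    repository-evolution statistics tables. Includes a synthetic
    version-history generator with planted ground-truth edit scripts so the
    entire pipeline is verifiable offline, plus a command-line interface for
    diffing files, building tables and simulating corpora.
License: MIT
Encoding: UTF-8
Imports:
    xml2,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
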