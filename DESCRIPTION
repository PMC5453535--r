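Package: smnprofiler
Title: Ensemble-Aware Interaction and Burial Profiling of SMN Structures
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Structural profiling of the survival motor neuron (SMN) protein
    and its complexes from multi-model (NMR ensemble) PDB files. Detects salt
    bridges and side-chain hydrogen bonds with explicit geometric criteria,
    computes Shrake-Rupley solvent accessible surface areas and relative
    burial against NACCESS standard reference values, aggregates detections
    across ensemble models, classifies potentially important residues, and
    annotates spinal muscular atrophy (SMA) linked missense mutations with a
    rule-based electrostatic impact typology. Includes an NMR chemical-shift
    assignment completeness audit and deterministic synthetic-fixture
    generators for end-to-end testing without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
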