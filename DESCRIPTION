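Package: tmdscape
Title: Comparative Analysis of Single-Pass Transmembrane Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of the transmembrane domains (TMDs)
    of single-pass (bitopic) membrane proteins. Refines approximate TMD
    intervals into hydrophobic-core edges with a sliding-window hydrophobicity
    scan (GES, Wimley-White octanol, or Biological scale), aligns every TMD
    from its cytosolic edge so positions run cytosol to exoplasm regardless of
    topology, and computes positional analytics over aligned sets: residue
    frequency matrices, mean hydropathy and residue-volume profiles with
    standard errors, per-position two-sample tests, hydrophobic length
    distributions, leaflet-preference ratios, helical size moments, and
    consensus sequences. Includes curation utilities (ortholog-style length and
    hydrophobicity filters, identity-based redundancy reduction, set
    equalization), a small feed-forward neural network that classifies
    organelle of residence from TMD region compositions with cross-validation
    and Matthews-correlation statistics, and a synthetic-data generator that
    emulates organelle-specific TMD properties for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
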