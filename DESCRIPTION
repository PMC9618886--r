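Package: tmerep
Title: Tumor-Microenvironment Immune-Repertoire Analysis for Lymphoma Clone Tables
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Downstream analysis of adaptive immune-receptor repertoire (AIRR)
    clone tables from lymphoma tissue. Reads AIRR Rearrangement TSV and
    MiXCR-style clone exports, identifies and excludes the dominant
    lymphoma-derived TRB clone, renormalizes clone frequencies to obtain the
    tumor-microenvironment (TME) repertoire, and computes repertoire summary
    statistics (richness, Shannon entropy, clonality score, top-10 clone
    proportion, V-family usage). Compares two case groups by exact
    Mann-Whitney tests, detects shared (public) and differentially abundant
    CDR3 sequences, and provides a clinical statistics layer (two-sided
    Fisher exact test by hypergeometric enumeration, Kaplan-Meier estimation
    with log-rank comparison, flow-cytometry subset proportions, and greedy
    1:k case-control matching). A seeded synthetic-data generator emulates
    heavy-tailed clone abundance with a spiked tumor clone, Dirichlet
    V-family usage, a cross-sample public-clone pool, and censored survival,
    so the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
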