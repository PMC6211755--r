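Package: btchar
Title: Characterization Toolkit for Bacillus thuringiensis Cry and Vip3 Toxins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computational pipeline for characterizing Bacillus thuringiensis
    isolates by their insecticidal toxin complement. Provides in-silico PCR
    with degenerate IUPAC primers for vip3 gene screening and typing,
    unique-tryptic-peptide inference of Cry protein content from
    search-engine peptide-spectrum-match tables, probit dose-response
    analysis with Fieller fiducial limits and the fiducial-limit-overlap
    significance rule, protein-level characterization (ORF translation,
    molecular mass, residue differences, size-exclusion calibration and
    oligomeric state), and a seeded synthetic-data generator so every stage
    can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
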