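Package: methylstoich
Title: Per-Residue Lysine Methylation Stoichiometry from Label-Free Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies site-specific lysine methylation stoichiometry of
    (possibly highly repetitive) proteins from peptide-level label-free
    mass-spectrometry results. Provides in-silico tryptic digestion with
    missed cleavages, ingestion of search-engine peptide tables with
    modification annotations, equal apportionment of shared-peptide
    abundance across repeat occurrences, per-lysine occupancy percentages
    over the unmethylated/mono/di/trimethyl states, protein-level
    methylation summaries, flanking-sequence motif analysis with
    information content, a synthetic-data simulator with known ground
    truth for end-to-end parameter-recovery testing, and optical-density
    autoagglutination phenotype utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
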