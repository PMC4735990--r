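Package: phspec
Title: Sequence and Structure Analysis of PH Domain Binding Specificity
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Combined sequence/structure analysis of pleckstrin-homology (PH)
    domain binding specificity for inositol phosphates. Provides sliding-window
    physicochemical sequence profiles mapped onto multiple alignments,
    Lee-Richards solvent-accessible surface areas and residue exposure
    fractions, ligand-protein contact-surface partitioning into legitimate and
    illegitimate contacts with complementarity statistics, a finite-difference
    Poisson-Boltzmann solver for surface electrostatic potentials, signature
    motif scanning, and a rule-based decision procedure that assigns PH
    domains to four binding-specificity groups. Ships a synthetic-data
    generator producing labelled PH-like sequences and toy protein-ligand
    complexes so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    Biostrings,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
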