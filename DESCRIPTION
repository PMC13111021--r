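Package: tcrdyn
Title: Longitudinal T-Cell Receptor Beta Repertoire Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for longitudinal analysis of T-cell receptor beta (TCRB)
    repertoires from AIRR rearrangement tables: clonotype collapsing with
    junction translation and productivity filtering, detection of convergent
    rearrangements (identical CDR3 amino-acid sequence and V gene encoded by
    distinct nucleotide sequences), rarefaction to a common sequencing depth,
    Shannon diversity, Pielou evenness, convergence frequency, clone-frequency
    principal component analysis, rank-based group inference with
    Benjamini-Hochberg correction, Kaplan-Meier survival stratification, and a
    synthetic longitudinal cohort simulator that exploits codon degeneracy to
    plant convergent clonotype groups with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    survival,
    utils,
    vegan
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
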