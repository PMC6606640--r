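Package: cpdtools
Title: Compensated Pathogenic Deviations in Coagulation Factors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying compensated pathogenic deviations (CPDs) in
    human proteins, built around the hemophilia coagulation factors FVIII and
    FIX. A CPD is a human pathogenic missense variant whose mutant residue is
    the native residue in an ortholog of another species. The package scans
    ortholog multiple sequence alignments to classify variants as compensated
    or not, characterizes their molecular impact (protein stability change,
    solvent accessibility, BLOSUM62 substitution scores, Shannon entropy of
    the alignment column), tests the association between compensation and
    clinical severity (Fisher's exact test, Mood's median test), and accounts
    for the genetic background of each individual as the missense burden over
    a hemostasis gene panel. A synthetic-data generator with recorded ground
    truth emulates the variant databases, structure-based property tables and
    population cohort the analysis expects, so the full pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
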