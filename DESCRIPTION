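Package: oralactivity
Title: Paired Metagenome-Metatranscriptome Activity Analysis of the Oral Microbiota
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies species-specific and pathway-level transcriptional
    activity of microbial communities from paired shotgun metagenomes (DNA)
    and metatranscriptomes (RNA), as the log10 ratio of RNA to DNA relative
    abundance. Parses MetaPhlAn-style taxonomic tables and HUMAnN2-style
    stratified functional tables, computes contributional species diversity,
    compositional (Aitchison) and ratio-based (weighted Jaccard) beta
    diversity with principal-coordinate ordination and Shepard fidelity
    checks, and tests site and disease effects with subject-restricted
    permutation PERMANOVA, a Dirichlet-Monte-Carlo CLR differential
    abundance test, and a repeated-measures log-linear model with
    Benjamini-Hochberg FDR control. Includes a synthetic-data generator
    emulating a repeated-measures oral study (plaque, tongue, saliva;
    healthy vs periodontitis) with planted effects for power and
    calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
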