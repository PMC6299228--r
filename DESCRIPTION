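Package: dehaloscout
Title: Genome Mining and Physiology Calculations for Organohalide-Respiring Bacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens annotated bacterial genomes for putative reductive
    dehalogenase (RDase A) genes using the conserved twin-arginine (Tat)
    export signal and iron-sulfur cluster binding motifs, characterizes the
    surrounding gene cluster (membrane-anchor RDase B, sigma-54-dependent
    transcriptional activators, MarR/CRP-FNR regulators) and scans operon
    promoter regions for the sigma-54 -24/-12 element. Also provides
    pairwise-identity ortholog grouping, alignment column filtering,
    neighbor-joining trees with reference-based clade assignment, and the
    quantitative physiology calculations used to confirm organohalide
    respiration: debromination electron balance, protein yield per mmol
    electrons, concentration mass balance, and qPCR relative standard curve
    expression fold changes. Seeded synthetic-genome generators with planted
    operons supply ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    ape,
    igraph,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
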