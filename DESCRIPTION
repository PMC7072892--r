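Package: mirnascore
Title: Reliability Scoring and False-Positive Characterization for miRNA
    Microarray Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing of normalized miRNA microarray expression
    tables. Each mature miRNA receives a reliability score in [0,1]
    combining its median expression across samples, the chronological
    miRBase MIMAT accession number, and the Spearman correlation between
    mature and precursor (pre-miRNA) expression profiles. The package also
    provides validation utilities (cumulative expression coverage curves,
    score-versus-sequencing concordance with a specificity ratio,
    Mann-Whitney rank separation, grid-search weight selection), sequence
    features of false-positive probes (GC-content and mismatch-tolerant
    genomic occurrence counting), a synthetic paired array/sequencing data
    generator with planted ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    tools
Config/testthat/edition: 3
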