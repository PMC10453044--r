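Package: hibdel
Title: Deletion Detection and Interval Mapping from SNP Array Intensity
    Shifts in Hexaploid Wheat
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Detects and maps large chromosomal deletions in allohexaploid
    wheat mutants from two-channel SNP-array intensity data (NormTheta /
    NormR cluster coordinates). Implements a cluster-shift statistic against
    a euploid parent and a panel-average reference, null-allele detection,
    heterozygous confirmation in backcross F1 progeny, subgenome attribution
    via single-site markers, flanking-marker interval estimation, and gene
    annotation of deletion intervals. A synthetic-data module simulates the
    homoeologous probe-hybridisation signal structure of the three wheat
    subgenomes under an allele-dosage model, so the whole pipeline runs and
    is validated without external data. Also provides stem water-soluble
    carbohydrate (WSC) remobilisation statistics for post-anthesis
    time-course phenotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    tools,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
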