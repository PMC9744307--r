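Package: tadcoord
Title: TAD-Level Coordination Statistics for Cohesin Perturbation Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical toolkit for nascent-transcription studies of cohesin
    regulators (NIPBL/WAPL-class knockdowns). Implements permutation tests for
    the clustering and directional coordination of differentially expressed
    genes within topologically associating domains (TADs), loop-anchor
    proximity enrichment and distance-fold-change correlation, hypergeometric
    gene-set overlap against a fixed gene universe, a dominant-TSS caller for
    PRO-seq 3' end signal, a fully/partially/not-rescued classifier for
    double-knockdown experiments, and Oligopaint FISH contact and
    configuration statistics based on sphere geometry. A synthetic-data
    generator reproduces the statistical structure of each input so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
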