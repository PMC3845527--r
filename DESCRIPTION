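Package: melopav
Title: Gene Presence/Absence Variation Calling from Resequencing Read Depth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects gene presence/absence variation (PAV) among resequenced
    cultivars from per-gene read depth against a common reference genome.
    Implements a two-screen candidate search (pairwise normalized-ratio and
    absolute-count screens), a low-support filter, a deterministic
    absence/partial-absence reviewer based on relative depth and breadth of
    coverage, homology-graph gene-family construction from tabular BLASTN
    hits, positional tandem-cluster detection on the annotation backbone, and
    2x2 contingency enrichment statistics with Yates continuity correction.
    A synthetic-cohort generator simulates annotation, family and tandem
    architecture, planted deletions, read counts and homology hits, so the
    whole pipeline is testable without the original sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
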