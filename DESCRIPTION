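Package: bathydelim
Title: Multi-Criterion Molecular Species Delimitation with Bathymetric Structure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Distance-, network- and likelihood-based delimitation of
    species-level lineages from multi-marker DNA sequence alignments, with
    depth-stratified summaries for deep-sea taxa. Implements Kimura
    2-parameter pairwise divergences with barcoding-gap and 4x-criterion
    tests, haplotype collapsing and sharing reports, statistical-parsimony
    haplotype networks under a 95 percent connection limit, the
    single-threshold general mixed Yule-coalescent (GMYC) model with a
    likelihood-ratio test against a one-process null, a bathymetric-break
    scan, and a coalescent-within-Yule synthetic data generator for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
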