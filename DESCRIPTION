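Package: lrsv
Title: Structural Variant Calling from Long-Read Alignments with
    Adaptive Signature Clustering and Learned Filters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects and genotypes five classes of structural variation
    (deletions, insertions, duplications, inversions and translocations)
    from coordinate-sorted long-read alignments.  Single-read evidence is
    collected from CIGAR gaps (intra-alignment signatures) and from
    split-read geometry (inter-alignment signatures), grouped by a
    two-step clustering algorithm whose similarity scale adapts to the
    local and global signature depth, and screened by two learned
    false-positive filters: a random forest over split-read feature
    vectors and a small convolutional network over per-cluster feature
    matrices.  Genotypes are assigned by a three-hypothesis binomial
    likelihood over allele-support counts with platform-specific error
    rates.  Includes a deterministic simulator that builds references,
    implants variants and synthesizes noisy alignments with ground truth,
    so that the whole pipeline can be exercised and retrained without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rsamtools,
    GenomicRanges,
    IRanges,
    ranger,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
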