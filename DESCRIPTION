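Package: vafclust
Title: Coverage-Masked VAF Distances and Ward Clustering for Whole-Genome Relatedness
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers relatedness among sequenced individuals from per-sample
    variant-allele-frequency (VAF) vectors. Reads Freebayes-style variant
    records and per-site depth tables, applies caller-level inclusion filters
    (quality, alternate-observation count, total depth, minimum VAF) and an
    optional restriction to coding intervals, builds a samples-by-sites VAF
    matrix with a depth mask, and computes pairwise-complete normalized
    Euclidean distances in which each sample pair uses only positions
    adequately covered in both samples. Distances are clustered with Ward's
    method (ward.D2); clade stability is assessed by resampling variant
    positions with replacement. A read-level simulator of diverged diploid
    species and F1 hybrids provides cohorts with known structure for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    stats,
    utils,
    jsonlite,
    mclust,
    vcfR
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
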