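Package: vitnet
Title: Phylogeny, Hybrid Detection and Morphometric Signal in the Grape Genus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated molecular and morphological analysis toolkit for the
    grape genus Vitis and similar recently radiated plant groups. Reads per-locus
    Sanger alignments with IUPAC heterozygote codes, computes per-locus diversity
    statistics (segregating sites, Watterson's theta, nucleotide diversity,
    haplotype diversity, Tajima's D, Fay and Wu's H), phases diploid consensus
    sequences into haplotypes by an expectation-maximisation algorithm, builds
    median-joining haplotype networks, detects interspecific hybrids from
    inter-haplotype difference outliers with parental-clade assignment and
    chlorotype-based cross-direction inference, constructs neighbour-joining
    trees with bootstrap support from sequence or SNP-array data including an
    ascertainment-bias subsampling experiment, and quantifies phylogenetic
    signal in leaf measurements and ordinal ampelographic descriptors with
    Abouheif's permutation test and phylogenetic principal component analysis.
    A synthetic-data generator reproduces the statistical structure of such
    studies with full ground truth so every stage is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    ape,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
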