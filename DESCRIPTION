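Package: snppick
Title: Minimal SNP Marker Panels for Paternity Exclusion in Half-Sib Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects a minimal, linkage-aware set of biallelic SNP markers that
    identifies the paternal parent of offspring from a known, homozygous maternal
    parent within a closed, genotyped candidate population. Marker selection is
    formulated as a binary integer program over a pairwise discriminatory-power
    tensor with a heterozygosity weight for close relatives and a physical-distance
    adjacency penalty that favours marker sets near linkage equilibrium. Provides
    an exact branch-and-bound solver, a weighted greedy constructor, a one/two-flip
    neighborhood search, dataset-construction filters (minor allele frequency,
    spacing, windowed LD pruning), a Mendelian offspring simulator with genotype
    masking, an exclusion-based paternity assigner scored against simulation truth,
    and Cervus-format export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
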