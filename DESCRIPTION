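Package: viropop
Title: Viral Population Dereplication, Abundance, Microdiversity and
    Community Ecology for Metagenomic Viromes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis of assembled viral metagenomes: dereplication
    of viral contigs into species-rank populations by average nucleotide
    identity and alignment coverage, assembly-fragmentation (breakage)
    analysis against long-read representatives, trimmed-mean (tpmean)
    abundance estimation with a breadth-of-coverage presence rule,
    hypervariable-region detection from per-base read depth, additive
    virus-host linkage scoring from prophage-BLAST, tRNA-match and WIsH
    evidence, per-population nucleotide diversity (pi) from filtered and
    depth-subsampled SNV tables with bootstrap and permutation inference,
    and community-ecology statistics (cube-root Bray-Curtis, PCoA,
    PERMANOVA, centroid distances, SIMPER, bootstrapped prevalence medians).
    Includes a synthetic virome generator with known ground truth so the
    whole pipeline is testable without sequencing data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    vcfR
Suggests:
    ape,
    jsonlite,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
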