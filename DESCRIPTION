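Package: psimap
Title: Colocalization of GWAS Variants with Primate-Specific Genomic Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds non-overlapping primate-specific information (PSI) regions
    by merging heterogeneous element catalogs (HARs, human-specific insertions,
    primate-specific regulatory elements and six further classes), maps
    genome-wide significant GWAS variants into the merged regions, collapses
    significant variants into independent loci through lead-variant linkage
    disequilibrium blocks, and runs chi-square contrasts of mapping by trait
    category, element type and regulatory status. Includes a seeded synthetic
    generator for toy genomes, element sets, LD structure and GWAS summary
    statistics with known ground truth, so the whole pipeline is testable
    end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    IRanges,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
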