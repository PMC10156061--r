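Package: pebpminer
Title: Mining, Classification and Allele Phasing of Plant PEBP (FT/TFL1) Gene Homologs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for surveying plant genome assemblies for homologs of the
    PEBP (phosphatidylethanolamine-binding protein) gene family, which
    contains the FT, TFL1 and MFT clades controlling flowering time and seed
    dormancy. The package locates candidate loci by translated homology
    search, validates the canonical four-exon gene structure by spliced
    CDS-to-genome alignment, derives cross-assembly consensus coding
    sequences, classifies proteins into clades and predicts FT
    inducer/repressor function from diagnostic residues, builds
    neighbour-joining protein phylogenies with bootstrap support,
    demultiplexes and phases dual-barcoded long-amplicon read pools into
    alleles with zygosity calls, and annotates allele variants as
    synonymous, non-synonymous or stop-gained. A deterministic synthetic
    data generator produces scaffolds with embedded genes, multi-assembly
    variant sets, allele pairs and barcoded amplicon read pools so the whole
    pipeline can be exercised at desk scale without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    phangorn,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
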