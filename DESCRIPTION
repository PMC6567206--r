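Package: mabcr
Title: Genome Characterization for Marker-Assisted Backcross Breeding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to characterize introgression lines from marker-assisted
    backcross (MABC) breeding programs using whole-genome variant data.
    Filters multi-sample variant calls (donor parent, recurrent parent,
    progeny) by missingness, ploidy, depth, quality and heterozygote allele
    balance; classifies progeny sites by parental origin; computes observed
    and theoretical recurrent-parent genome recovery rates; segments
    chromosomes into graphical-genotype blocks and window densities; and
    provides a minimal codon-level variant-effect annotator with trait-gene
    cross-referencing. A forward-time backcross simulator (Haldane meioses,
    foreground selection at a target locus, configurable noise) generates
    fully synthetic multi-sample VCFs with known truth for validation.
License: MIT
Encoding: UTF-8
Imports:
    vcfR,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
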