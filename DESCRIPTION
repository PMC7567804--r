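Package: genomplexity
Title: Genomic Complexity Analysis of Whole-Genome Tumor Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterise structural and numerical genomic
    complexity in whole-genome sequenced tumors. Implements whole-genome
    doubling and chromosome-arm aneuploidy calling from allele-specific
    copy-number segments, rearrangement (32-category) and copy-number
    (40-category) feature catalogs together with the SBS96 trinucleotide
    substitution catalog, de-novo signature extraction by non-negative
    matrix factorisation with randomisation-based rank selection and
    cosine matching to reference signatures, exposure refitting with a
    minimum-contribution threshold, kataegis detection by piecewise
    constant fitting of inter-mutation distances, detection and
    classification of chromosomes carrying localized complex
    rearrangements (breakage-fusion-bridge, chromothripsis), and
    locus-level annotations (TERT-upstream breakpoints with
    super-enhancer proximity, telomere-length ratios, recurrent
    breakpoint binning). A synthetic tumor-cohort generator with truth
    labels supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    vcfR,
    pracma,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
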