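Package: cosegmap
Title: Mapping-by-Sequencing of Recessive Loci from Pooled Pedigree
    Cosegregation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Localizes a recessive Mendelian locus by mapping-by-sequencing:
    quality filtering of multi-sample variant calls, cosegregation
    classification against expected genotypes in parents, pooled offspring
    and unrelated individuals, run- and sliding-window interval statistics,
    recombinant-based interval refinement, and coding-consequence annotation
    (premature stop codons, frameshifts, splice sites) of candidate genes.
    Includes a pedigree simulator that generates reference scaffolds, gene
    models, repeat tracks and multi-sample VCFs with a planted stop-gain,
    and shape descriptors (roundness, solidity) for digitized organelle
    outlines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stringr,
    tibble,
    tidyr,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
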