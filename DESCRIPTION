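Package: codonsel
Title: Codon Usage Bias and Selection on Synonymous Sites from Population Haplotype Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing codon usage bias and weak selection on
    synonymous sites from per-gene coding-sequence haplotype alignments.
    Implements gene-level codon bias statistics (effective number of codons,
    frequency of optimal codons, codon adaptation index) with an
    amino-acid-composition randomization test; Nei-Gojobori synonymous and
    nonsynonymous site counting; diversity and polymorphism estimators
    (pairwise synonymous diversity, Watterson's theta, Tajima's D) with
    outgroup polarization of preferred and unpreferred codon changes;
    Akashi's translational-accuracy test with Mantel-Haenszel pooling;
    and maximum-likelihood estimation of the population-scaled selection
    coefficient on synonymous mutations from the site frequency spectrum
    under a reversible mutation-selection-drift model with an optional
    one-step population expansion. A synthetic-data generator produces
    haplotype alignments, gene annotations and spectra with the same
    statistical structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    GenomicRanges,
    jsonlite,
    rtracklayer,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
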