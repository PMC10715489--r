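Package: pepscape
Title: Comparative Characterisation of MHC Class-I Immunopeptidomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Set comparison, binding-affinity classification, physicochemical
    profiling and spectral-count quantification of MHC class-I peptide
    repertoires, as used to compare immunopeptidomes across engineered cell
    lines. Classifies peptides as strong or weak binders from percentile-rank
    predictions and derives a scaled binding score; profiles peptide length
    and C-terminal Kyte-Doolittle hydrophobicity with pairwise permutation
    tests; quantifies peptides shared between two samples with a Normalised
    Expression Score, fold-change classification and protein-level grouping;
    and searches identified peptides against a variant-derived mutated
    proteome built from VCF, GTF and CDS FASTA inputs. A synthetic-data
    generator produces complete fixture sets with ground truth so the whole
    pipeline runs and is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    purrr,
    rlang,
    stats,
    utils,
    jsonlite,
    Biostrings,
    GenomicRanges,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
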