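Package: crisprki
Title: Cloning-Free CRISPR/Cas9 Knock-In Design, Whole-Genome Verification,
    and a PCNA Cell-Cycle Reporter Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for designing cloning-free CRISPR/Cas9 knock-in donors
    (short 30-40 bp homology arms, in-frame fluorophore cassettes without
    start or stop codons, biotinylated donor primers, external genotyping
    primers, and donor molarity arithmetic), for verifying integrations from
    whole-genome paired-end sequencing against an insert-augmented reference
    (discordant anchor-pair clustering, split-read junction refinement, and
    depth-ratio copy-number classification), for classifying Sanger junction
    reads against the expected homology-directed repair allele, and for
    quantifying an endogenous single-channel PCNA cell-cycle reporter from
    nuclear time-lapse movies (intensity traces, pixel-intensity-distribution
    widths, replication-focus speckles, and phase segmentation). Includes
    ground-truthed simulators for loci, planted-insertion read libraries, and
    nucleus movies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
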