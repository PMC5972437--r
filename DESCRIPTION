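Package: crisprEval
Title: Matched-Site Selection, Donor Design and Editing-Outcome
    Classification for Multi-Nuclease CRISPR Experiments
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for head-to-head evaluation of CRISPR-Cas nucleases
    (SpCas9, SaCas9, NmCas9, AsCpf1, LbCpf1) at shared genomic loci. Scans
    sequences for matched target sites whose flanks satisfy the combined PAM
    requirements of several nucleases at once, models blunt (Cas9) and
    staggered (Cpf1/Cas12a) cut-site coordinates, designs symmetric and
    asymmetric single-stranded oligodeoxynucleotide (ssODN) repair templates
    that place a restriction site between the Cas9 and Cpf1 cleavage
    positions, classifies amplicon-sequencing reads into NHEJ
    (Insertion/Deletion/Match) and HDR (Correct/Wrong/No incorporation)
    outcome categories, and encodes the comparison statistics and
    nuclease-selection guidelines derived from such screens. A seeded
    amplicon-read simulator with per-read ground truth supports end-to-end
    validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
biocViews: CRISPR, SequenceMatching, Alignment, Software
RoxygenNote: 7.3.3
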