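Package: trfkit
Title: tRNA-Derived Fragment Classification and Quantification from
    Small RNA-Seq, with RNA Decay Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the analysis of tRNA-derived small RNA fragments
    (tRFs) from size-selected small-RNA sequencing libraries. Builds
    custom reference sets from tRNA gene models (intron removal, CCA
    addition, 3'-trailer windows), scans downstream sequence for RNA
    polymerase III oligo(T) terminators, aligns reads through an ordered
    cascade in which only reads unmapped at one stage proceed to the
    next, classifies fragments as tRF-5, tRF-3 or tRF-1 (including
    terminator readthrough calls), normalizes counts to CPM with
    percentile-based expression filtering and MA statistics, and
    computes an internally-controlled intragenic tRF-1/tRF-3 biomarker
    metric. Also estimates mRNA half-lives from actinomycin-D time
    courses, attributes steady-state differences to transcription versus
    stability, and provides oligo-probe Tm/Ti and isotope decay-correction
    utilities. A synthetic-data module generates tRNA gene models, reads
    and decay series with known ground truth for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
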