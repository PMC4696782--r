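Package: pepmine
Title: In Silico Neuropeptidome and Receptor Discovery from Transcriptome Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Mines transcript assemblies for neuropeptide precursor- and
    receptor-encoding sequences and predicts mature peptide structures. The
    workflow covers six-frame translation and open-reading-frame extraction,
    signal-peptide calls (heuristic or annotation override), precursor
    completeness classification (full-length, N-/C-terminal partial, internal
    fragment), prohormone-convertase cleavage-site rules at mono- and dibasic
    loci, peptide excision with C-terminal amidation, N-terminal
    pyroglutamate, tyrosine-sulfation and disulfide decoration, motif-based
    peptide family classification, translated homology search with
    reciprocal-best-hit vetting, hydropathy-based transmembrane-segment
    detection for receptor characterization, and pairwise identity/similarity
    statistics with Clustal-style conservation symbols. A ground-truthed
    synthetic precursor and transcriptome generator makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
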