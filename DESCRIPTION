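Package: aptapanel
Title: Cell-SELEX Aptamer Panel Discovery and Diagnostic Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis chain for whole-cell SELEX aptamer discovery and
    downstream diagnostic evaluation: sliding-window quality trimming and
    length filtering of per-round FASTQ reads, sequence-frequency enrichment
    tables and top-candidate nomination; saturation-binding dissociation
    constant (Kd) estimation with a nonspecific linear term; diagnostic
    sensitivity/specificity/accuracy of aptamers and aptamer panels on
    labeled tissue cohorts with stratified recognition summaries; a
    proteomic fold-change/membrane/phenotype filter cascade for candidate
    target shortlisting; and molecular-dynamics trajectory post-processing
    (Kabsch superposition RMSD, GROMOS conformational clustering,
    hydrogen-bond occupancy). Includes synthetic-data generators with known
    ground truth for every input the pipeline consumes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    methods,
    minpack.lm,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
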