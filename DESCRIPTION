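Package: finchdev
Title: Matched Transcriptome-Methylome Analysis of Developing Songbird Telencephalon
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for stagewise differential-expression testing,
    developmental expression-pattern classification, RRBS/oxRRBS
    methylation quantification and moderated differential methylation,
    transcription-factor binding-site enrichment with exact PWM match
    p-values, expression-methylation integration by linear mixed models,
    and Z-chromosome dosage-compensation classification, exercised
    end-to-end on synthetic data with known ground truth that mirrors a
    4-age x 2-sex pooled-replicate songbird brain study design.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    edgeR,
    limma,
    lme4,
    lmerTest,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
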