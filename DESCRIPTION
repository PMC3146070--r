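Package: mesmark
Title: Gene-Body Histone-Mark Quantification for ChIP-Seq in C. elegans Embryos
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies gene-body histone-mark enrichment (H3K36me3 and
    controls) from mapped single-end ChIP-seq reads: fragment extension,
    per-base-pair coverage pileup, genome-wide median normalization,
    replicate averaging, per-gene gene-body scores with log10 scatter
    tables, chromosome-level X-versus-autosome summaries, and anchored
    TSS/TES metagene profiles in 50 bp bins with 95% confidence intervals.
    Includes SAGE tag-count expression-class gene-set construction,
    immunostaining proportion statistics, ChIP-qPCR percent-input
    computation, and a deterministic synthetic-data generator (toy genome,
    classed gene annotation, enrichment-model read simulation, tissue tag
    tables) so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices, yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
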